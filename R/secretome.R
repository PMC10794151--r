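#' Enrichment status of a protein under one treatment
#'
#' Spectral-count enrichment relative to vehicle: a protein absent under
#' vehicle but detected after treatment is `unique`; with vehicle counts
#' the fold change is `treated/vehicle` and the protein is `enriched` only
#' when the fold change strictly exceeds 2; absent in both it is
#' `not_enriched`.
#'
#' @param psm_vehicle,psm_treated Non-negative spectral counts.
#' @return List with `status` (`"unique"`, `"enriched"`, `"not_enriched"`)
#'   and `fold` (`NA` when vehicle is zero).
#' @export
enrichment_status <- function(psm_vehicle, psm_treated) {
  if (psm_vehicle < 0 || psm_treated < 0)
    stop("PSM counts must be non-negative", call. = FALSE)
  if (psm_vehicle == 0) {
    if (psm_treated > 0) return(list(status = "unique", fold = NA_real_))
    return(list(status = "not_enriched", fold = NA_real_))
  }
  fold <- psm_treated / psm_vehicle
  list(status = if (fold > 2) "enriched" else "not_enriched", fold = fold)
}

validate_psm_table <- function(table, mw_windows) {
  req <- c("protein_id", "gene", "mw_kda", "secreted", "fraction",
           "psm_vehicle", "psm_pf", "psm_protx")
  missing <- setdiff(req, names(table))
  if (length(missing))
    stop("PSM table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    counts <- c(r$psm_vehicle, r$psm_pf, r$psm_protx)
    if (any(!is.finite(counts)) || any(counts < 0) ||
        any(counts != round(counts)))
      stop(sprintf("row %d (%s): PSM counts must be non-negative integers",
                   i, r$protein_id), call. = FALSE)
    if (!is.finite(r$mw_kda) || r$mw_kda <= 0)
      stop(sprintf("row %d (%s): molecular weight must be positive",
                   i, r$protein_id), call. = FALSE)
    frac_win <- switch(as.character(r$fraction),
                       "10-30" = c(10, 30), "30-100" = c(30, 100), NULL)
    if (!is.null(frac_win) &&
        (r$mw_kda < frac_win[1] || r$mw_kda > frac_win[2]))
      warning(sprintf("row %s: MW %.1f kDa inconsistent with declared fraction %s",
                      r$protein_id, r$mw_kda, r$fraction), call. = FALSE)
  }
  invisible(table)
}

#' Three-criterion secretome candidate filter
#'
#' Selects candidate secreted mediators from a fractionated
#' conditioned-medium PSM table. A row passes when (1) its molecular
#' weight lies inside one of the size windows (closed bounds; default
#' 10-30 or 30-100 kDa), (2) it is unique to, or more than twofold
#' enriched in, *both* treatments relative to vehicle, and (3) it is
#' annotated as secreted. The filter is a deterministic screen - no
#' normalisation, no statistics - and its output order (descending
#' combined treated PSM count, ties by protein id) does not depend on the
#' input row order.
#'
#' @param table A `psm_table` data frame (see [generate_psm_fixture()] for
#'   the column schema).
#' @param mw_windows List of length-2 numeric vectors, the admissible
#'   molecular-weight windows in kDa.
#' @return A data frame of class `candidate_list`: the passing rows plus
#'   reason codes (`reason_pf`, `reason_protx`) and fold changes
#'   (`fold_pf`, `fold_protx`). Empty input yields an empty candidate
#'   list.
#' @export
apply_candidate_filter <- function(table,
                                   mw_windows = list(c(10, 30), c(30, 100))) {
  empty <- structure(
    data.frame(protein_id = character(0), gene = character(0),
               mw_kda = numeric(0), secreted = logical(0),
               fraction = character(0), psm_vehicle = integer(0),
               psm_pf = integer(0), psm_protx = integer(0),
               reason_pf = character(0), reason_protx = character(0),
               fold_pf = numeric(0), fold_protx = numeric(0)),
    class = c("candidate_list", "data.frame"))
  if (nrow(table) == 0L) return(empty)
  validate_psm_table(table, mw_windows)
  keep <- logical(nrow(table))
  reason_pf <- reason_protx <- character(nrow(table))
  fold_pf <- fold_protx <- numeric(nrow(table))
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    in_window <- any(vapply(mw_windows, function(w)
      r$mw_kda >= w[1] && r$mw_kda <= w[2], logical(1)))
    epf <- enrichment_status(r$psm_vehicle, r$psm_pf)
    epx <- enrichment_status(r$psm_vehicle, r$psm_protx)
    enriched_both <- epf$status %in% c("unique", "enriched") &&
      epx$status %in% c("unique", "enriched")
    keep[i] <- in_window && enriched_both && isTRUE(r$secreted)
    reason_pf[i] <- if (epf$status == "unique") "unique_pf" else
      if (epf$status == "enriched") "fold_pf" else "not_enriched"
    reason_protx[i] <- if (epx$status == "unique") "unique_protx" else
      if (epx$status == "enriched") "fold_protx" else "not_enriched"
    fold_pf[i] <- if (is.null(epf$fold)) NA_real_ else epf$fold
    fold_protx[i] <- if (is.null(epx$fold)) NA_real_ else epx$fold
  }
  out <- cbind(as.data.frame(table)[keep, , drop = FALSE],
               data.frame(reason_pf = reason_pf[keep],
                          reason_protx = reason_protx[keep],
                          fold_pf = fold_pf[keep],
                          fold_protx = fold_protx[keep]))
  ord <- order(-(out$psm_pf + out$psm_protx), out$protein_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_list", "data.frame")
  out
}

#' @export
print.candidate_list <- function(x, ...) {
  cat(sprintf("<candidate_list> %d candidate(s) passing the three-criterion filter\n",
              nrow(x)))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Read / write PSM tables as TSV
#'
#' Plain tab-separated files with the documented header
#' (`protein_id`, `gene`, `mw_kda`, `secreted`, `fraction`,
#' `psm_vehicle`, `psm_pf`, `psm_protx`).
#'
#' @param table A `psm_table` (or candidate list) to write.
#' @param path File path.
#' @return `read_psm_table()` returns a `psm_table`;
#'   `write_psm_table()` returns `path` invisibly.
#' @export
write_psm_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_psm_table
#' @export
read_psm_table <- function(path) {
  d <- utils::read.delim(path, check.names = TRUE)
  class(d) <- c("psm_table", "data.frame")
  d
}
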