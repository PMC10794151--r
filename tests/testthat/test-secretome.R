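test_that("enrichment status implements the strict more-than-twofold rule", {
  expect_equal(enrichment_status(0, 7)$status, "unique")
  e <- enrichment_status(3, 6)
  expect_equal(e$status, "not_enriched")   # fold exactly 2.0 fails
  expect_equal(e$fold, 2)
  expect_equal(enrichment_status(3, 7)$status, "enriched")
  expect_equal(enrichment_status(3, 7)$fold, 7 / 3, tolerance = 1e-12)
  expect_equal(enrichment_status(0, 0)$status, "not_enriched")
  expect_error(enrichment_status(-1, 2), "non-negative")
})

test_that("the packaged fixture yields exactly the six planted candidates", {
  tbl <- generate_psm_fixture()
  cand <- suppressWarnings(apply_candidate_filter(tbl))
  expect_equal(nrow(cand), 6)
  expect_true("HSPA1A" %in% cand$gene)
  expect_true("MDK" %in% cand$gene)
  # each decoy fails, and for the documented single reason
  expect_false(any(c("DECMW", "DECPF", "DECFOLD", "DECSEC") %in% cand$gene))
  hsp <- cand[cand$gene == "HSPA1A", ]
  expect_equal(hsp$reason_pf, "unique_pf")
  expect_equal(hsp$reason_protx, "unique_protx")
})

test_that("each fixture decoy fails exactly one criterion", {
  tbl <- generate_psm_fixture()
  crit <- function(r) {
    mw_ok <- (r$mw_kda >= 10 & r$mw_kda <= 30) |
      (r$mw_kda >= 30 & r$mw_kda <= 100)
    both <- function(v, t) (v == 0 & t > 0) | (v > 0 & t / v > 2)
    enr_ok <- both(r$psm_vehicle, r$psm_pf) & both(r$psm_vehicle, r$psm_protx)
    c(mw_ok, enr_ok, isTRUE(r$secreted))
  }
  for (g in c("DECMW", "DECPF", "DECFOLD", "DECSEC")) {
    fails <- sum(!crit(tbl[tbl$gene == g, ]))
    expect_equal(fails, 1L, info = g)
  }
})

test_that("the filter is monotone in treated counts and order-invariant", {
  tbl <- generate_psm_fixture()
  base <- suppressWarnings(apply_candidate_filter(tbl))
  # raising any treated count never removes a candidate
  boosted <- tbl
  boosted$psm_pf <- boosted$psm_pf + 5L
  boosted$psm_protx <- boosted$psm_protx + 5L
  up <- suppressWarnings(apply_candidate_filter(boosted))
  expect_true(all(base$protein_id %in% up$protein_id))
  # lowering treated counts never adds one
  cut <- tbl
  cut$psm_pf <- pmax(0L, cut$psm_pf - 3L)
  down <- suppressWarnings(apply_candidate_filter(cut))
  expect_true(all(down$protein_id %in% base$protein_id))
  # row order does not matter
  shuffled <- tbl[rev(seq_len(nrow(tbl))), ]
  expect_identical(suppressWarnings(apply_candidate_filter(shuffled)), base)
})

test_that("degenerate tables are handled per contract", {
  tiny <- generate_psm_fixture()[0, ]
  expect_equal(nrow(apply_candidate_filter(tiny)), 0)

  all5 <- data.frame(protein_id = c("A", "B"), gene = c("a", "b"),
                     mw_kda = c(5, 5), secreted = TRUE,
                     fraction = "10-30", psm_vehicle = 0L,
                     psm_pf = 10L, psm_protx = 10L)
  expect_equal(nrow(suppressWarnings(apply_candidate_filter(all5))), 0)

  bad <- all5
  bad$psm_pf[1] <- -2L
  expect_error(suppressWarnings(apply_candidate_filter(bad)), "row 1")
})

test_that("PSM tables round-trip through TSV", {
  tbl <- generate_psm_fixture()
  path <- tempfile(fileext = ".tsv")
  write_psm_table(tbl, path)
  back <- read_psm_table(path)
  expect_equal(back$psm_pf, tbl$psm_pf)
  expect_equal(back$mw_kda, tbl$mw_kda)
  expect_identical(suppressWarnings(apply_candidate_filter(back))$protein_id,
                   suppressWarnings(apply_candidate_filter(tbl))$protein_id)
})
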