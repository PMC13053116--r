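test_that("triage thresholds follow the published review design", {
  expect_equal(triage_variant(15, FALSE)$path, "FULL_ACMG")
  expect_equal(triage_variant(2, TRUE)$path, "LOF_CURATION")
  expect_equal(triage_variant(14, FALSE)$path, "ABBREVIATED")
  expect_equal(triage_variant(0, TRUE)$path, "ABBREVIATED")
  expect_true(triage_variant(20, TRUE)$also_lof)
  expect_false(triage_variant(20, FALSE)$also_lof)
  expect_error(triage_variant(-1, FALSE), "negative")
})

test_that("triage is a pure function of (AC, pLoF) across the AC range", {
  set.seed(11)
  ac <- c(0:100, sort(sample.int(1e6, 400)))
  for (plof in c(TRUE, FALSE)) {
    got <- triage_variant(ac, rep(plof, length(ac)))
    # independent restatement of the rule
    want <- ifelse(ac >= 15, "FULL_ACMG",
                   ifelse(plof & ac >= 2, "LOF_CURATION", "ABBREVIATED"))
    expect_equal(got$path, want)
    expect_equal(got$also_lof, plof & ac >= 15)
  }
})

test_that("classification policy matches the hand-written grid", {
  sources <- c("P", "LP", "CONFLICTING_WITH_PLP", "DM", "PLOF_HC")
  curated <- c("P", "LP", "VUS", "LB", "B", NA)
  for (s in sources) {
    for (cu in curated) {
      got <- reconcile_classification(s, cu)
      want <- oracle_reconcile(s, cu)
      expect_equal(got, want, info = paste(s, cu))
    }
  }
  # multi-source precedence: P beats LP beats held-at-VUS claims
  expect_equal(reconcile_classification(c("DM", "P"))$final_class, "P")
  expect_equal(reconcile_classification(c("LP", "DM"))$final_class, "LP")
  expect_equal(reconcile_classification(c("DM", "PLOF_HC"))$final_class, "VUS")
  expect_true(reconcile_classification(c("DM", "PLOF_HC"))$downgraded_from_plp)
  expect_false(reconcile_classification("PLOF_HC")$downgraded_from_plp)
  expect_error(reconcile_classification("XX"), "unknown source assertion")
  expect_error(reconcile_classification("P", "MAYBE"), "unknown classification")
})

test_that("a curation downgrade to VUS is flagged and kept in the relaxed set", {
  rec <- tibble::tibble(contig = "3", pos = 1L, ref = "A", alt = "G",
                        source = "CLINVAR", asserted_class = "LP",
                        hgvs_c = NA_character_, hgvs_p = NA_character_,
                        source_id = NA_character_)
  cand <- dedupe_candidates(rec)
  cls <- tibble::tibble(contig = "3", pos = 1L, ref = "A", alt = "G",
                        final_class = "VUS")
  out <- classify_candidates(cand, cls)
  expect_equal(out$final_class, "VUS")
  expect_true(out$downgraded_from_plp)
  expect_equal(nrow(inclusion_set(out, "conservative")), 0L)
  expect_equal(nrow(inclusion_set(out, "relaxed")), 1L)
})

test_that("inclusion sets reproduce the study composition and invariants", {
  res <- fixture_pipeline()
  cons <- inclusion_set(res$classified, "conservative")
  rel <- inclusion_set(res$classified, "relaxed")
  expect_equal(nrow(res$classified), 270L)
  expect_equal(nrow(cons), 238L)
  expect_equal(nrow(rel), 266L)
  expect_setequal(cons$final_class, c("P", "LP"))
  expect_false(any(rel$final_class %in% c("B", "LB")))
  # conservative subset of relaxed; difference is exactly the downgrades
  key <- function(x) paste(x$contig, x$pos, x$ref, x$alt)
  expect_true(all(key(cons) %in% key(rel)))
  expect_equal(nrow(rel) - nrow(cons),
               sum(res$classified$downgraded_from_plp &
                     res$classified$final_class == "VUS"))
  expect_equal(sum(res$classified$final_class == "P"), 8L)
  expect_equal(sum(res$classified$final_class == "LP"), 230L)
  # empty input stays empty
  expect_equal(nrow(inclusion_set(res$classified[0, ], "relaxed")), 0L)
})

test_that("triage queue orders full reviews first, then by allele count", {
  res <- fixture_pipeline()
  q <- triage_queue(res$classified)
  rank <- match(q$triage_path, c("FULL_ACMG", "LOF_CURATION", "ABBREVIATED"))
  expect_true(!is.unsorted(rank))
  for (p in unique(q$triage_path)) {
    expect_true(!is.unsorted(-q$ac_total[q$triage_path == p]))
  }
  # fixture triage load matches the study: 104 full/LoF reviews of 270
  expect_equal(sum(q$triage_path != "ABBREVIATED"), 104L)
})
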