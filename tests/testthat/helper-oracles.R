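# Independent oracles used across the suite.

# apply a (pos, ref, alt) edit to a context string anchored at context_start
apply_edit <- function(context, context_start, pos, ref, alt) {
  off <- pos - context_start + 1
  stopifnot(substr(context, off, off + nchar(ref) - 1) == ref)
  paste0(substr(context, 1, off - 1), alt,
         substr(context, off + nchar(ref), nchar(context)))
}

# brute force: enumerate every equivalent (pos, ref, alt) representation of
# an edit within the context, keep those with non-empty ACGT alleles, and
# return the leftmost among the shortest (minimal) representations.
oracle_normalize <- function(context, context_start, pos, ref, alt) {
  mutated <- apply_edit(context, context_start, pos, ref, alt)
  L <- nchar(context)
  cands <- list()
  for (p in seq_len(L)) {
    for (rl in 0:(L - p + 1)) {
      al <- nchar(mutated) - (L - rl)
      if (al < 1 || rl < 1) next
      cref <- substr(context, p, p + rl - 1)
      calt <- substr(mutated, p, p + al - 1)
      if (cref == calt) next
      if (apply_edit(context, 1, p, cref, calt) == mutated) {
        cands[[length(cands) + 1]] <- list(
          pos = context_start + p - 1, ref = cref, alt = calt,
          len = rl + al
        )
      }
    }
  }
  stopifnot(length(cands) > 0)
  lens <- vapply(cands, `[[`, numeric(1), "len")
  cands <- cands[lens == min(lens)]
  poss <- vapply(cands, `[[`, numeric(1), "pos")
  cands[[which.min(poss)]]
}

# hand-written classification policy table: curated class wins; otherwise
# P and LP are honoured and every other claim is held at VUS.
oracle_reconcile <- function(asserted, curated) {
  final <- if (!is.na(curated)) {
    curated
  } else {
    switch(asserted, P = "P", LP = "LP", "VUS")
  }
  list(
    final_class = final,
    downgraded_from_plp = final == "VUS" &&
      asserted %in% c("P", "LP", "CONFLICTING_WITH_PLP", "DM")
  )
}

# minimal candidate table builder for estimator tests: one row per variant
# with AC/AN columns for every standard group (zeros elsewhere)
make_variants <- function(ac, an, group) {
  n <- max(length(ac), length(an))
  ac <- rep_len(ac, n); an <- rep_len(an, n)
  group <- rep_len(group, n)
  out <- tibble::tibble(
    contig = "3", pos = seq_len(n), ref = "A", alt = "C"
  )
  for (g in ancestry_groups()) {
    out[[paste0("AC_", g)]] <- ifelse(group == g, ac, 0L)
    out[[paste0("AN_", g)]] <- ifelse(group == g, an,
                                      ifelse(an > 0, 10000L, 0L))
    out[[paste0("nhomalt_", g)]] <- 0L
  }
  out
}

# shared deterministic fixture bundle for tests that need the full pipeline
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "genoprev-fixture")
      cache <<- generate_paper_fixture(dir)
    }
    cache
  }
})

fixture_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture_bundle()
      cfg <- run_config(
        freqs = fx$paths$frequencies, clinvar = fx$paths$clinvar,
        hgmd = fx$paths$hgmd, plof = fx$paths$plof,
        classifications = fx$paths$classifications,
        populations = fx$paths$populations, mode = "both",
        out_dir = file.path(tempdir(), "genoprev-fixture-run")
      )
      cache <<- suppressWarnings(run_pipeline(cfg))
    }
    cache
  }
})
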