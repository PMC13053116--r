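write_tsv_tmp <- function(df, name) {
  p <- file.path(tempdir(), name)
  readr::write_tsv(df, p, progress = FALSE)
  p
}

test_that("clinvar reader applies the P/LP/conflicting inclusion criterion", {
  df <- tibble::tibble(
    contig = "3", pos = 1:6 * 10L, ref = "A", alt = "G",
    classification = c("Pathogenic", "Likely pathogenic", "Benign",
                       "Uncertain significance",
                       "Conflicting classifications of pathogenicity",
                       "Conflicting classifications of pathogenicity"),
    has_plp = c(0L, 0L, 0L, 0L, 1L, 0L),
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    source_id = paste0("V", 1:6)
  )
  rec <- read_source_table(write_tsv_tmp(df, "cv.tsv"), "clinvar")
  expect_equal(nrow(rec), 3L)
  expect_setequal(rec$asserted_class, c("P", "LP", "CONFLICTING_WITH_PLP"))
  sk <- skip_summary(rec)
  expect_equal(sum(sk$n), 3L)
  expect_setequal(sk$reason,
                  c("clinvar_benign", "clinvar_vus", "conflicting_without_plp"))
  # conservation: kept + skipped = rows read
  expect_equal(nrow(rec) + sum(sk$n), attr(rec, "n_rows"))
})

test_that("hgmd and plof readers keep only DM / HC records", {
  df <- tibble::tibble(
    contig = "3", pos = 1:3 * 10L, ref = "C", alt = "T",
    classification = c("DM", "DM?", "DP"), source_id = paste0("CM", 1:3)
  )
  rec <- read_source_table(write_tsv_tmp(df, "hg.tsv"), "hgmd")
  expect_equal(rec$asserted_class, "DM")
  expect_equal(sum(skip_summary(rec)$n), 2L)

  df$classification <- c("HC", "LC", "OS")
  rec2 <- read_source_table(write_tsv_tmp(df, "pl.tsv"), "plof")
  expect_equal(rec2$asserted_class, "PLOF_HC")
  expect_equal(sum(skip_summary(rec2)$n), 2L)
})

test_that("header-only files give empty record sets; missing columns error", {
  empty <- tibble::tibble(contig = character(), pos = integer(),
                          ref = character(), alt = character(),
                          classification = character())
  rec <- read_source_table(write_tsv_tmp(empty, "empty.tsv"), "clinvar")
  expect_equal(nrow(rec), 0L)

  bad <- tibble::tibble(contig = "3", pos = 1L, ref = "A", alt = "G")
  expect_error(read_source_table(write_tsv_tmp(bad, "bad.tsv"), "hgmd"),
               "classification")
  expect_error(read_frequency_table(write_tsv_tmp(bad, "badf.tsv")), "AC_afr")
})

test_that("unparseable rows are skipped with their line number", {
  df <- tibble::tibble(
    contig = "3", pos = c("10", "oops", "30"), ref = c("A", "A", "AA"),
    alt = c("G", "G", "AA"), classification = "DM"
  )
  rec <- read_source_table(write_tsv_tmp(df, "rows.tsv"), "hgmd")
  expect_equal(nrow(rec), 1L)
  expect_true(any(grepl("unparseable_row_line_", skip_summary(rec)$reason)))
})

test_that("frequency table enforces AC/AN/nhomalt consistency", {
  fx <- fixture_bundle()
  freqs <- read_frequency_table(fx$paths$frequencies)
  expect_true(all(freqs$AC_nfe <= freqs$AN_nfe))
  bad <- freqs[1, ]
  bad$AC_afr <- bad$AN_afr + 1L
  expect_error(read_frequency_table(write_tsv_tmp(bad, "badfreq.tsv")),
               "inconsistent")
})

test_that("vcf dialect of the frequency table matches the tsv dialect", {
  skip_if_not_installed("vcfR")
  fx <- fixture_bundle()
  freqs <- read_frequency_table(fx$paths$frequencies)
  sub <- freqs[1:5, ]
  groups <- ancestry_groups()
  triples <- as.vector(t(outer(c("AC_", "AN_", "nhomalt_"), groups, paste0)))
  info <- apply(sub[triples], 1, function(r) {
    paste(paste0(triples, "=", r), collapse = ";")
  })
  vcf <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=", triples,
           ",Number=1,Type=Integer,Description=\"x\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
            sub$contig, sub$pos, sub$ref, sub$alt, info)
  )
  vp <- file.path(tempdir(), "freq.vcf")
  writeLines(vcf, vp)
  from_vcf <- read_frequency_table(vp, dialect = "vcf")
  expect_equal(as.data.frame(from_vcf[names(sub)]), as.data.frame(sub),
               ignore_attr = TRUE)
})

test_that("dedupe collapses keys, unions provenance, and matches a set oracle", {
  rec <- function(pos, source, cls) {
    tibble::tibble(contig = "3", pos = pos, ref = "A", alt = "G",
                   source = source, asserted_class = cls,
                   hgvs_c = NA_character_, hgvs_p = NA_character_,
                   source_id = NA_character_)
  }
  records <- dplyr::bind_rows(
    rec(100L, "CLINVAR", "LP"), rec(100L, "HGMD", "DM"),
    rec(200L, "CLINVAR", "P")
  )
  cand <- dedupe_candidates(records)
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$n_sources[cand$pos == 100L], 2L)
  expect_false(any(cand$is_plof))

  # random duplicate-injected list vs brute-force distinct-key count
  set.seed(7)
  pool <- sample(1:400, 60)
  many <- dplyr::bind_rows(lapply(sample(pool, 150, replace = TRUE),
                                  function(p) rec(p, "HGMD", "DM")))
  cand2 <- dedupe_candidates(many)
  expect_equal(nrow(cand2), length(unique(many$pos)))
  expect_true(!is.unsorted(cand2$pos))
  # idempotence of the dedup key set
  expect_equal(nrow(dedupe_candidates(many[!duplicated(many$pos), ])),
               nrow(cand2))
})

test_that("candidates missing from the frequency table contribute zero AF", {
  fx <- fixture_bundle()
  freqs <- read_frequency_table(fx$paths$frequencies)
  rec <- tibble::tibble(contig = "3", pos = c(freqs$pos[1], 999L),
                        ref = c(freqs$ref[1], "A"),
                        alt = c(freqs$alt[1], "G"),
                        source = "HGMD", asserted_class = "DM",
                        hgvs_c = NA_character_, hgvs_p = NA_character_,
                        source_id = NA_character_)
  cand <- dedupe_candidates(rec, freqs)
  expect_equal(nrow(cand), 2L)          # retained for curation queues
  absent <- cand[cand$pos == 999L, ]
  expect_false(absent$in_gnomad)
  expect_equal(absent$ac_total, 0L)
  expect_true(cand$in_gnomad[cand$pos == freqs$pos[1]])
})
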