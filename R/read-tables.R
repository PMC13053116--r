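#' Read an ancestry-stratified frequency table
#'
#' Reads a per-variant allele-count table with one `AC_<group>`,
#' `AN_<group>`, `nhomalt_<group>` triple per ancestry group, either as TSV
#' or as a sites VCF whose INFO field carries the same keys. `AC` is the
#' alternate allele count, `AN` the total number of called alleles (2 x
#' genotyped individuals) and `nhomalt` the number of homozygous carriers.
#'
#' @param path Path to the table.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param groups Ancestry-group labels expected in the header; defaults to
#'   [ancestry_groups()].
#' @return A tibble with columns `contig`, `pos`, `ref`, `alt` and the
#'   per-group triples. Rows violating `AC <= AN` or `2*nhomalt <= AC` raise
#'   an error naming the offending variant.
#' @export
read_frequency_table <- function(path, dialect = c("tsv", "vcf"),
                                 groups = ancestry_groups()) {
  dialect <- match.arg(dialect)
  triples <- as.vector(t(outer(c("AC_", "AN_", "nhomalt_"), groups, paste0)))
  if (dialect == "tsv") {
    df <- read_tsv_strict(path, c("contig", "pos", "ref", "alt", triples))
  } else {
    df <- read_frequency_vcf(path, triples)
  }
  df$pos <- as.integer(df$pos)
  for (cc in triples) df[[cc]] <- as.integer(df[[cc]])
  for (g in groups) {
    ac <- df[[paste0("AC_", g)]]
    an <- df[[paste0("AN_", g)]]
    hm <- df[[paste0("nhomalt_", g)]]
    bad <- which(ac > an | 2L * hm > ac | ac < 0L | an < 0L | hm < 0L)
    if (length(bad)) {
      stop("inconsistent AC/AN/nhomalt for group ", g, " at ",
           df$contig[bad[1]], ":", df$pos[bad[1]], call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

read_frequency_vcf <- function(path, triples) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcf dialect requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- data.frame(
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  for (key in triples) {
    val <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    if (all(is.na(val))) {
      stop("missing mandatory INFO field ", key, " in ", path, call. = FALSE)
    }
    out[[key]] <- as.integer(val)
  }
  out
}

# classification-string mappings per source dialect
clinvar_class_map <- c(
  "pathogenic" = "P",
  "likely pathogenic" = "LP",
  "pathogenic/likely pathogenic" = "LP",
  "uncertain significance" = "EXCLUDE_VUS",
  "likely benign" = "EXCLUDE_BENIGN",
  "benign" = "EXCLUDE_BENIGN"
)

#' Read a source assertion table
#'
#' Reads a ClinVar-, HGMD- or pLoF-style candidate table (TSV with columns
#' `contig`, `pos`, `ref`, `alt`, `classification`, `review_status`,
#' `hgvs_c`, `hgvs_p`, `source_id`) and keeps only rows meeting the source's
#' inclusion criterion:
#'
#' * `clinvar`: pathogenic / likely pathogenic, or conflicting records with
#'   at least one P/LP assertion (requires a truthy `has_plp` column on
#'   conflicting rows). VUS- and benign-only records are excluded.
#' * `hgmd`: disease-causing mutation (`DM`) records only.
#' * `plof`: high-confidence predicted loss-of-function (`HC`) records only.
#'
#' Excluded rows are tallied by reason in the `skips` attribute (see
#' [skip_summary()]), so that included + skipped = rows read.
#'
#' @param path Path to the TSV.
#' @param source One of `"clinvar"`, `"hgmd"`, `"plof"`.
#' @return Tibble of source records with columns `contig`, `pos`, `ref`,
#'   `alt`, `source`, `asserted_class`, `hgvs_c`, `hgvs_p`, `source_id`.
#' @export
read_source_table <- function(path, source = c("clinvar", "hgmd", "plof")) {
  source <- match.arg(source)
  df <- read_tsv_strict(path, c("contig", "pos", "ref", "alt", "classification"))
  for (opt in c("review_status", "hgvs_c", "hgvs_p", "source_id")) {
    if (is.null(df[[opt]])) df[[opt]] <- NA_character_
  }
  n_in <- nrow(df)
  cls <- tolower(trimws(as.character(df$classification)))
  skip_reason <- rep(NA_character_, n_in)

  if (source == "clinvar") {
    asserted <- unname(clinvar_class_map[cls])
    conflicting <- grepl("^conflicting", cls)
    if (any(conflicting)) {
      if (is.null(df$has_plp)) {
        skip_reason[conflicting] <- "conflicting_missing_plp_flag"
      } else {
        has_plp <- as.logical(as.integer(df$has_plp)) %in% TRUE
        asserted[conflicting & has_plp] <- "CONFLICTING_WITH_PLP"
        skip_reason[conflicting & !has_plp] <- "conflicting_without_plp"
      }
    }
    skip_reason[is.na(asserted) & is.na(skip_reason) & !conflicting] <-
      "unrecognized_classification"
    skip_reason[asserted %in% "EXCLUDE_VUS"] <- "clinvar_vus"
    skip_reason[asserted %in% "EXCLUDE_BENIGN"] <- "clinvar_benign"
    asserted[!is.na(asserted) & startsWith(asserted, "EXCLUDE")] <- NA_character_
  } else if (source == "hgmd") {
    asserted <- ifelse(toupper(cls) == "DM", "DM", NA_character_)
    skip_reason[is.na(asserted)] <- "hgmd_not_dm"
  } else {
    asserted <- ifelse(toupper(cls) == "HC", "PLOF_HC", NA_character_)
    skip_reason[is.na(asserted)] <- "plof_not_high_confidence"
  }

  keep <- is.na(skip_reason) & !is.na(asserted)
  # malformed coordinates are skipped with the line number logged
  pos_ok <- !is.na(suppressWarnings(as.integer(df$pos)))
  allele_ok <- grepl("^[ACGTacgt]+$", df$ref) & grepl("^[ACGTacgt]+$", df$alt) &
    toupper(df$ref) != toupper(df$alt)
  bad_row <- keep & !(pos_ok & allele_ok)
  if (any(bad_row)) {
    skip_reason[bad_row] <- paste0("unparseable_row_line_", which(bad_row) + 1L)
    keep[bad_row] <- FALSE
  }

  out <- tibble::tibble(
    contig = as.character(df$contig[keep]),
    pos = as.integer(df$pos[keep]),
    ref = toupper(df$ref[keep]),
    alt = toupper(df$alt[keep]),
    source = toupper(source_label(source)),
    asserted_class = asserted[keep],
    hgvs_c = as.character(df$hgvs_c[keep]),
    hgvs_p = as.character(df$hgvs_p[keep]),
    source_id = as.character(df$source_id[keep])
  )
  skips <- table(skip_reason[!keep & !is.na(skip_reason)])
  attr(out, "skips") <- tibble::tibble(
    reason = names(skips), n = as.integer(skips)
  )
  attr(out, "n_rows") <- n_in
  out
}

source_label <- function(source) {
  switch(source, clinvar = "CLINVAR", hgmd = "HGMD", plof = "GNOMAD_PLOF")
}

`%||%` <- function(x, y) ifelse(is.na(x), y, x)

#' Skip summary of a source read
#'
#' @param x A table returned by [read_source_table()].
#' @return Tibble with columns `reason` and `n`, one row per skip reason.
#' @export
skip_summary <- function(x) {
  s <- attr(x, "skips")
  if (is.null(s)) tibble::tibble(reason = character(), n = integer()) else s
}

#' Read a curated classification file
#'
#' TSV with columns `contig`, `pos`, `ref`, `alt`, `final_class` (one of P,
#' LP, VUS, LB, B) and optional `curation_date`, `evidence_note`. Absence of
#' a row for a candidate means no curation was performed.
#'
#' @param path Path to the TSV.
#' @return Tibble of curated classifications.
#' @export
read_classification_file <- function(path) {
  df <- read_tsv_strict(path, c("contig", "pos", "ref", "alt", "final_class"))
  df$final_class <- toupper(trimws(df$final_class))
  bad <- setdiff(unique(df$final_class), GP_FINAL_CLASSES)
  if (length(bad)) {
    stop("unknown classification label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$pos <- as.integer(df$pos)
  tibble::as_tibble(df)
}

#' Read a population-size table
#'
#' TSV with columns `population_name`, `population_size` and optional
#' `year`, `source_note`, used by [project_affected()].
#'
#' @param path Path to the TSV.
#' @return Tibble of populations.
#' @export
read_population_table <- function(path) {
  df <- read_tsv_strict(path, c("population_name", "population_size"))
  df$population_size <- as.numeric(df$population_size)
  tibble::as_tibble(df)
}

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
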