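#' Configuration for a simulated reference cohort
#'
#' @param groups Tibble (or data frame) with columns `label` and `an`
#'   (allele number per group: 2 x genotyped individuals, even, positive).
#' @param n_variants_by_class Named counts for classes `P`, `LP`, `VUS`,
#'   `LB`, `B` (missing classes default to 0).
#' @param target_sum_q Named per-group true aggregate allele frequency of
#'   the pathogenic/likely pathogenic variants, each in `[0, 0.5)`.
#' @param plof_fraction Proportion of variants flagged as high-confidence
#'   predicted loss-of-function.
#' @param seed Integer seed; every stochastic draw in
#'   [generate_cohort()] is scoped to it.
#' @return Validated config (a list) for [generate_cohort()].
#' @export
cohort_config <- function(groups, n_variants_by_class, target_sum_q,
                          plof_fraction = 0.3, seed = 1L) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("label", "an") %in% names(groups)),
            all(groups$an > 0), all(groups$an %% 2 == 0))
  cls <- stats::setNames(rep(0L, length(GP_FINAL_CLASSES)), GP_FINAL_CLASSES)
  cls[names(n_variants_by_class)] <- as.integer(n_variants_by_class)
  stopifnot(all(cls >= 0))
  tq <- rep(0, nrow(groups))
  names(tq) <- groups$label
  tq[names(target_sum_q)] <- target_sum_q
  stopifnot(all(tq >= 0), all(tq < 0.5))
  if (any(tq > 0) && cls[["P"]] + cls[["LP"]] == 0L) {
    stop("target aggregate frequency requires at least one P/LP variant",
         call. = FALSE)
  }
  list(groups = groups, n_variants_by_class = cls, target_sum_q = tq,
       plof_fraction = plof_fraction, seed = as.integer(seed))
}

#' Simulate a gnomAD-like cohort
#'
#' Draws per-variant true allele frequencies by splitting each group's
#' target aggregate frequency across its pathogenic/likely pathogenic
#' variants with a symmetric Dirichlet, then samples observed allele counts
#' `AC ~ Binomial(AN, q)` per group and sets homozygote counts to the
#' Hardy-Weinberg expectation rounded down. VUS variants receive one tenth
#' of the target mass (they carry frequency but are excluded from
#' conservative estimates); benign variants are sampled at the same scale.
#' The same seed always reproduces the same tables.
#'
#' @param config From [cohort_config()].
#' @param dir Optional output directory; when given, the candidate tables,
#'   frequency table, classification file and a manifest are written in the
#'   same TSV dialects the readers consume.
#' @return List with `frequencies`, `classifications`, `clinvar`,
#'   `truth` (per-variant, per-group true `q`), and `paths` when `dir` was
#'   supplied.
#' @export
generate_cohort <- function(config, dir = NULL) {
  cls <- config$n_variants_by_class
  n <- sum(cls)
  if (n == 0L) stop("config contains zero variants", call. = FALSE)
  labels <- config$groups$label
  an <- stats::setNames(config$groups$an, labels)

  withr::with_seed(config$seed, {
    final_class <- rep(names(cls), times = cls)
    is_plp <- final_class %in% c("P", "LP")
    # symmetric Dirichlet split via normalized Gamma(1) draws
    q <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
    for (g in labels) {
      tq <- config$target_sum_q[[g]]
      if (tq > 0) {
        w <- rgamma(sum(is_plp), shape = 1)
        q[is_plp, g] <- tq * w / sum(w)
        if (any(!is_plp)) {
          w2 <- rgamma(sum(!is_plp), shape = 1)
          q[!is_plp, g] <- 0.1 * tq * w2 / sum(w2)
        }
      }
    }
    AC <- matrix(rbinom(n * length(labels), rep(an, each = n), as.vector(q)),
                 n, length(labels), dimnames = list(NULL, labels))
    plof <- stats::runif(n) < config$plof_fraction
  })
  AN <- matrix(rep(an, each = n), n, dimnames = list(NULL, labels))
  NH <- pmin(floor((AC / AN)^2 * AN / 2), floor(AC / 2))

  ids <- tibble::tibble(
    contig = "3", pos = 81600000L + seq_len(n) * 17L,
    ref = c("A", "C", "G", "T")[(seq_len(n) %% 4L) + 1L],
    alt = c("C", "G", "T", "A")[(seq_len(n) %% 4L) + 1L]
  )
  freqs <- ids
  for (g in labels) {
    freqs[[paste0("AC_", g)]] <- as.integer(AC[, g])
    freqs[[paste0("AN_", g)]] <- as.integer(AN[, g])
    freqs[[paste0("nhomalt_", g)]] <- as.integer(NH[, g])
  }
  # frequency columns for any standard group absent from the config
  for (g in setdiff(GP_GROUPS, labels)) {
    freqs[[paste0("AC_", g)]] <- 0L
    freqs[[paste0("AN_", g)]] <- 0L
    freqs[[paste0("nhomalt_", g)]] <- 0L
  }

  clinvar <- dplyr::bind_cols(ids, tibble::tibble(
    classification = ifelse(final_class == "P", "Pathogenic", "Likely pathogenic"),
    review_status = "criteria provided, multiple submitters",
    has_plp = 0L,
    hgvs_c = paste0("c.sim", seq_len(n)),
    hgvs_p = NA_character_,
    source_id = paste0("SIM", seq_len(n))
  ))
  plof_tbl <- dplyr::bind_cols(ids[plof, ], tibble::tibble(
    classification = "HC", review_status = NA_character_,
    hgvs_c = paste0("c.sim", which(plof)), hgvs_p = NA_character_,
    source_id = paste0("SIMpLoF", which(plof))
  ))
  classifications <- dplyr::bind_cols(ids, tibble::tibble(
    final_class = final_class,
    curation_date = "simulated", evidence_note = ""
  ))
  truth <- dplyr::bind_cols(ids, tibble::as_tibble(q))

  out <- list(frequencies = freqs, clinvar = clinvar, plof = plof_tbl,
              classifications = classifications, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      frequencies = file.path(dir, "frequencies.tsv"),
      clinvar = file.path(dir, "clinvar.tsv"),
      plof = file.path(dir, "plof.tsv"),
      classifications = file.path(dir, "classifications.tsv"),
      manifest = file.path(dir, "manifest.json")
    )
    readr::write_tsv(freqs, paths$frequencies, progress = FALSE)
    readr::write_tsv(clinvar, paths$clinvar, progress = FALSE)
    readr::write_tsv(plof_tbl, paths$plof, progress = FALSE)
    readr::write_tsv(classifications, paths$classifications, progress = FALSE)
    jsonlite::write_json(
      list(generator = "genoprev::generate_cohort", seed = config$seed,
           n_variants_by_class = as.list(config$n_variants_by_class),
           target_sum_q = as.list(config$target_sum_q),
           plof_fraction = config$plof_fraction,
           groups = stats::setNames(as.list(config$groups$an), labels)),
      paths$manifest, auto_unbox = TRUE, pretty = TRUE
    )
    out$paths <- paths
  }
  out
}
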