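#' Curation triage decision from allele count
#'
#' Assigns the curation path used to prioritize review of candidate
#' variants: any variant with total allele count at or above 15 (global
#' allele frequency above 1e-5 in a gnomAD-v4-sized cohort) receives a full
#' ACMG/AMP curation; below that, predicted loss-of-function variants seen
#' more than once receive a dedicated LoF curation; everything else gets an
#' abbreviated curation (e.g. a literature check). A full-curation variant
#' that is also pLoF additionally requires LoF curation (`also_lof`).
#'
#' @param ac_total Total (all-groups) allele count; vectorized.
#' @param is_plof Logical, high-confidence predicted loss-of-function flag.
#' @return Tibble with columns `path` (`"FULL_ACMG"`, `"LOF_CURATION"` or
#'   `"ABBREVIATED"`) and `also_lof`.
#' @export
#' @examples
#' triage_variant(c(15, 2, 14, 0), c(FALSE, TRUE, FALSE, TRUE))
triage_variant <- function(ac_total, is_plof) {
  if (any(ac_total < 0)) stop("negative allele count", call. = FALSE)
  stopifnot(length(is_plof) == length(ac_total))
  path <- ifelse(ac_total >= 15, "FULL_ACMG",
                 ifelse(is_plof & ac_total > 1, "LOF_CURATION", "ABBREVIATED"))
  tibble::tibble(path = path, also_lof = path == "FULL_ACMG" & is_plof)
}

#' Reconcile source assertions with a curated classification
#'
#' The scalar classification policy: a curated classification (the outcome
#' of human ACMG/AMP review, supplied via the classification file) always
#' wins. Without curation, source assertions map conservatively -- ClinVar
#' P and LP are taken at face value, while HGMD disease-causing-mutation
#' claims, conflicting-with-P/LP records and bare pLoF calls are held at
#' VUS rather than promoted.
#'
#' @param asserted_classes Character vector of source assertions for one
#'   candidate (subset of `P`, `LP`, `CONFLICTING_WITH_PLP`, `DM`,
#'   `PLOF_HC`).
#' @param curated_class Optional curated classification (`P`, `LP`, `VUS`,
#'   `LB`, `B`) or `NA`.
#' @return List with `final_class` and `downgraded_from_plp` (`TRUE` only
#'   for a final VUS whose provenance carried a P/LP-type claim).
#' @export
reconcile_classification <- function(asserted_classes, curated_class = NA) {
  bad <- setdiff(asserted_classes, GP_SOURCE_CLASSES)
  if (length(bad)) {
    stop("unknown source assertion label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.na(curated_class) && !curated_class %in% GP_FINAL_CLASSES) {
    stop("unknown classification label: ", curated_class, call. = FALSE)
  }
  final <- if (!is.na(curated_class)) {
    curated_class
  } else if ("P" %in% asserted_classes) {
    "P"
  } else if ("LP" %in% asserted_classes) {
    "LP"
  } else {
    "VUS"
  }
  plp_claim <- any(asserted_classes %in% c("P", "LP", "CONFLICTING_WITH_PLP", "DM"))
  list(
    final_class = final,
    downgraded_from_plp = final == "VUS" && plp_claim
  )
}

#' Classify candidates against a curated classification file
#'
#' Applies [reconcile_classification()] across a candidate table and
#' attaches the triage decision from [triage_variant()].
#'
#' @param candidates Tibble from [dedupe_candidates()].
#' @param classifications Optional tibble from [read_classification_file()].
#' @return `candidates` with added columns `final_class`, `curated`,
#'   `downgraded_from_plp`, `triage_path`, `also_lof`.
#' @export
classify_candidates <- function(candidates, classifications = NULL) {
  n <- nrow(candidates)
  curated <- rep(NA_character_, n)
  if (!is.null(classifications) && nrow(classifications)) {
    idx <- match(
      paste(candidates$contig, candidates$pos, candidates$ref, candidates$alt),
      paste(classifications$contig, classifications$pos,
            classifications$ref, classifications$alt)
    )
    curated <- classifications$final_class[idx]
  }
  rec <- lapply(seq_len(n), function(i) {
    reconcile_classification(candidates$asserted_classes[[i]], curated[i])
  })
  out <- candidates
  out$final_class <- vapply(rec, `[[`, character(1), "final_class")
  out$curated <- !is.na(curated)
  out$downgraded_from_plp <- vapply(rec, `[[`, logical(1), "downgraded_from_plp")
  tri <- triage_variant(out$ac_total, out$is_plof)
  out$triage_path <- tri$path
  out$also_lof <- tri$also_lof
  out
}

#' Conservative or relaxed inclusion set
#'
#' The conservative set keeps pathogenic and likely pathogenic variants
#' only. The relaxed set additionally keeps VUSs that entered the candidate
#' list with a P/LP-type claim and were downgraded during curation;
#' database-VUS records never become candidates in the first place. Benign
#' and likely benign variants are always excluded. Input ordering is
#' preserved.
#'
#' @param classified Tibble from [classify_candidates()].
#' @param mode `"conservative"` or `"relaxed"`.
#' @return Filtered tibble.
#' @export
inclusion_set <- function(classified, mode = c("conservative", "relaxed")) {
  mode <- match.arg(mode)
  keep <- classified$final_class %in% c("P", "LP")
  if (mode == "relaxed") {
    keep <- keep | (classified$final_class == "VUS" & classified$downgraded_from_plp)
  }
  classified[keep, ]
}

#' Export a triage queue
#'
#' Orders classified candidates for curation: full ACMG/AMP reviews first,
#' then LoF curations, then abbreviated reviews, each by descending allele
#' count.
#'
#' @param classified Tibble from [classify_candidates()].
#' @param path Optional TSV output path.
#' @return The ordered tibble, invisibly when `path` is given.
#' @export
triage_queue <- function(classified, path = NULL) {
  ord <- order(match(classified$triage_path,
                     c("FULL_ACMG", "LOF_CURATION", "ABBREVIATED")),
               -classified$ac_total)
  out <- classified[ord, c("contig", "pos", "ref", "alt", "hgvs_c",
                           "triage_path", "also_lof", "ac_total", "final_class")]
  if (!is.null(path)) {
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
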