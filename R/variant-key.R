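#' Construct a normalized variant key
#'
#' A variant key is the minimal, left-aligned `(contig, pos, ref, alt)`
#' representation of a variant on a stated genome build. It is the join key
#' used to deduplicate candidates across sources; HGVS strings are carried as
#' provenance metadata only.
#'
#' @param contig Chromosome label (e.g. `"3"` or `"chr3"`).
#' @param pos 1-based position of the first base of `ref`.
#' @param ref,alt Reference and alternate allele strings (A/C/G/T).
#' @param build Genome-build label; defaults to `"GRCh38"`.
#' @return A one-row tibble with columns `contig`, `pos`, `ref`, `alt`,
#'   `build`. Alleles are validated but not normalized; see
#'   [normalize_variant()].
#' @export
#' @examples
#' variant_key("3", 81550000, "A", "C")
variant_key <- function(contig, pos, ref, alt, build = "GRCh38") {
  check_alleles(ref, alt, contig, pos)
  tibble::tibble(
    contig = as.character(contig), pos = as.integer(pos),
    ref = toupper(ref), alt = toupper(alt), build = build
  )
}

check_alleles <- function(ref, alt, contig, pos) {
  id <- paste0(contig, ":", pos, " ", ref, ">", alt)
  if (!grepl("^[ACGTacgt]+$", ref) || !grepl("^[ACGTacgt]+$", alt)) {
    stop("non-ACGT characters in alleles of variant ", id, call. = FALSE)
  }
  if (toupper(ref) == toupper(alt)) {
    stop("ref equals alt for variant ", id, call. = FALSE)
  }
  invisible(TRUE)
}

#' Normalize a variant to its minimal, left-aligned representation
#'
#' Applies the standard VCF normalization: shared suffix and prefix bases are
#' trimmed (keeping a single anchor base for indels) and, when a reference
#' context is supplied, indels are shifted to their leftmost equivalent
#' position. Normalization is idempotent.
#'
#' @param key A variant key as returned by [variant_key()] (or any one-row
#'   data frame with `contig`, `pos`, `ref`, `alt`).
#' @param context Optional reference-context string spanning the variant
#'   locus, used for left alignment. Without it only prefix/suffix trimming
#'   is performed.
#' @param context_start 1-based genomic position of the first base of
#'   `context`.
#' @return A one-row tibble like `key` with normalized `pos`, `ref`, `alt`.
#' @export
#' @examples
#' # right-aligned 1bp deletion in a homopolymer shifts left
#' normalize_variant(variant_key("3", 104, "AA", "A"),
#'                   context = "TTCAAAG", context_start = 100)
normalize_variant <- function(key, context = NULL, context_start = 1L) {
  stopifnot(nrow(key) == 1L)
  pos <- as.integer(key$pos)
  ref <- toupper(key$ref)
  alt <- toupper(key$alt)
  check_alleles(ref, alt, key$contig, pos)

  if (!is.null(context)) {
    context <- toupper(context)
    base_at <- function(p) {
      off <- p - context_start + 1L
      if (off < 1L || off > nchar(context)) {
        stop("left alignment of ", key$contig, ":", pos,
             " walked outside the supplied reference context", call. = FALSE)
      }
      substr(context, off, off)
    }
    if (substr(context, pos - context_start + 1L,
               pos - context_start + nchar(ref)) != ref) {
      stop("ref allele does not match reference context at ",
           key$contig, ":", pos, call. = FALSE)
    }
    # vt-style normalization loop: shrink right / extend left, then trim left
    repeat {
      nr <- nchar(ref); na <- nchar(alt)
      if (nr > 0 && na > 0 &&
          substr(ref, nr, nr) == substr(alt, na, na) &&
          !(nr == 1L && na == 1L)) {
        ref <- substr(ref, 1L, nr - 1L)
        alt <- substr(alt, 1L, na - 1L)
      } else if (nchar(ref) == 0L || nchar(alt) == 0L) {
        pos <- pos - 1L
        b <- base_at(pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      } else {
        break
      }
    }
    while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
    }
  } else {
    # no context: trim only (cannot shift); suffix first, then prefix
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
    }
  }

  if (ref == alt) {
    stop("ref equals alt after normalization for variant at ",
         key$contig, ":", key$pos, call. = FALSE)
  }
  out <- key
  out$pos <- pos
  out$ref <- ref
  out$alt <- alt
  out
}
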