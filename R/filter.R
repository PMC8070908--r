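#' Marker-screening configuration
#'
#' Defaults follow standard BSA-Seq practice for an F2 dominant-trait
#' design: per-bulk total depth of at least 5x, parents (when present)
#' required to be homozygous for different alleles, and the two bulks
#' required to show genotypic inconsistency (different calls, or at least
#' one heterozygous call — a bulk pooling segregating plants is expected to
#' look heterozygous near the locus and away from it alike).
#'
#' @param min_bulk_depth Minimum total read depth per bulk at a site.
#' @param require_parental_polymorphism Require both parents homozygous for
#'   different alleles (skipped automatically when no parent data are
#'   present).
#' @param require_bulk_inconsistency Require bulk genotype calls to differ
#'   or at least one bulk to be heterozygous.
#' @return A list of class `bsa_filter_config`.
#' @export
filter_config <- function(min_bulk_depth = 5L,
                          require_parental_polymorphism = TRUE,
                          require_bulk_inconsistency = TRUE) {
  stopifnot(min_bulk_depth >= 1)
  structure(
    list(
      min_bulk_depth = as.integer(min_bulk_depth),
      require_parental_polymorphism = isTRUE(require_parental_polymorphism),
      require_bulk_inconsistency = isTRUE(require_bulk_inconsistency)
    ),
    class = "bsa_filter_config"
  )
}

#' Screen variants before index computation
#'
#' Applies, in order: (0) sites with missing allele depths in either bulk
#' are rejected (the index is undefined there); (a) total depth in each bulk
#' must reach `min_bulk_depth`; (b) when parent data are present and
#' required, both parents must be homozygous for different alleles; (c) when
#' required, the two bulks' genotype calls must differ or at least one must
#' be heterozygous. Bulk genotypes come from the VCF `GT` field when
#' present, otherwise from an allele-depth majority vote (ties are called
#' heterozygous).
#'
#' @param x A variant tibble (see [read_variants()]).
#' @param config A [filter_config()] object.
#' @return A list with `variants` (the passing records, original order
#'   preserved) and `tally` (tibble `rule`, `n`: records removed by
#'   `missing_bulk_data`, `bulk_depth`, `parental_polymorphism`,
#'   `bulk_consistency`, plus the `passed` count). The tally sums to
#'   `nrow(x)`.
#' @export
filter_variants <- function(x, config = filter_config()) {
  assert_variants(x)
  n0 <- nrow(x)

  missing_bulk <- is.na(x$ad0_al) | is.na(x$ad1_al) |
    is.na(x$ad0_gl) | is.na(x$ad1_gl)
  n_missing <- sum(missing_bulk)
  x <- x[!missing_bulk, , drop = FALSE]

  dp_al <- x$ad0_al + x$ad1_al
  dp_gl <- x$ad0_gl + x$ad1_gl
  low <- dp_al < config$min_bulk_depth | dp_gl < config$min_bulk_depth
  n_depth <- sum(low)
  x <- x[!low, , drop = FALSE]

  parents_present <- any(!is.na(x$gt_hairy)) || any(!is.na(x$gt_glab))
  n_parental <- 0L
  if (config$require_parental_polymorphism && parents_present && nrow(x) > 0) {
    poly <- gt_is_hom(x$gt_hairy) & gt_is_hom(x$gt_glab) &
      x$gt_hairy != x$gt_glab
    poly[is.na(poly)] <- FALSE
    n_parental <- sum(!poly)
    x <- x[poly, , drop = FALSE]
  }

  n_consist <- 0L
  if (config$require_bulk_inconsistency && nrow(x) > 0) {
    gt_al <- effective_gt(x$gt_al, x$ad0_al, x$ad1_al)
    gt_gl <- effective_gt(x$gt_gl, x$ad0_gl, x$ad1_gl)
    inconsistent <- gt_al != gt_gl | gt_al == "0/1" | gt_gl == "0/1"
    inconsistent[is.na(inconsistent)] <- FALSE
    n_consist <- sum(!inconsistent)
    x <- x[inconsistent, , drop = FALSE]
  }

  tally <- tibble(
    rule = c(
      "missing_bulk_data", "bulk_depth", "parental_polymorphism",
      "bulk_consistency", "passed"
    ),
    n = c(n_missing, n_depth, n_parental, n_consist, nrow(x))
  )
  stopifnot(sum(tally$n) == n0)
  list(variants = x, tally = tally)
}
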