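#' Determine the hairy-parent allele at each site
#'
#' The SNP-index is oriented to the allele carried by the hairy (dominant,
#' W30-like) parent. When the hairy parent has a homozygous call, that call
#' decides the orientation (`1/1` -> alt, `0/0` -> ref). Sites where the
#' hairy parent is heterozygous are unorientable and flagged `NA` (they are
#' dropped, and counted, by [compute_indices()]). When no hairy-parent
#' genotype is available, the fallback policy applies.
#'
#' @param x A variant tibble (see [read_variants()]).
#' @param fallback What to do without a hairy-parent genotype: `"alt"`
#'   orients to the alternate allele (the convention for bulk-only calls
#'   against a reference that matches the recessive parent); `"error"`
#'   aborts.
#' @return Integer vector, one per record: `1` (alt is the hairy allele),
#'   `0` (ref), or `NA` (unorientable heterozygous parent).
#' @export
orient_hairy_allele <- function(x, fallback = c("alt", "error")) {
  assert_variants(x)
  fallback <- match.arg(fallback)
  code <- gt_code(x$gt_hairy)
  out <- rep(NA_integer_, nrow(x))
  out[!is.na(code) & code == 2L] <- 1L
  out[!is.na(code) & code == 0L] <- 0L
  no_call <- is.na(x$gt_hairy)
  if (any(no_call)) {
    if (fallback == "error") {
      abort("hairy-parent genotype missing and fallback = 'error'")
    }
    out[no_call] <- 1L
  }
  out
}

#' Compute per-bulk SNP-indices and the delta(SNP-index)
#'
#' For each (filtered) site the bulk SNP-index is the fraction of that
#' bulk's reads supporting the hairy-parent allele, and
#' `delta = index_AL - index_GL`, so linkage to the hairy allele drives
#' delta positive. The identical formula applied to indel-class records is
#' the indel-index; records keep their `class` so the two streams can be
#' scanned separately.
#'
#' @inheritParams orient_hairy_allele
#' @return A list with `index` — a tibble of `chrom`, `pos`, `class`,
#'   `hairy_allele`, `index_AL`, `index_GL`, `delta`, `depth_AL`,
#'   `depth_GL` — and `n_unorientable`, the count of sites dropped because
#'   the hairy parent was heterozygous.
#' @export
compute_indices <- function(x, fallback = c("alt", "error")) {
  assert_variants(x)
  ori <- orient_hairy_allele(x, fallback)
  n_unorientable <- sum(is.na(ori))
  keep <- !is.na(ori)
  x <- x[keep, , drop = FALSE]
  ori <- ori[keep]

  depth_al <- x$ad0_al + x$ad1_al
  depth_gl <- x$ad0_gl + x$ad1_gl
  if (any(is.na(depth_al) | is.na(depth_gl) | depth_al == 0 | depth_gl == 0)) {
    abort("zero or missing bulk depth: records must pass filter_variants() first")
  }
  hairy_al <- ifelse(ori == 1L, x$ad1_al, x$ad0_al)
  hairy_gl <- ifelse(ori == 1L, x$ad1_gl, x$ad0_gl)
  index_al <- hairy_al / depth_al
  index_gl <- hairy_gl / depth_gl

  list(
    index = tibble(
      chrom = x$chrom, pos = x$pos, class = x$class,
      hairy_allele = ori,
      index_AL = index_al, index_GL = index_gl,
      delta = index_al - index_gl,
      depth_AL = as.integer(depth_al), depth_GL = as.integer(depth_gl)
    ),
    n_unorientable = n_unorientable
  )
}
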