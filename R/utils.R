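# Internal helpers shared across modules.

# Canonical sample roles at the pipeline boundary. Parents are optional
# (bulk-only variant calls are supported); bulks are mandatory.
bsa_roles <- function() {
  c("parent_hairy", "parent_glabrous", "bulk_AL", "bulk_GL")
}

# role -> column suffix used in the variant tibble
role_suffix <- c(
  parent_hairy    = "hairy",
  parent_glabrous = "glab",
  bulk_AL         = "al",
  bulk_GL         = "gl"
)

variant_cols <- function() {
  c(
    "chrom", "pos", "ref", "alt", "class",
    as.vector(outer(c("gt_", "ad0_", "ad1_"), role_suffix, paste0))
  )
}

assert_variants <- function(x, arg = "variants") {
  missing <- setdiff(variant_cols(), names(x))
  if (length(missing) > 0) {
    abort(paste0(
      "`", arg, "` is not a variant table: missing column(s) ",
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(x)
}

# "0/0" -> 0, "0/1"/"1/0" -> 1, "1/1" -> 2, anything else -> NA
gt_code <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  out
}

gt_is_hom <- function(gt) {
  code <- gt_code(gt)
  !is.na(code) & code != 1L
}

# Majority-vote genotype from ref/alt depths; ties are called heterozygous.
infer_gt_from_ad <- function(ad0, ad1) {
  out <- rep(NA_character_, length(ad0))
  ok <- !is.na(ad0) & !is.na(ad1) & (ad0 + ad1) > 0
  out[ok & ad1 > ad0] <- "1/1"
  out[ok & ad1 < ad0] <- "0/0"
  out[ok & ad1 == ad0] <- "0/1"
  out
}

# Bulk genotype used by the inconsistency screen: VCF GT when present,
# otherwise inferred from allele depths.
effective_gt <- function(gt, ad0, ad1) {
  ifelse(is.na(gt), infer_gt_from_ad(ad0, ad1), gt)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
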