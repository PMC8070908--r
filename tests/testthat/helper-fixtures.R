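# Fixtures are built in code at test time; nothing binary is stored.

toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=A01,length=25000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "W30", "082", "AL", "GL"), collapse = "\t"),
    paste(c("A01", "300", ".", "AT", "A", ".", "PASS", ".", "GT:AD:DP",
      "0/0:27,0:27", "1/1:0,26:26", "0/1:40,38:78", "1/1:2,74:76"),
      collapse = "\t"),
    paste(c("A01", "100", ".", "A", "G", ".", "PASS", ".", "GT:AD:DP",
      "1/1:0,27:27", "0/0:26,0:26", "0/1:30,48:78", "0/0:70,6:76"),
      collapse = "\t"),
    paste(c("A01", "200", ".", "C", "T,G", ".", "PASS", ".", "GT:AD:DP",
      "1/1:0,27,0:27", "0/0:26,0,0:26", "0/1:30,40,8:78", "./.:.:."),
      collapse = "\t")
  ), path)
  path
}

toy_roles <- c(
  parent_hairy = "W30", parent_glabrous = "082",
  bulk_AL = "AL", bulk_GL = "GL"
)

toy_gff <- function(path = tempfile(fileext = ".gff3"),
                    lines = c(
                      "A01\ttoy\tgene\t100\t200\t.\t+\t.\tID=Bra000001",
                      "A01\ttoy\tgene\t500\t900\t.\t-\t.\tID=Bra000002"
                    )) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# One biallelic variant row with overridable fields.
vrow <- function(chrom = "A01", pos = 100L, ref = "A", alt = "G",
                 class = "snp",
                 gt_hairy = "1/1", ad_hairy = c(0L, 27L),
                 gt_glab = "0/0", ad_glab = c(26L, 0L),
                 gt_al = "0/1", ad_al = c(30L, 48L),
                 gt_gl = "0/0", ad_gl = c(70L, 6L)) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, class = class,
    gt_hairy = gt_hairy, ad0_hairy = ad_hairy[1], ad1_hairy = ad_hairy[2],
    gt_glab = gt_glab, ad0_glab = ad_glab[1], ad1_glab = ad_glab[2],
    gt_al = gt_al, ad0_al = ad_al[1], ad1_al = ad_al[2],
    gt_gl = gt_gl, ad0_gl = ad_gl[1], ad1_gl = ad_gl[2]
  )
}

# Minimal per-site index table for scan tests; regular spacing keeps window
# midpoints equal to the mean member position.
index_tbl <- function(delta, chrom = "A01", spacing = 1000L,
                      pos = spacing * seq_along(delta)) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), class = "snp",
    hairy_allele = 1L, index_AL = NA_real_, index_GL = NA_real_,
    delta = delta, depth_AL = 50L, depth_GL = 50L
  )
}

# Down-scaled simulated cross for fast unit tests.
small_sim_config <- function(seed = NULL, ...) {
  sim_config(
    genome = tibble::tibble(
      name = c("A01", "A02", "Scaffold01"),
      length_bp = c(5e6, 5e6, 5e5),
      length_cM = c(50, 50, 2)
    ),
    n_markers_per_chrom = 60L,
    causal = list(chrom = "A01", pos = 2500000L),
    n_f2 = 80L, bulk_size = 15L,
    mean_depth_AL = 40, mean_depth_GL = 40,
    parent_depth_hairy = 25, parent_depth_glab = 25,
    seed = seed,
    ...
  )
}
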