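test_that("zero genetic length yields unbroken parental haplotypes", {
  cfg <- sim_config(
    genome = tibble::tibble(name = "A01", length_bp = 1e6, length_cM = 0),
    n_markers_per_chrom = 30L, causal = list(chrom = "A01", pos = 5e5),
    n_f2 = 40L, bulk_size = 8L, seed = 1L
  )
  set.seed(1)
  f2 <- simulate_f2(cfg)
  # without recombination every individual is constant across markers
  per_ind_range <- apply(f2$geno, 1, function(g) max(g) - min(g))
  expect_true(all(per_ind_range == 0))
})

test_that("hairy counts match the Binomial(n, 3/4) law across seeds", {
  # oracle: central 99% binomial interval
  n <- 294L
  lo <- qbinom(0.005, n, 0.75)
  hi <- qbinom(0.995, n, 0.75)
  cfg <- sim_config(
    genome = tibble::tibble(name = "A01", length_bp = 1e6, length_cM = 10),
    n_markers_per_chrom = 5L, causal = list(chrom = "A01", pos = 5e5),
    n_f2 = n, bulk_size = 50L
  )
  inside <- 0L
  for (seed in seq_len(200L)) {
    set.seed(seed)
    counts <- simulate_f2(cfg)$counts
    expect_equal(sum(counts), n)
    inside <- inside + (counts[["n_hairy"]] >= lo && counts[["n_hairy"]] <= hi)
  }
  # ~2 of 200 runs are expected outside a 99% interval
  expect_gte(inside, 192L)
})

test_that("bulk allele frequencies follow the dominant-locus expectations", {
  # Mendelian oracle, by enumeration: F2 genotypes AA:Aa:aa = 1:2:1; among
  # dominant-phenotype plants P(AA)=1/3, P(Aa)=2/3, so the hairy-bulk W30
  # allele frequency at a fully linked marker is (2*1/3 + 1*2/3)/2 = 2/3;
  # the glabrous bulk is all aa, frequency 0.
  p_geno <- c(AA = 1 / 4, Aa = 1 / 2, aa = 1 / 4)
  p_given_dom <- p_geno[c("AA", "Aa")] / sum(p_geno[c("AA", "Aa")])
  f_oracle <- sum(p_given_dom * c(2, 1)) / 2
  expect_equal(f_oracle, 2 / 3)

  cfg <- sim_config(
    genome = tibble::tibble(
      name = c("A01", "A02"), length_bp = c(1e6, 1e6), length_cM = c(10, 10)
    ),
    n_markers_per_chrom = 6L, causal = list(chrom = "A01", pos = 5e5),
    n_f2 = 294L, bulk_size = 50L,
    mean_depth_AL = 2000, mean_depth_GL = 2000, error_rate = 0
  )
  f_al_causal <- f_gl_causal <- idx_al_causal <- numeric(40)
  f_al_unlinked <- numeric(40)
  for (seed in seq_len(40L)) {
    cfg$seed <- seed
    sim <- simulate_bsa(cfg)
    cz <- sim$truth$is_causal
    f_al_causal[seed] <- sim$truth$f_AL[cz]
    f_gl_causal[seed] <- sim$truth$f_GL[cz]
    v <- sim$variants[cz, ]
    hairy_reads <- ifelse(v$gt_hairy == "1/1", v$ad1_al, v$ad0_al)
    idx_al_causal[seed] <- hairy_reads / (v$ad0_al + v$ad1_al)
    un <- sim$truth$chrom == "A02"
    f_al_unlinked[seed] <- mean(sim$truth$f_AL[un])
  }
  # glabrous plants are homozygous recessive: exactly zero, every run
  expect_true(all(f_gl_causal == 0))
  expect_lt(abs(mean(f_al_causal) - 2 / 3), 0.02)
  # at high depth the read-level index tracks the bulk frequency
  expect_lt(abs(mean(idx_al_causal) - 2 / 3), 0.02)
  # unlinked markers sit at 1/2 by symmetry
  expect_lt(abs(mean(f_al_unlinked) - 0.5), 0.02)
})

test_that("error-free reads from a fixed parent all carry its allele", {
  cfg <- small_sim_config(seed = 3L)
  cfg$error_rate <- 0
  sim <- simulate_bsa(cfg)
  v <- sim$variants
  hairy_parent_other <- ifelse(v$gt_hairy == "1/1", v$ad0_hairy, v$ad1_hairy)
  expect_true(all(hairy_parent_other == 0))
  glab_parent_other <- ifelse(v$gt_glab == "1/1", v$ad0_glab, v$ad1_glab)
  expect_true(all(glab_parent_other == 0))
})

test_that("invalid designs are rejected with informative errors", {
  expect_error(
    sim_config(n_f2 = 100L, bulk_size = 50L),
    "recessive phenotype class"
  )
  cfg <- small_sim_config()
  cfg$causal <- NULL
  set.seed(1)
  expect_error(simulate_f2(cfg), "no causal locus")

  # too few individuals in a phenotype class
  cfg2 <- small_sim_config(seed = 5L)
  set.seed(5)
  f2 <- simulate_f2(cfg2)
  f2$phenotype[f2$phenotype == "glabrous"] <- "hairy"
  f2$phenotype[1] <- "glabrous"
  expect_error(sample_bulk_reads(f2, cfg2), "glabrous")
})

test_that("simulated bundles are deterministic under the seed and read back", {
  dir1 <- tempfile()
  dir2 <- tempfile()
  dir3 <- tempfile()
  sim_a <- simulate_bsa(small_sim_config(seed = 11L))
  p1 <- write_sim_bundle(sim_a, dir1)
  sim_b <- simulate_bsa(small_sim_config(seed = 11L))
  p2 <- write_sim_bundle(sim_b, dir2)
  sim_c <- simulate_bsa(small_sim_config(seed = 12L))
  p3 <- write_sim_bundle(sim_c, dir3)

  expect_equal(unname(tools::md5sum(p1[["vcf"]])), unname(tools::md5sum(p2[["vcf"]])))
  expect_false(tools::md5sum(p1[["vcf"]]) == tools::md5sum(p3[["vcf"]]))

  back <- read_variants(p1[["vcf"]], toy_roles)
  orig <- dplyr::arrange(sim_a$variants, chrom, pos, alt)
  expect_equal(back$pos, orig$pos)
  expect_equal(back$class, orig$class)
  expect_equal(back$ad1_al, orig$ad1_al)
  expect_equal(back$gt_hairy, orig$gt_hairy)

  genes <- read_genes(p1[["gff3"]])
  expect_gt(nrow(genes), 0)
  truth <- readr::read_tsv(p1[["truth"]], show_col_types = FALSE)
  expect_true(all(truth$f_AL >= 0 & truth$f_AL <= 1))
  expect_equal(sum(truth$is_causal), 1L)
})
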