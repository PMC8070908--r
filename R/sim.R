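#' Configuration for a synthetic BSA-Seq experiment
#'
#' The defaults reproduce the design of the Chinese cabbage leaf-trichome
#' mapping experiment the package is built around: an F2 of 294 plants
#' segregating 3:1 for a single dominant locus, phenotype bulks of 50 plants
#' each, bulk sequencing depths of ~78.9x (AL) and ~76.2x (GL) and parental
#' depths of ~27.5x / ~26.8x. The default genome mimics a draft assembly:
#' three 25-Mb chromosomes (100 cM each) plus two 1-Mb scaffolds (4 cM),
#' with 400 markers per sequence (2,000 total).
#'
#' @param genome A tibble/data.frame with columns `name`, `length_bp`,
#'   `length_cM` describing the simulated sequences.
#' @param n_markers_per_chrom Number of polymorphic markers drawn uniformly
#'   on each sequence.
#' @param causal List with `chrom` and `pos` (bp) of the causal locus, or
#'   `NULL` for a neutral genome (phenotypes then cannot be assigned).
#' @param inheritance Trait model; only `"dominant_hairy"` (one dominant
#'   allele from the hairy parent) is implemented.
#' @param n_f2 Number of F2 individuals.
#' @param bulk_size Plants per phenotype bulk.
#' @param mean_depth_AL,mean_depth_GL Mean Poisson sequencing depth per bulk.
#' @param parent_depth_hairy,parent_depth_glab Mean Poisson depth for the
#'   two parental resequencing samples.
#' @param error_rate Per-read probability that a read reports the other
#'   allele (symmetric two-allele miscall model).
#' @param indel_fraction Fraction of markers simulated as 1-bp insertions
#'   rather than SNPs (the causal marker is always a SNP).
#' @param seed Integer seed consumed by [simulate_bsa()]; `NULL` leaves the
#'   RNG state alone.
#' @return A list of class `bsa_sim_config`.
#' @export
sim_config <- function(genome = default_sim_genome(),
                       n_markers_per_chrom = 400L,
                       causal = list(chrom = "A02", pos = 12500000L),
                       inheritance = "dominant_hairy",
                       n_f2 = 294L,
                       bulk_size = 50L,
                       mean_depth_AL = 78.9,
                       mean_depth_GL = 76.2,
                       parent_depth_hairy = 27.5,
                       parent_depth_glab = 26.8,
                       error_rate = 0.001,
                       indel_fraction = 0.05,
                       seed = NULL) {
  genome <- as_tibble(genome)
  stopifnot(
    all(c("name", "length_bp", "length_cM") %in% names(genome)),
    n_markers_per_chrom >= 1, n_f2 >= 4, bulk_size >= 1,
    mean_depth_AL > 0, mean_depth_GL > 0,
    parent_depth_hairy > 0, parent_depth_glab > 0,
    error_rate >= 0, error_rate < 0.5,
    indel_fraction >= 0, indel_fraction < 1
  )
  inheritance <- match.arg(inheritance, "dominant_hairy")
  if (!is.null(causal)) {
    i <- match(causal$chrom, genome$name)
    if (is.na(i)) {
      abort(paste0("causal chromosome '", causal$chrom, "' not in genome"))
    }
    if (causal$pos < 1 || causal$pos > genome$length_bp[i]) {
      abort("causal position outside its chromosome")
    }
  }
  # under a 3:1 segregation the recessive class is the limiting one
  if (bulk_size > floor(n_f2 / 4)) {
    abort("bulk_size exceeds the expected size of the recessive phenotype class")
  }
  structure(
    list(
      genome = genome, n_markers_per_chrom = as.integer(n_markers_per_chrom),
      causal = causal, inheritance = inheritance, n_f2 = as.integer(n_f2),
      bulk_size = as.integer(bulk_size),
      mean_depth_AL = mean_depth_AL, mean_depth_GL = mean_depth_GL,
      parent_depth_hairy = parent_depth_hairy,
      parent_depth_glab = parent_depth_glab,
      error_rate = error_rate, indel_fraction = indel_fraction,
      seed = seed
    ),
    class = "bsa_sim_config"
  )
}

#' @rdname sim_config
#' @export
default_sim_genome <- function() {
  tibble(
    name = c("A01", "A02", "A03", "Scaffold000100", "Scaffold000200"),
    length_bp = c(25e6, 25e6, 25e6, 1e6, 1e6),
    length_cM = c(100, 100, 100, 4, 4)
  )
}

#' Simulate F2 genotypes from a biparental cross
#'
#' Each F2 individual receives, per chromosome, two gametes from
#' heterozygous F1 parents. Crossovers per gamete are Poisson-distributed
#' with mean `length_cM / 100` (Haldane model, no interference) and placed
#' uniformly on the genetic map; marker genetic positions are proportional
#' to their physical positions. Phenotypes follow the dominant single-gene
#' model: hairy iff the individual carries at least one hairy-parent (W30)
#' allele at the causal locus, so the expected hairy fraction is 0.75.
#'
#' @param config A [sim_config()] object.
#' @param markers Optional marker table (as produced internally); drawn
#'   from `config` when `NULL`.
#' @return A list with `markers` (tibble: `chrom`, `pos`, `cM`, `class`,
#'   `hairy_is_alt`, `ref`, `alt`, `is_causal`), `geno` (integer matrix,
#'   individuals x markers, counting hairy-parent alleles 0/1/2),
#'   `phenotype` (character, `"hairy"`/`"glabrous"`), and `counts`
#'   (named vector `n_hairy`, `n_glabrous`).
#' @export
simulate_f2 <- function(config, markers = NULL) {
  stopifnot(inherits(config, "bsa_sim_config"))
  if (is.null(markers)) {
    markers <- draw_markers(config)
  }
  g <- config$genome
  n <- config$n_f2
  geno <- matrix(0L, nrow = n, ncol = nrow(markers))
  for (ci in seq_len(nrow(g))) {
    idx <- which(markers$chrom == g$name[ci])
    if (length(idx) == 0) next
    cm <- markers$cM[idx]
    L <- g$length_cM[ci]
    chrom_geno <- matrix(0L, nrow = n, ncol = length(idx))
    for (i in seq_len(n)) {
      chrom_geno[i, ] <- sim_gamete(cm, L) + sim_gamete(cm, L)
    }
    geno[, idx] <- chrom_geno
  }

  if (is.null(config$causal)) {
    abort("cannot assign phenotypes: no causal locus configured")
  }
  causal_idx <- which(markers$is_causal)
  phenotype <- ifelse(geno[, causal_idx] >= 1L, "hairy", "glabrous")
  counts <- c(
    n_hairy = sum(phenotype == "hairy"),
    n_glabrous = sum(phenotype == "glabrous")
  )
  list(markers = markers, geno = geno, phenotype = phenotype, counts = counts)
}

# One gamete from a heterozygous F1: 0/1 per marker (1 = hairy-parent allele).
sim_gamete <- function(cm, length_cM) {
  start <- rbinom(1L, 1L, 0.5)
  n_xo <- rpois(1L, length_cM / 100)
  if (n_xo == 0L) {
    return(rep(start, length(cm)))
  }
  xo <- sort(runif(n_xo, 0, length_cM))
  (start + findInterval(cm, xo)) %% 2L
}

draw_markers <- function(config) {
  g <- config$genome
  pieces <- lapply(seq_len(nrow(g)), function(ci) {
    pos <- sort(sample.int(g$length_bp[ci], config$n_markers_per_chrom))
    tibble(chrom = g$name[ci], pos = as.integer(pos))
  })
  mk <- bind_rows(pieces)
  mk$is_causal <- FALSE
  if (!is.null(config$causal)) {
    hit <- mk$chrom == config$causal$chrom & mk$pos == config$causal$pos
    if (!any(hit)) {
      mk <- bind_rows(mk, tibble(
        chrom = config$causal$chrom,
        pos = as.integer(config$causal$pos), is_causal = TRUE
      ))
    } else {
      mk$is_causal[hit] <- TRUE
    }
  }
  mk <- arrange(mk, .data$chrom, .data$pos)
  mk <- mk[!duplicated(mk[, c("chrom", "pos")]), ]
  gi <- match(mk$chrom, g$name)
  mk$cM <- mk$pos / g$length_bp[gi] * g$length_cM[gi]
  n <- nrow(mk)
  mk$class <- ifelse(runif(n) < config$indel_fraction, "indel", "snp")
  mk$class[mk$is_causal] <- "snp"
  mk$hairy_is_alt <- runif(n) < 0.5
  bases <- c("A", "C", "G", "T")
  mk$ref <- sample(bases, n, replace = TRUE)
  mk$alt <- vapply(mk$ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  ins <- mk$class == "indel"
  mk$alt[ins] <- paste0(mk$ref[ins], sample(bases, sum(ins), replace = TRUE))
  mk[, c("chrom", "pos", "cM", "class", "hairy_is_alt", "ref", "alt", "is_causal")]
}

#' Sample pooled sequencing reads for the two bulks and parents
#'
#' Draws `bulk_size` individuals from each phenotype class, computes the
#' true hairy-parent allele frequency per marker in each bulk
#' (`f = hairy alleles / (2 * bulk_size)`), then samples a total depth
#' `Poisson(mean_depth)` and hairy-allele-supporting reads
#' `Binomial(depth, f(1 - e) + (1 - f)e)` per marker and bulk. Parents are
#' written homozygous-opposite at every marker with depth
#' `Poisson(parent_depth)`. Bulk genotype calls emulate a diploid caller on
#' the pool: alt-read fraction < 0.25 is `0/0`, > 0.75 is `1/1`, else `0/1`.
#'
#' @param f2 Output of [simulate_f2()].
#' @param config The [sim_config()] used.
#' @return A list with `variants` (tibble as from [read_variants()]) and
#'   `truth` (tibble `chrom`, `pos`, `is_causal`, `f_AL`, `f_GL`, with the
#'   phenotype counts as attribute `counts`).
#' @export
sample_bulk_reads <- function(f2, config) {
  mk <- f2$markers
  for (class_ in c("hairy", "glabrous")) {
    n_class <- sum(f2$phenotype == class_)
    if (n_class < config$bulk_size) {
      abort(paste0(
        "phenotype class '", class_, "' has only ", n_class,
        " individuals; bulk_size = ", config$bulk_size
      ))
    }
  }
  al_idx <- sample(which(f2$phenotype == "hairy"), config$bulk_size)
  gl_idx <- sample(which(f2$phenotype == "glabrous"), config$bulk_size)
  two_n <- 2 * config$bulk_size
  f_al <- colSums(f2$geno[al_idx, , drop = FALSE]) / two_n
  f_gl <- colSums(f2$geno[gl_idx, , drop = FALSE]) / two_n

  e <- config$error_rate
  n <- nrow(mk)
  draw_pool <- function(f, mean_depth) {
    depth <- rpois(n, mean_depth)
    hairy <- rbinom(n, depth, f * (1 - e) + (1 - f) * e)
    list(depth = depth, hairy = hairy)
  }
  al <- draw_pool(f_al, config$mean_depth_AL)
  gl <- draw_pool(f_gl, config$mean_depth_GL)
  ph <- draw_pool(rep(1, n), config$parent_depth_hairy)
  pg <- draw_pool(rep(0, n), config$parent_depth_glab)

  # hairy-parent allele -> ref/alt orientation per marker
  to_ref_alt <- function(pool) {
    ad1 <- ifelse(mk$hairy_is_alt, pool$hairy, pool$depth - pool$hairy)
    list(ad0 = as.integer(pool$depth - ad1), ad1 = as.integer(ad1))
  }
  al_ad <- to_ref_alt(al)
  gl_ad <- to_ref_alt(gl)
  ph_ad <- to_ref_alt(ph)
  pg_ad <- to_ref_alt(pg)

  caller_gt <- function(ad0, ad1) {
    dp <- ad0 + ad1
    frac <- ifelse(dp > 0, ad1 / dp, NA_real_)
    out <- rep(NA_character_, length(dp))
    out[!is.na(frac) & frac < 0.25] <- "0/0"
    out[!is.na(frac) & frac > 0.75] <- "1/1"
    out[!is.na(frac) & frac >= 0.25 & frac <= 0.75] <- "0/1"
    out
  }

  variants <- tibble(
    chrom = mk$chrom, pos = mk$pos, ref = mk$ref, alt = mk$alt,
    class = mk$class,
    gt_hairy = ifelse(mk$hairy_is_alt, "1/1", "0/0"),
    ad0_hairy = ph_ad$ad0, ad1_hairy = ph_ad$ad1,
    gt_glab = ifelse(mk$hairy_is_alt, "0/0", "1/1"),
    ad0_glab = pg_ad$ad0, ad1_glab = pg_ad$ad1,
    gt_al = caller_gt(al_ad$ad0, al_ad$ad1),
    ad0_al = al_ad$ad0, ad1_al = al_ad$ad1,
    gt_gl = caller_gt(gl_ad$ad0, gl_ad$ad1),
    ad0_gl = gl_ad$ad0, ad1_gl = gl_ad$ad1
  )
  truth <- tibble(
    chrom = mk$chrom, pos = mk$pos, is_causal = mk$is_causal,
    f_AL = f_al, f_GL = f_gl
  )
  attr(truth, "counts") <- f2$counts
  list(variants = variants, truth = truth)
}

#' Simulate a complete BSA-Seq experiment
#'
#' One-stop generator: seeds the RNG (when `config$seed` is set), simulates
#' the F2 ([simulate_f2()]) and the pooled reads ([sample_bulk_reads()]).
#'
#' @param config A [sim_config()] object.
#' @return A list with `variants`, `truth`, `f2` and `config`.
#' @export
simulate_bsa <- function(config = sim_config()) {
  if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  f2 <- simulate_f2(config)
  reads <- sample_bulk_reads(f2, config)
  list(
    variants = reads$variants, truth = reads$truth, f2 = f2,
    config = config
  )
}

#' Write a simulated experiment to standard files
#'
#' Emits a VCF 4.2 (samples W30, 082, AL, GL), a GFF3 of uniformly tiled
#' gene models, and a truth TSV (`chrom`, `pos`, `is_causal`, `f_AL`,
#' `f_GL`) into a directory.
#'
#' @param sim Output of [simulate_bsa()].
#' @param dir Output directory (created if needed).
#' @param gene_every,gene_width Tiling of synthetic gene models: one gene
#'   starts every `gene_every` bp, of width `gene_width` bp.
#' @return Named character vector of the written paths (`vcf`, `gff3`,
#'   `truth`), invisibly.
#' @export
write_sim_bundle <- function(sim, dir, gene_every = 20000L, gene_width = 15000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "sim.vcf"),
    gff3 = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.tsv")
  )
  contigs <- setNames(
    as.integer(sim$config$genome$length_bp),
    sim$config$genome$name
  )
  write_vcf(sim$variants, paths[["vcf"]], contigs = contigs)
  write_tiled_genes(sim$config$genome, paths[["gff3"]], gene_every, gene_width)
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}

# Uniform synthetic gene models along each simulated sequence.
write_tiled_genes <- function(genome, path, gene_every, gene_width) {
  rows <- character(0)
  counter <- 0L
  for (ci in seq_len(nrow(genome))) {
    starts <- seq(1L, as.integer(genome$length_bp[ci]) - gene_width,
      by = gene_every
    )
    ids <- sprintf("BraSim%06d", counter + seq_along(starts))
    counter <- counter + length(starts)
    rows <- c(rows, paste(
      genome$name[ci], "bsaseqr_sim", "gene",
      starts, starts + gene_width - 1L, ".",
      rep_len(c("+", "-"), length(starts)), ".",
      paste0("ID=", ids),
      sep = "\t"
    ))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
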