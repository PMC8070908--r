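#' Run the complete BSA-Seq analysis end-to-end
#'
#' Orchestrates the pipeline: (optionally) simulate an experiment, read the
#' VCF and gene models, screen markers, compute per-site indices, scan SNP
#' and indel streams separately (windows, LOESS, threshold, regions),
#' annotate regions with genes and GO terms, and write all result tables
#' plus a run manifest into `out_dir`. Identical inputs, parameters and
#' seed give byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param vcf,gff3,go_map Input paths: VCF with `GT`/`AD` for the four
#'   samples, GFF3 gene models, optional gene-to-GO TSV. Ignored when `sim`
#'   is given (the simulated bundle is used instead).
#' @param sample_roles Role-to-sample mapping for the VCF (see
#'   [read_variants()]).
#' @param sim Optional [sim_config()]; when supplied, a synthetic bundle is
#'   written under `out_dir/sim/` and analysed.
#' @param filter A [filter_config()].
#' @param scan A [scan_config()].
#' @param seed Integer seed for the stochastic stages (the simulator);
#'   overrides `sim$seed` when both are given.
#' @return Invisibly, a list with `index`, `windows`, `threshold`,
#'   `regions` (per stream), `region_genes`, `go`, `manifest`, and the
#'   output paths.
#' @export
run_pipeline <- function(out_dir,
                         vcf = NULL, gff3 = NULL, go_map = NULL,
                         sample_roles = c(
                           parent_hairy = "W30", parent_glabrous = "082",
                           bulk_AL = "AL", bulk_GL = "GL"
                         ),
                         sim = NULL,
                         filter = filter_config(),
                         scan = scan_config(),
                         seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  if (!is.null(sim)) {
    if (!is.null(seed)) {
      sim$seed <- as.integer(seed)
    }
    bundle <- stage("simulate", {
      s <- simulate_bsa(sim)
      write_sim_bundle(s, file.path(out_dir, "sim"))
    })
    vcf <- bundle[["vcf"]]
    gff3 <- bundle[["gff3"]]
  }
  if (is.null(vcf)) {
    abort("either `vcf` or `sim` must be supplied")
  }

  variants <- stage("read_variants", read_variants(vcf, sample_roles))
  genes <- if (!is.null(gff3)) stage("read_genes", read_genes(gff3)) else NULL
  gomap <- if (!is.null(go_map)) stage("read_go_map", read_go_map(go_map)) else NULL

  streams <- list(
    snp = variants[variants$class == "snp", , drop = FALSE],
    indel = variants[variants$class == "indel", , drop = FALSE]
  )

  results <- lapply(names(streams), function(cls) {
    v <- streams[[cls]]
    filt <- stage(paste0("filter_", cls), filter_variants(v, filter))
    idx <- stage(paste0("index_", cls), compute_indices(filt$variants))
    sc <- stage(paste0("scan_", cls), scan_deltas(idx$index, scan, source = cls))
    list(filter = filt, index = idx, scan = sc)
  })
  names(results) <- names(streams)

  all_regions <- bind_rows(lapply(results, function(r) r$scan$regions))
  annot <- NULL
  go <- NULL
  if (!is.null(genes) && nrow(all_regions) > 0) {
    annot <- stage("annotate", genes_in_regions(all_regions, genes))
    all_regions <- annot$regions
    if (!is.null(gomap)) {
      go <- stage("tally_go", tally_go(unique(annot$region_genes$gene_id), gomap))
    }
  }

  # ---- write tables -------------------------------------------------------
  paths <- list()
  for (cls in names(results)) {
    r <- results[[cls]]
    paths[[paste0("filter_tally_", cls)]] <-
      write_tsv_out(r$filter$tally, out_dir, paste0("filter_tally_", cls, ".tsv"))
    paths[[paste0("index_", cls)]] <-
      write_tsv_out(r$index$index, out_dir, paste0("index_", cls, ".tsv"))
    paths[[paste0("windows_", cls)]] <-
      write_tsv_out(
        r$scan$windows[, c(
          "chrom", "midpoint", "start", "end", "n_sites",
          "mean_delta", "smoothed_delta"
        )],
        out_dir, paste0("windows_", cls, ".tsv")
      )
    regs <- all_regions[all_regions$source == cls, , drop = FALSE]
    paths[[paste0("regions_", cls)]] <- file.path(out_dir, paste0("regions_", cls, ".tsv"))
    write_regions(regs, paths[[paste0("regions_", cls)]])
  }
  if (!is.null(annot)) {
    paths$region_genes <- write_tsv_out(annot$region_genes, out_dir, "region_genes.tsv")
  }
  if (!is.null(go)) {
    paths$go_tally <- write_tsv_out(go$tally, out_dir, "go_tally.tsv")
    paths$unannotated <- file.path(out_dir, "unannotated_genes.txt")
    writeLines(go$unannotated, paths$unannotated)
  }

  manifest <- list(
    tool = "bsaseqr",
    version = as.character(utils::packageVersion("bsaseqr")),
    seed = if (!is.null(sim)) sim$seed else seed,
    threshold_mode = scan$threshold_mode,
    thresholds = lapply(results, function(r) r$scan$threshold),
    params = list(
      filter = unclass(filter), scan = unclass(scan)
    ),
    inputs = lapply(
      Filter(Negate(is.null), list(vcf = vcf, gff3 = gff3, go_map = go_map)),
      function(p) unname(tools::md5sum(p))
    ),
    counts = lapply(names(results), function(cls) {
      r <- results[[cls]]
      list(
        input = sum(r$filter$tally$n),
        filtered = r$filter$tally$n[r$filter$tally$rule == "passed"],
        indexed = nrow(r$index$index),
        windows = nrow(r$scan$windows),
        regions = sum(all_regions$source == cls)
      )
    })
  )
  names(manifest$counts) <- names(results)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )

  invisible(list(
    variants = variants,
    snp = results$snp, indel = results$indel,
    regions = all_regions,
    region_genes = if (!is.null(annot)) annot$region_genes else NULL,
    go = go,
    manifest = manifest,
    paths = paths
  ))
}

write_tsv_out <- function(x, dir, name) {
  p <- file.path(dir, name)
  readr::write_tsv(x, p, na = "", progress = FALSE)
  p
}

#' Manhattan-style plot of a genome scan
#'
#' Window smoothed deltas coloured by chromosome, with a dashed threshold
#' line and optional shaded candidate regions. Requires ggplot2.
#'
#' @param windows Smoothed windows (see [smooth_loess()]).
#' @param threshold Optional numeric threshold for the dashed line.
#' @param regs Optional region tibble to shade.
#' @return A ggplot object.
#' @export
plot_scan <- function(windows, threshold = NULL, regs = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_scan() requires the ggplot2 package")
  }
  p <- ggplot2::ggplot(
    windows,
    ggplot2::aes(x = .data$midpoint / 1e6, y = .data$smoothed_delta,
      colour = .data$chrom)
  ) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "position (Mb)", y = expression(Delta * "(SNP-index)")
    ) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(regs) && nrow(regs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regs,
      ggplot2::aes(
        xmin = .data$start_clamped / 1e6, xmax = .data$end / 1e6,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "red", alpha = 0.15
    )
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(
      yintercept = threshold, linetype = "dashed", colour = "red"
    )
  }
  p
}
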