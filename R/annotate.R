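#' Intersect candidate regions with gene models
#'
#' A gene belongs to a region iff the two inclusive intervals overlap by at
#' least one base pair (any-overlap rule, not containment). Regions with
#' negative starts are clamped to 1 for the intersection — gene models
#' always start at 1 or later, so this changes nothing biologically.
#'
#' @param regs A region tibble (see [regions()]).
#' @param genes A gene tibble (see [read_genes()]).
#' @return A list with `regions` (`regs` with `n_genes` filled in) and
#'   `region_genes` (tibble `region_id` = `chrom:start-end`, `chrom`,
#'   `gene_id`, `gene_start`, `gene_end`), sorted deterministically.
#' @export
genes_in_regions <- function(regs, genes) {
  if (nrow(regs) == 0) {
    return(list(
      regions = regs,
      region_genes = tibble(
        region_id = character(), chrom = character(), gene_id = character(),
        gene_start = integer(), gene_end = integer()
      )
    ))
  }
  region_id <- paste0(regs$chrom, ":", regs$start, "-", regs$end)
  r_gr <- GenomicRanges::GRanges(
    regs$chrom,
    IRanges::IRanges(start = pmax(regs$start, 1L), end = regs$end)
  )
  g_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start, end = genes$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(r_gr, g_gr))
  ri <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)

  counts <- tabulate(ri, nbins = nrow(regs))
  out_regs <- regs
  out_regs$n_genes <- as.integer(counts)

  region_genes <- tibble(
    region_id = region_id[ri],
    chrom = regs$chrom[ri],
    gene_id = genes$gene_id[gi],
    gene_start = genes$start[gi],
    gene_end = genes$end[gi]
  )
  region_genes <- arrange(
    region_genes, .data$chrom, .data$gene_start, .data$gene_id
  )
  list(regions = out_regs, region_genes = region_genes)
}

#' Tally GO classifications of candidate genes
#'
#' Counts, per GO namespace and term, how many of the given candidate genes
#' carry that annotation. Genes without any term are listed separately, not
#' counted. The trichome-morphogenesis term (GO:0010090), when present, is
#' flagged so reports can surface it.
#'
#' @param gene_ids Character vector of candidate gene ids (typically
#'   `region_genes$gene_id` from [genes_in_regions()], de-duplicated).
#' @param go_map A mapping tibble (see [read_go_map()]).
#' @return A list with `tally` (tibble `namespace`, `go_id`, `n_genes`,
#'   `trichome_morphogenesis`, sorted by namespace, decreasing count, term)
#'   and `unannotated` (character vector of candidate genes without terms).
#' @export
tally_go <- function(gene_ids, go_map) {
  gene_ids <- unique(as.character(gene_ids))
  go_map$namespace <- normalize_namespace(go_map$namespace)
  hit <- go_map[go_map$gene_id %in% gene_ids, , drop = FALSE]
  hit <- distinct(hit, .data$gene_id, .data$go_id, .data$namespace)
  if (nrow(hit) == 0) {
    tally <- tibble(
      namespace = character(), go_id = character(), n_genes = integer(),
      trichome_morphogenesis = logical()
    )
    return(list(tally = tally, unannotated = sort(gene_ids)))
  }
  tally <- summarise(
    group_by(hit, .data$namespace, .data$go_id),
    n_genes = dplyr::n(), .groups = "drop"
  )
  tally$trichome_morphogenesis <- tally$go_id == "GO:0010090"
  tally <- arrange(
    tally, .data$namespace, desc(.data$n_genes), .data$go_id
  )
  unannotated <- sort(setdiff(gene_ids, unique(hit$gene_id)))
  list(tally = tally, unannotated = unannotated)
}
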