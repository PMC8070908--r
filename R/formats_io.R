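#' Read a BSA-Seq variant table from a VCF file
#'
#' Parses a VCF 4.x file carrying `GT` and `AD` FORMAT fields for two parents
#' and two phenotype bulks, and returns one biallelic record per ALT allele.
#' Multi-allelic sites are decomposed at read time: record *k* of a site
#' carries the reference depth and the depth of ALT *k*; genotypes involving
#' a third allele become missing for that record.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param sample_roles Named character vector mapping roles to VCF sample
#'   names. Roles `bulk_AL` (trait bulk) and `bulk_GL` (opposite bulk) are
#'   required; `parent_hairy` (the parent carrying the dominant allele, e.g.
#'   W30) and `parent_glabrous` (e.g. 082) are optional — parental screens
#'   are skipped downstream when parents are absent.
#'
#' @return A tibble sorted by `(chrom, pos)` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `class` (`"snp"` iff REF and ALT are both single bases,
#'   else `"indel"`), and per role `gt_*` (genotype as `"0/0"`, `"0/1"`,
#'   `"1/1"` or `NA`), `ad0_*` (reference-supporting depth), `ad1_*`
#'   (alt-supporting depth). Suffixes: `hairy`, `glab`, `al`, `gl`.
#'   Missing genotypes/depths are preserved as `NA`, never coerced to zero.
#' @export
read_variants <- function(path, sample_roles) {
  if (!file.exists(path)) {
    abort(paste0("VCF file not found: ", path))
  }
  sample_roles <- unlist(sample_roles)
  unknown <- setdiff(names(sample_roles), bsa_roles())
  if (length(unknown) > 0) {
    abort(paste0("unknown sample role(s): ", paste(unknown, collapse = ", ")))
  }
  for (need in c("bulk_AL", "bulk_GL")) {
    if (!need %in% names(sample_roles)) {
      abort(paste0("configuration error: no sample mapped to role '", need, "'"))
    }
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(vcf@gt)[-1]
  for (role in names(sample_roles)) {
    if (!sample_roles[[role]] %in% have) {
      abort(paste0(
        "configuration error: sample '", sample_roles[[role]],
        "' for role '", role, "' not present in VCF header (samples: ",
        paste(have, collapse = ", "), ")"
      ))
    }
  }

  fix <- vcf@fix
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(empty_variants())
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  ad_raw <- vcfR::extract.gt(vcf, element = "AD")

  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  if (any(n_alt == 0 | is.na(fix[, "ALT"]))) {
    bad <- which(n_alt == 0 | is.na(fix[, "ALT"]))[1]
    abort(paste0("malformed VCF record at data line ", bad, ": no ALT allele"))
  }
  rec <- rep(seq_len(n_rec), n_alt) # source record of each decomposed row
  k <- sequence(n_alt)              # which alt allele the row represents

  pos <- as.integer(fix[, "POS"])
  if (anyNA(pos)) {
    abort(paste0(
      "malformed VCF record at data line ", which(is.na(pos))[1],
      ": non-integer POS"
    ))
  }

  out <- tibble(
    chrom = fix[rec, "CHROM"],
    pos = pos[rec],
    ref = fix[rec, "REF"],
    alt = unlist(alt_list),
    class = ifelse(nchar(fix[rec, "REF"]) == 1L & nchar(unlist(alt_list)) == 1L,
      "snp", "indel"
    )
  )

  for (role in bsa_roles()) {
    suf <- role_suffix[[role]]
    if (role %in% names(sample_roles)) {
      s <- sample_roles[[role]]
      ads <- parse_ad(ad_raw[, s], n_alt, rec, k)
      out[[paste0("gt_", suf)]] <- recode_gt(gt_raw[rec, s], k)
      out[[paste0("ad0_", suf)]] <- ads$ad0
      out[[paste0("ad1_", suf)]] <- ads$ad1
    } else {
      out[[paste0("gt_", suf)]] <- NA_character_
      out[[paste0("ad0_", suf)]] <- NA_integer_
      out[[paste0("ad1_", suf)]] <- NA_integer_
    }
  }

  # stable sort: decomposed records of one site keep their ALT order
  arrange(out, .data$chrom, .data$pos)
}

empty_variants <- function() {
  out <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), class = character()
  )
  for (suf in role_suffix) {
    out[[paste0("gt_", suf)]] <- character()
    out[[paste0("ad0_", suf)]] <- integer()
    out[[paste0("ad1_", suf)]] <- integer()
  }
  out
}

# Split comma-separated AD strings and pick (ref, alt k) depths for each
# decomposed row. AD vectors must have length 1 + n_alt at their site.
parse_ad <- function(ad, n_alt, rec, k) {
  ok <- is.na(ad) | grepl("^[0-9]+(,[0-9]+)*$", ad) | ad == "."
  if (!all(ok)) {
    abort(paste0(
      "malformed AD field at data line ", which(!ok)[1], ": '",
      ad[!ok][1], "'"
    ))
  }
  parts <- strsplit(ifelse(ad == ".", NA_character_, ad), ",", fixed = TRUE)
  bad_len <- !is.na(ad) & ad != "." & lengths(parts) != (1L + n_alt)
  if (any(bad_len)) {
    abort(paste0(
      "malformed AD field at data line ", which(bad_len)[1],
      ": expected ", 1L + n_alt[bad_len][1], " depths, found ",
      lengths(parts)[bad_len][1]
    ))
  }
  ad0 <- rep(NA_integer_, length(rec))
  ad1 <- rep(NA_integer_, length(rec))
  has <- !vapply(parts[rec], function(p) length(p) == 0 || anyNA(p), logical(1))
  idx <- which(has)
  if (length(idx) > 0) {
    ad0[idx] <- vapply(idx, function(i) as.integer(parts[[rec[i]]][1]), integer(1))
    ad1[idx] <- vapply(idx, function(i) as.integer(parts[[rec[i]]][k[i] + 1L]), integer(1))
  }
  list(ad0 = ad0, ad1 = ad1)
}

# Re-express a genotype call relative to alt allele k: alleles {0, k} map to
# {0, 1}; genotypes touching any other allele are missing for this record.
recode_gt <- function(gt, k) {
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  alleles <- strsplit(gt, "[/|]")
  vapply(seq_along(gt), function(i) {
    a <- suppressWarnings(as.integer(alleles[[i]]))
    if (length(a) != 2 || anyNA(a)) {
      return(NA_character_)
    }
    if (!all(a %in% c(0L, k[i]))) {
      return(NA_character_)
    }
    b <- sort(as.integer(a == k[i]))
    paste0(b[1], "/", b[2])
  }, character(1))
}

#' Read gene models from a GFF3 file
#'
#' Imports features of type `gene` with their `ID` attribute. Coordinates
#' are taken as-is (GFF3 is 1-based, fully inclusive). Features without an
#' `ID` are skipped with a warning; duplicated gene ids are an error.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`, `"-"` or `"unknown"`).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GFF3 file not found: ", path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  ids <- as.character(gr$ID)
  no_id <- is.na(ids) | ids == ""
  if (any(no_id)) {
    warn(paste0(
      sum(no_id), " gene feature(s) without an ID attribute were skipped"
    ))
    gr <- gr[!no_id]
    ids <- ids[!no_id]
  }
  if (anyDuplicated(ids) > 0) {
    abort(paste0(
      "duplicate gene_id in annotation: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(strand %in% c("+", "-"), strand, "unknown")
  )
}

#' Read a gene-to-GO mapping table
#'
#' Expects a headerless (or headered) TSV with two or three columns:
#' `gene_id`, `go_id` and optionally `namespace` (one of
#' `biological_process`, `cellular_component`, `molecular_function`; the
#' abbreviations `BP`, `CC`, `MF` are accepted).
#'
#' @param path Path to the TSV mapping file.
#' @return A tibble with columns `gene_id`, `go_id`, `namespace`.
#' @export
read_go_map <- function(path) {
  raw <- readr::read_tsv(path,
    col_names = FALSE, col_types = readr::cols(.default = "c"),
    progress = FALSE
  )
  if (ncol(raw) < 2 || ncol(raw) > 3) {
    abort("GO mapping file must have 2 or 3 tab-separated columns")
  }
  # tolerate a header row
  if (grepl("gene", raw[[1]][1], ignore.case = TRUE)) {
    raw <- raw[-1, , drop = FALSE]
  }
  out <- tibble(
    gene_id = raw[[1]],
    go_id = raw[[2]],
    namespace = if (ncol(raw) == 3) raw[[3]] else NA_character_
  )
  out$namespace <- normalize_namespace(out$namespace)
  out
}

go_namespaces <- function() {
  c("biological_process", "cellular_component", "molecular_function")
}

normalize_namespace <- function(x) {
  abbrev <- c(
    BP = "biological_process", CC = "cellular_component",
    MF = "molecular_function"
  )
  x <- ifelse(toupper(x) %in% names(abbrev), abbrev[toupper(x)], x)
  bad <- !is.na(x) & !x %in% go_namespaces()
  if (any(bad)) {
    abort(paste0("unknown GO namespace: '", x[bad][1], "'"))
  }
  unname(x)
}

#' Construct a candidate-region table
#'
#' Coordinates are 1-based and fully inclusive; `length = end - start + 1`.
#' Starts may be negative (single-site regions flanked beyond a scaffold
#' edge are reported unclamped); `start_clamped = max(start, 1)` is provided
#' alongside, and lengths are always computed from the unclamped span.
#'
#' @param chrom,start,end Vectors of equal length describing the regions.
#' @param n_genes Optional integer vector of per-region gene counts.
#' @param source Optional marker class the regions derive from
#'   (`"snp"`/`"indel"`).
#' @return A tibble with columns `chrom`, `start`, `end`, `length`,
#'   `n_genes`, `source`, `start_clamped`.
#' @export
regions <- function(chrom, start, end, n_genes = NA_integer_, source = NA_character_) {
  start <- as.integer(round(start))
  end <- as.integer(round(end))
  if (any(end < start)) {
    abort("region end < start")
  }
  tibble(
    chrom = as.character(chrom), start = start, end = end,
    length = end - start + 1L,
    n_genes = as.integer(n_genes),
    source = as.character(source),
    start_clamped = pmax(start, 1L)
  )
}

#' Write candidate regions as a TSV table
#'
#' Emits the columns `Chrom`, `Start`, `End`, `Length`, `NumberOfGenes`,
#' with `Length` recomputed as `End - Start + 1` (inclusive convention) and
#' absent gene counts left empty.
#'
#' @param x A region tibble (see [regions()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(x, path) {
  out <- tibble(
    Chrom = x$chrom,
    Start = x$start,
    End = x$end,
    Length = x$end - x$start + 1L,
    NumberOfGenes = x$n_genes
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a candidate-region TSV table
#'
#' Inverse of [write_regions()]; also accepts tables without a `Length`
#' column (lengths are recomputed from the inclusive convention).
#'
#' @param path Path to a region TSV with columns `Chrom`, `Start`, `End`
#'   and optionally `NumberOfGenes`.
#' @inheritParams regions
#' @return A region tibble (see [regions()]).
#' @export
read_regions <- function(path, source = NA_character_) {
  raw <- readr::read_tsv(path,
    col_types = readr::cols(
      Chrom = readr::col_character(), Start = readr::col_double(),
      End = readr::col_double(), .default = readr::col_guess()
    ),
    progress = FALSE
  )
  need <- c("Chrom", "Start", "End")
  if (!all(need %in% names(raw))) {
    abort("region table must have columns Chrom, Start, End")
  }
  n_genes <- if ("NumberOfGenes" %in% names(raw)) {
    as.integer(raw$NumberOfGenes)
  } else {
    NA_integer_
  }
  regions(raw$Chrom, raw$Start, raw$End, n_genes = n_genes, source = source)
}

#' Write a variant table as a VCF 4.2 file
#'
#' Serializes a (biallelic) variant tibble back to VCF with `GT:AD:DP`
#' sample fields, one column per role present. Used by the simulator to emit
#' standard inputs; the result reads back through [read_variants()].
#'
#' @param x A variant tibble (see [read_variants()]).
#' @param path Output VCF path.
#' @param sample_names Named character vector giving the VCF sample name for
#'   each role to write.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path,
                      sample_names = c(
                        parent_hairy = "W30", parent_glabrous = "082",
                        bulk_AL = "AL", bulk_GL = "GL"
                      ),
                      contigs = NULL) {
  assert_variants(x)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsaseqr",
    if (!is.null(contigs)) {
      paste0("##contig=<ID=", names(contigs), ",length=", as.integer(contigs), ">")
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      unname(sample_names)
    ), collapse = "\t")
  )
  fmt_sample <- function(gt, ad0, ad1) {
    gt_s <- ifelse(is.na(gt), "./.", gt)
    ad_s <- ifelse(is.na(ad0) | is.na(ad1), ".", paste0(ad0, ",", ad1))
    dp_s <- ifelse(is.na(ad0) | is.na(ad1), ".", ad0 + ad1)
    paste(gt_s, ad_s, dp_s, sep = ":")
  }
  cols <- vapply(names(sample_names), function(role) {
    suf <- role_suffix[[role]]
    fmt_sample(
      x[[paste0("gt_", suf)]],
      x[[paste0("ad0_", suf)]],
      x[[paste0("ad1_", suf)]]
    )
  }, character(nrow(x)))
  if (nrow(x) == 1) cols <- matrix(cols, nrow = 1)
  body <- paste(
    x$chrom, x$pos, ".", x$ref, x$alt, ".", "PASS", ".", "GT:AD:DP",
    apply(cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}
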