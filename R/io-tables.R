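# Readers and writers for the tabular formats around the variant calls:
# gene models, copy-number segments, array genotypes, catalogues, gene lists,
# blacklist BED, and the result-table report bundle.
#
# All coordinates are 1-based inclusive internally (VCF convention); BED
# inputs are converted at the boundary.

#' Read a gene model
#'
#' Reads a tab-separated gene model with one row per gene: span, strand, CDS
#' blocks (comma-separated 1-based inclusive start/end lists) and functional
#' class tags (semicolon-separated, may be empty). With `coords = "bed"` the
#' span and CDS coordinates are interpreted as 0-based half-open and converted.
#'
#' @param path Path to a TSV file with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `cds_starts`, `cds_ends`, `class_tags`.
#' @param coords Coordinate convention of the input, `"1-based"` (default) or
#'   `"bed"`.
#' @return A gene model tibble (see [synthetic_gene_model()]).
#' @export
read_gene_model <- function(path, coords = c("1-based", "bed")) {
  coords <- match.arg(coords)
  cols <- c("gene_id", "chrom", "start", "end", "strand", "cds_starts",
            "cds_ends", "class_tags")
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  stop_if_missing_cols(x, cols, "gene model")
  x <- keep_known_cols(x, cols, "gene model")
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$class_tags <- ifelse(is.na(x$class_tags), "", x$class_tags)
  if (coords == "bed") {
    conv <- bed_to_inclusive(x$start, x$end)
    x$start <- conv$start; x$end <- conv$end
    x$cds_starts <- vapply(strsplit(x$cds_starts, ",", fixed = TRUE), function(s) {
      paste(as.integer(s) + 1L, collapse = ",")
    }, "")
  }
  validate_gene_model(as_tibble(x))
}

#' Validate a gene model table
#'
#' Enforces the gene-model invariants: unique gene identifiers, `start <=
#' end`, every CDS interval inside the gene span, and non-overlapping CDS
#' intervals within a gene.
#'
#' @param genes A gene model tibble.
#' @return The input, invisibly-validated (returned visibly for piping).
#' @export
validate_gene_model <- function(genes) {
  if (anyDuplicated(genes$gene_id)) abort("gene model: duplicate gene_id")
  if (any(genes$start > genes$end)) abort("gene model: start > end")
  cds <- unnest_cds(genes)
  if (any(cds$start > cds$end)) abort("gene model: CDS start > end")
  span <- genes[match(cds$gene_id, genes$gene_id), ]
  if (any(cds$start < span$start | cds$end > span$end)) {
    abort("gene model: CDS interval outside gene span")
  }
  by_gene <- split(cds, cds$gene_id)
  for (g in by_gene) {
    if (nrow(g) < 2) next
    g <- g[order(g$start), ]
    if (any(g$start[-1] <= g$end[-nrow(g)])) {
      abort(sprintf("gene model: overlapping CDS intervals in %s", g$gene_id[[1]]))
    }
  }
  genes
}

#' Write a gene model to TSV
#' @param genes A gene model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(genes, path) {
  readr::write_tsv(genes, path, progress = FALSE)
  invisible(path)
}

#' Read copy-number segments
#'
#' Reads a SEG-like tab-separated file of per-sample copy-number segments
#' with a continuous copy-number value. Same-sample segments on a chromosome
#' must not overlap.
#'
#' @param path TSV with columns `sample_id`, `chrom`, `start`, `end`, `cn`.
#' @return A tibble of validated segments.
#' @export
read_segments <- function(path) {
  cols <- c("sample_id", "chrom", "start", "end", "cn")
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stop_if_missing_cols(x, cols, "segment table")
  x <- keep_known_cols(x, cols, "segment table")
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  validate_segments(as_tibble(x))
}

#' Validate a copy-number segment table
#' @param segments Segment tibble (`sample_id`, `chrom`, `start`, `end`, `cn`).
#' @return The validated input.
#' @export
validate_segments <- function(segments) {
  if (any(segments$start > segments$end)) abort("segments: start > end")
  if (any(segments$cn < 0)) abort("segments: cn must be non-negative")
  grp <- split(segments, paste(segments$sample_id, segments$chrom))
  for (g in grp) {
    if (nrow(g) < 2) next
    g <- g[order(g$start), ]
    if (any(g$start[-1] <= g$end[-nrow(g)])) {
      abort(sprintf("segments: overlapping segments for %s on %s",
                    g$sample_id[[1]], g$chrom[[1]]))
    }
  }
  segments
}

#' Read SNP-array genotype calls
#'
#' @param path TSV with columns `sample_id`, `chrom`, `pos`, `genotype`
#'   (one of `hom_ref`, `het`, `hom_alt`), `ref`, `alt`.
#' @return A tibble of validated array genotype calls.
#' @export
read_array_genotypes <- function(path) {
  cols <- c("sample_id", "chrom", "pos", "genotype", "ref", "alt")
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stop_if_missing_cols(x, cols, "array genotype table")
  x <- keep_known_cols(x, cols, "array genotype table")
  bad <- setdiff(unique(x$genotype), c("hom_ref", "het", "hom_alt"))
  if (length(bad) > 0) {
    abort(sprintf("array genotypes: unknown genotype code(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (any(x$ref == x$alt)) abort("array genotypes: ref and alt must differ")
  x$pos <- as.integer(x$pos)
  as_tibble(x)
}

#' Read a cancer mutation catalogue
#'
#' @param path TSV with columns `gene_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `source_label`.
#' @return A tibble of catalogue mutations.
#' @export
read_catalogue <- function(path) {
  cols <- c("gene_id", "chrom", "pos", "ref_allele", "alt_allele", "source_label")
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stop_if_missing_cols(x, cols, "mutation catalogue")
  x <- keep_known_cols(x, cols, "mutation catalogue")
  if (any(x$ref_allele == x$alt_allele)) abort("catalogue: ref and alt must differ")
  if (any(x$pos < 1)) abort("catalogue: positions must be >= 1")
  x$pos <- as.integer(x$pos)
  as_tibble(x)
}

#' Read a curated gene list with functional class tags
#'
#' @param path TSV with columns `gene_id`, `class` (long format; a gene in
#'   several families has one row per family).
#' @return A tibble with `gene_id` and `class`.
#' @export
read_gene_list <- function(path) {
  cols <- c("gene_id", "class")
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stop_if_missing_cols(x, cols, "gene list")
  x <- keep_known_cols(x, cols, "gene list")
  as_tibble(x)
}

#' Read blacklist regions from a BED file
#'
#' BED is 0-based half-open; intervals are converted to the package's 1-based
#' inclusive convention (both ends inclusive after conversion).
#'
#' @param path BED file (3+ columns, no header).
#' @return A tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name` (fourth BED column, `NA` when absent).
#' @export
read_blacklist <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(x) < 3) abort("blacklist BED needs at least 3 columns")
  conv <- bed_to_inclusive(as.integer(x[[2]]), as.integer(x[[3]]))
  tibble(
    chrom = as.character(x[[1]]),
    start = conv$start,
    end = conv$end,
    name = if (ncol(x) >= 4) as.character(x[[4]]) else NA_character_
  )
}

#' Write blacklist regions to a BED file
#' @param blacklist Tibble with `chrom`, `start`, `end` (1-based inclusive)
#'   and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blacklist_bed <- function(blacklist, path) {
  conv <- inclusive_to_bed(blacklist$start, blacklist$end)
  out <- data.frame(blacklist$chrom, conv$start, conv$end)
  if (!is.null(blacklist$name)) out$name <- blacklist$name
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a bundle of result tables to TSV plus a JSON index
#'
#' Writes every table in `tables` as `<name>.tsv` under `out_dir` (created if
#' needed) with a deterministic column order (as given) and row order (as
#' given; pipeline outputs are already deterministically sorted), plus a
#' `report.json` holding any scalar entries and the per-table row counts.
#' Re-running on identical inputs yields byte-identical files.
#'
#' @param tables Named list; data-frame entries become TSV files, everything
#'   else goes into `report.json`.
#' @param out_dir Output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(tables, out_dir) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("write_report: tables must be a fully named list")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  scalars <- list()
  counts <- list()
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      readr::write_tsv(as_tibble(x), f, progress = FALSE)
      files <- c(files, f)
      counts[[nm]] <- nrow(x)
    } else {
      scalars[[nm]] <- x
    }
  }
  f <- file.path(out_dir, "report.json")
  jsonlite::write_json(c(scalars, list(table_rows = counts)), f,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(c(files, f))
}
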