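# Deterministic synthetic genome annotation used by the cohort generator.
#
# No raw data are deposited for the six-cell-line study the pipeline is
# modelled on, so all coordinates here are synthetic: real melanoma-relevant
# gene symbols are laid out on an artificial six-chromosome genome with
# regular gene spans and CDS blocks. What matters downstream is the relational
# structure (which genes are in the cancer catalogue, the curated list, the
# blacklist), not the coordinates themselves.

#' Gene sets of the synthetic annotation
#'
#' The fixed gene sets the synthetic cohort is built around:
#' `cosmic_mutated_genes()` are the catalogue genes with known point
#' mutations, `cosmic_deleted_gene_set()` the catalogue genes reported as
#' deleted in cancer, and `de_novo_gene_set()` recurrently mutated genes
#' absent from both the catalogue and the curated list.
#'
#' @return A character vector of gene symbols.
#' @name gene_sets
NULL

#' @rdname gene_sets
#' @export
cosmic_mutated_genes <- function() {
  c("BRAF", "HYDIN", "SPTA1", "XKR6", "NRAS", "SMC1B", "MADD", "MKS1", "PKHD1")
}

#' @rdname gene_sets
#' @export
cosmic_deleted_gene_set <- function() {
  c("CDKN2A", "MAP2K4", "AXIN1", "JAK2", "KIT", "PDGFRA", "RB1", "TET2",
    "ZRANB1", "APC")
}

#' @rdname gene_sets
#' @export
de_novo_gene_set <- function() {
  c("C4orf23", "PAICS", "CNST", "KIF23", "MRPL1", "MUC19", "DCAKD", "MRPL53",
    "RBMXL1", "ZNF66P")
}

curated_families <- function() {
  list(
    "PI3K/Akt signalling" = c("PIK3R4", "PIK3C2G", "PREX2", "PIK3CG"),
    "MAPK signalling" = c("MAP3K4", "BRAF", "MAPK6", "MAP2K3", "MAP3K5"),
    "Glutamate signalling" = c("GRIN2B", "GRIN3A", "GRM5", "PLCB1", "PLCB4",
                               "PLCE1", "PLCZ1", "GRM1", "PLCXD2"),
    "RAS-RAF Ser/Thr kinases" = c("BRAF", "NRAS"),
    "Protein tyrosine kinases" = c("FGFR1", "MET", "PTK2B", "PTK7"),
    "Metalloproteinases" = c("ADAM22", "ADAMTS18", "MMP24", "MMP25", "ADAMTS9",
                             "ADAMTS12", "ADAM23", "ADAMTS6", "MMP19"),
    "Protein tyrosine phosphatases" = c("PTPN1", "PTPRK", "PTPN13", "PTPRF",
                                        "PTPRD", "PTPLA"),
    "G protein-coupled receptors" = c("GPR64", "GPR101", "GPR112", "GPR158",
                                      "GRM5", "GPR113", "GPR151", "GPR133",
                                      "GRM1")
  )
}

# HLA-like loci and homologous repeated genes: coding variants mapping here
# are unreliable and are blacklisted by the filter cascade.
blacklist_gene_set <- function() {
  c("HLA_LIKE_A", "HLA_LIKE_B", "HOMOLOG_REP1", "HOMOLOG_REP2")
}

#' Curated melanoma gene list (synthetic subset)
#'
#' A long-format gene list assigning melanoma-relevant genes to the signalling
#' cascade or molecular-function family they belong to, mirroring the
#' structure of curated melanoma gene panels (a gene belonging to several
#' families appears once per family, e.g. `GRM5` under both glutamate
#' signalling and G protein-coupled receptors). This is a small synthetic
#' subset standing in for a full curated panel.
#'
#' @return A tibble with columns `gene_id` and `class`.
#' @examples
#' dplyr::count(melanoma_gene_list(), class)
#' @export
melanoma_gene_list <- function() {
  fam <- curated_families()
  tibble(
    gene_id = unlist(fam, use.names = FALSE),
    class = rep(names(fam), lengths(fam))
  )
}

#' Synthetic gene model
#'
#' Builds the deterministic gene model the synthetic cohort is generated
#' against: melanoma-relevant symbols (cancer-catalogue genes, curated-family
#' genes, recurrently mutated "de novo" genes), blacklisted HLA-like and
#' homologous repeated loci, and anonymous filler genes, laid out round-robin
#' on six synthetic chromosomes. Every gene has six 500-bp CDS blocks inside
#' a 12-kb span.
#'
#' @param n_filler Number of anonymous filler genes (default 40).
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `cds_starts`, `cds_ends` (comma-separated 1-based inclusive coordinates)
#'   and `class_tags` (semicolon-separated family labels, may be empty).
#' @examples
#' genes <- synthetic_gene_model()
#' head(genes)
#' @export
synthetic_gene_model <- function(n_filler = 40) {
  fam <- curated_families()
  curated <- unique(unlist(fam, use.names = FALSE))
  ids <- unique(c(cosmic_mutated_genes(), cosmic_deleted_gene_set(), curated,
                  de_novo_gene_set(), blacklist_gene_set(),
                  sprintf("GENE%03d", seq_len(n_filler))))
  i <- seq_along(ids)
  chrom <- paste0("chr", (i - 1L) %% 6L + 1L)
  slot <- (i - 1L) %/% 6L
  start <- 100001L + slot * 150000L
  end <- start + 11999L
  offsets <- seq(0L, 10000L, by = 2000L)
  cds_starts <- vapply(start, function(s) paste(s + offsets, collapse = ","), "")
  cds_ends <- vapply(start, function(s) paste(s + offsets + 499L, collapse = ","), "")
  gl <- melanoma_gene_list()
  tags <- vapply(ids, function(g) {
    paste(gl$class[gl$gene_id == g], collapse = ";")
  }, "")
  tibble(
    gene_id = ids, chrom = chrom, start = start, end = end,
    strand = rep_len(c("+", "-"), length(ids)),
    cds_starts = cds_starts, cds_ends = cds_ends, class_tags = unname(tags)
  )
}

# One row per CDS interval: gene_id, chrom, start, end.
unnest_cds <- function(genes) {
  starts <- strsplit(genes$cds_starts, ",", fixed = TRUE)
  ends <- strsplit(genes$cds_ends, ",", fixed = TRUE)
  nper <- lengths(starts)
  tibble(
    gene_id = rep(genes$gene_id, nper),
    chrom = rep(genes$chrom, nper),
    start = as.integer(unlist(starts)),
    end = as.integer(unlist(ends))
  )
}

# Long-format class tags: gene_id, class.
gene_class_tags <- function(genes) {
  tags <- strsplit(genes$class_tags, ";", fixed = TRUE)
  tags <- lapply(tags, function(x) x[nzchar(x)])
  nper <- lengths(tags)
  tibble(gene_id = rep(genes$gene_id, nper), class = unlist(tags, use.names = FALSE))
}

# Blacklist regions = full spans of the blacklisted loci (1-based inclusive).
synthetic_blacklist <- function(genes = synthetic_gene_model()) {
  bl <- genes[genes$gene_id %in% blacklist_gene_set(), , drop = FALSE]
  tibble(chrom = bl$chrom, start = bl$start, end = bl$end, name = bl$gene_id)
}

# Fixed per-gene catalogue position: 100 bp into the first CDS block.
catalogue_position <- function(genes, gene_id) {
  g <- genes[match(gene_id, genes$gene_id), , drop = FALSE]
  if (anyNA(g$gene_id)) {
    abort(sprintf("gene(s) not in gene model: %s",
                  paste(gene_id[is.na(g$gene_id)], collapse = ", ")))
  }
  first_cds <- as.integer(vapply(strsplit(g$cds_starts, ",", fixed = TRUE),
                                 function(x) x[[1]], ""))
  tibble(gene_id = g$gene_id, chrom = g$chrom, pos = first_cds + 100L)
}

#' Synthetic cancer mutation catalogue
#'
#' A COSMIC-style catalogue of known cancer mutations keyed by exact genomic
#' position and alleles on the synthetic gene model. Contains one entry per
#' catalogued gene, at the same fixed position the cohort generator uses to
#' inject driver mutations, so exact-position matching against it is exercised
#' end-to-end.
#'
#' @param genes Gene model tibble, as from [synthetic_gene_model()].
#' @return A tibble with columns `gene_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `source_label`.
#' @export
synthetic_catalogue <- function(genes = synthetic_gene_model()) {
  mm <- c("BRAF", "NRAS", "XKR6", "MADD", "PKHD1")
  ids <- cosmic_mutated_genes()
  loc <- catalogue_position(genes, ids)
  refalt <- list(
    BRAF = c("A", "T"), NRAS = c("T", "C"), HYDIN = c("C", "T"),
    SPTA1 = c("G", "A"), XKR6 = c("C", "A"), SMC1B = c("C", "T"),
    MADD = c("G", "A"), MKS1 = c("C", "T"), PKHD1 = c("G", "T")
  )
  tibble(
    gene_id = loc$gene_id, chrom = loc$chrom, pos = loc$pos,
    ref_allele = unname(vapply(refalt[loc$gene_id], `[`, "", 1L)),
    alt_allele = unname(vapply(refalt[loc$gene_id], `[`, "", 2L)),
    source_label = ifelse(loc$gene_id %in% mm, "malignant_melanoma", "other_tumour")
  )
}
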