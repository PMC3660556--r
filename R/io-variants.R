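# VCF input/output for single-nucleotide variant calls.

#' Read SNV calls from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into the package's per-variant
#' table. Only biallelic single-nucleotide substitutions are kept;
#' multi-allelic lines are split into one record per alternate allele before
#' the SNV test, and non-SNV records (indels, symbolic alleles) are skipped
#' with a reported count. The non-reference allele fraction is recomputed
#' from the `AD` FORMAT field (alternate reads over all reads at the site)
#' rather than trusted from an annotation, and the call quality is taken from
#' the `QUAL` column. Optional `GENE=` and `CSQ=` INFO keys populate the gene
#' assignment and functional consequence.
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample identifier to attach to every record. Defaults to
#'   the (single) genotype column name in the VCF.
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `quality`, `af`, `known`, `in_house`, `gene_id`, `consequence`.
#'   `known` and `in_house` are initialised to `FALSE`; see
#'   [flag_known_sites()]. The number of skipped non-SNV records is attached
#'   as attribute `n_skipped`.
#' @seealso [write_variants_vcf()], [flag_known_sites()], [apply_hq_filter()]
#' @export
read_variants <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- empty_variants()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  gt_names <- colnames(v@gt)
  gt_names <- setdiff(gt_names, "FORMAT")
  if (is.null(sample_id)) {
    if (length(gt_names) != 1) {
      abort("VCF has multiple genotype columns; supply sample_id and a single-sample file")
    }
    sample_id <- gt_names[[1]]
  }
  ad <- tryCatch(unname(vcfR::extract.gt(v, element = "AD")[, 1]),
                 error = function(e) rep(NA_character_, nrow(fix)))
  dp <- tryCatch(suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1])),
                 error = function(e) rep(NA_integer_, nrow(fix)))

  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_rank <- sequence(n_alt)

  ad_split <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
  ad_total <- unname(vapply(ad_split, function(x) {
    x <- suppressWarnings(as.numeric(x))
    if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  }, 0))
  ad_alt <- unname(mapply(function(x, k) {
    x <- suppressWarnings(as.numeric(x))
    if (length(x) >= k + 1) x[[k + 1]] else NA_real_
  }, ad_split[idx], alt_rank, USE.NAMES = FALSE))

  rec <- tibble(
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = toupper(fix$REF[idx]),
    alt = toupper(unlist(alts, use.names = FALSE)),
    quality = suppressWarnings(as.numeric(fix$QUAL[idx])),
    info = fix$INFO[idx],
    ad_total = ad_total[idx],
    ad_alt = ad_alt,
    dp = dp[idx]
  )

  is_snv <- rec$ref %in% DNA_BASES & rec$alt %in% DNA_BASES & rec$ref != rec$alt
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    inform(sprintf("read_variants: skipped %d non-SNV record(s) in %s",
                   n_skipped, basename(path)))
  }
  rec <- rec[is_snv, , drop = FALSE]

  depth <- ifelse(is.na(rec$ad_total), rec$dp, rec$ad_total)
  if (anyNA(depth)) abort("read_variants: cannot derive read depth (need AD or DP FORMAT field)")
  if (anyNA(rec$quality)) abort("read_variants: missing QUAL for one or more SNV records")
  af <- ifelse(depth > 0, rec$ad_alt / depth, 0)
  if (anyNA(af)) abort("read_variants: cannot derive allele fraction (need per-allele AD counts)")

  out <- tibble(
    sample_id = sample_id,
    chrom = rec$chrom,
    pos = rec$pos,
    ref = rec$ref,
    alt = rec$alt,
    depth = as.integer(round(depth)),
    quality = rec$quality,
    af = af,
    known = FALSE,
    in_house = FALSE,
    gene_id = info_field(rec$info, "GENE"),
    consequence = dplyr::coalesce(info_field(rec$info, "CSQ"), "unannotated")
  )
  validate_variants(out)
  attr(out, "n_skipped") <- n_skipped
  out
}

info_field <- function(info, key) {
  info <- ifelse(is.na(info), "", info)
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regexpr(pat, info, perl = TRUE)
  out <- rep(NA_character_, length(info))
  ok <- m != -1L
  if (any(ok)) {
    hit <- substr(info[ok], m[ok], m[ok] + attr(m, "match.length")[ok] - 1L)
    out[ok] <- sub(paste0("^;?", key, "="), "", hit)
  }
  out
}

empty_variants <- function() {
  tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), depth = integer(),
    quality = numeric(), af = numeric(), known = logical(),
    in_house = logical(), gene_id = character(), consequence = character()
  )
}

#' Validate a variant table
#'
#' Checks the per-variant invariants: alleles are distinct single bases,
#' positions are >= 1, depths are non-negative and allele fractions lie in
#' [0, 1]. Called by the readers and the generator; exported so hand-built
#' tables can be validated too.
#'
#' @param variants A variant tibble (see [read_variants()] for the schema).
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_variants <- function(variants) {
  stop_if_missing_cols(variants, c("sample_id", "chrom", "pos", "ref", "alt",
                                   "depth", "quality", "af"), "variant table")
  if (nrow(variants) == 0) return(invisible(variants))
  if (!all(variants$ref %in% DNA_BASES) || !all(variants$alt %in% DNA_BASES)) {
    abort("variant table: ref/alt must be single bases A/C/G/T")
  }
  if (any(variants$ref == variants$alt)) abort("variant table: ref and alt must differ")
  if (any(variants$pos < 1)) abort("variant table: positions must be >= 1")
  if (any(variants$depth < 0)) abort("variant table: read depth must be non-negative")
  if (any(variants$af < 0 | variants$af > 1)) abort("variant table: allele fraction must be in [0, 1]")
  if (any(variants$quality < 0)) abort("variant table: call quality must be non-negative")
  invisible(variants)
}

#' Flag variants found in known-site and in-house catalogues
#'
#' Sets the `known` flag for variants whose (chrom, pos, ref, alt) key occurs
#' in a known-sites catalogue (a dbSNP-like table) and the `in_house` flag for
#' those occurring in a local prior-projects set.
#'
#' @param variants A variant tibble.
#' @param known_sites,in_house_sites Tibbles with columns `chrom`, `pos`,
#'   `ref`, `alt` (either may be `NULL` to leave the corresponding flag
#'   untouched).
#' @return The variant tibble with updated `known` / `in_house` columns.
#' @export
flag_known_sites <- function(variants, known_sites = NULL, in_house_sites = NULL) {
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  if (!is.null(known_sites)) {
    stop_if_missing_cols(known_sites, c("chrom", "pos", "ref", "alt"), "known_sites")
    variants$known <- key(variants) %in% key(known_sites)
  }
  if (!is.null(in_house_sites)) {
    stop_if_missing_cols(in_house_sites, c("chrom", "pos", "ref", "alt"), "in_house_sites")
    variants$in_house <- key(variants) %in% key(in_house_sites)
  }
  variants
}

#' Write a variant table to a single-sample VCF file
#'
#' Emits a minimal, plain-text VCF 4.2 file carrying depth and per-allele
#' read counts in the `AD`/`DP` FORMAT fields, call quality in `QUAL`, and
#' gene/consequence annotation in `GENE=`/`CSQ=` INFO keys, so that
#' [read_variants()] reproduces the table exactly (allele fractions are
#' integer read ratios). Records are sorted by chromosome and position.
#'
#' @param variants Variant tibble for one sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  validate_variants(variants)
  sid <- unique(variants$sample_id)
  if (length(sid) > 1) abort("write_variants_vcf writes one sample per file")
  if (length(sid) == 0) sid <- "SAMPLE"
  v <- arrange(variants, .data$chrom, .data$pos, .data$alt)
  ad_alt <- as.integer(round(v$af * v$depth))
  ad_ref <- v$depth - ad_alt
  gt <- ifelse(v$af >= 0.9, "1/1", "0/1")
  info <- ifelse(
    is.na(v$gene_id),
    paste0("CSQ=", v$consequence),
    paste0("GENE=", v$gene_id, ";CSQ=", v$consequence)
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=melascope",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene identifier\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Functional consequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sid)
  )
  body <- if (nrow(v) > 0) {
    paste(v$chrom, v$pos, ".", v$ref, v$alt,
          format(v$quality, trim = TRUE, scientific = FALSE), "PASS", info,
          "GT:AD:DP",
          paste0(gt, ":", ad_ref, ",", ad_alt, ":", v$depth),
          sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}
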