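# Synthetic multi-sample cohort generator with ground-truth tables.
#
# The generator emulates the statistical structure the analysis assumes for a
# six-sample metastatic melanoma cell line cohort: a C>T/G>A-dominated
# substitution spectrum, known/novel status with a dbSNP-like known-sites
# catalogue, negative-binomial read depth around 45x, lognormal call quality,
# read-sampled allele fractions with het/hom zygosity structure, injected
# driver mutations at cancer-catalogue positions, orthogonal array genotypes
# with depth-dependent heterozygote miscalls on the sequencing side, and
# copy-number segments embedding amplifications, one-copy losses and
# homozygous deletions in a diploid background.

SPECTRUM_LEVELS <- c("C>T/G>A", "C>A/G>T", "C>G/G>C", "T>C/A>G", "T>A/A>T", "T>G/A>C")

# The two strand members (ref, alt) of each collapsed class, pyrimidine first.
SPECTRUM_MEMBERS <- list(
  "C>T/G>A" = list(c("C", "T"), c("G", "A")),
  "C>A/G>T" = list(c("C", "A"), c("G", "T")),
  "C>G/G>C" = list(c("C", "G"), c("G", "C")),
  "T>C/A>G" = list(c("T", "C"), c("A", "G")),
  "T>A/A>T" = list(c("T", "A"), c("A", "T")),
  "T>G/A>C" = list(c("T", "G"), c("A", "C"))
)

#' Default injected driver mutations
#'
#' BRAF V600E-like driver carried by four of six samples (homozygous in one)
#' and an NRAS Q61R-like homozygous driver in a fifth sample; the sixth sample
#' is wild-type for both. Positions and alleles coincide with the synthetic
#' cancer catalogue so exact-position confirmation is exercised.
#'
#' @return A tibble with columns `gene_id`, `sample_id`, `zygosity`.
#' @export
default_drivers <- function() {
  tibble(
    gene_id = c("BRAF", "BRAF", "BRAF", "BRAF", "NRAS"),
    sample_id = c("Me01", "Me04", "Me08", "Me12", "Me02"),
    zygosity = c("heterozygous", "homozygous", "heterozygous", "heterozygous",
                 "homozygous")
  )
}

#' Default copy-number events
#'
#' Gene-anchored events embedded in the diploid background: recurrent CDKN2A
#' homozygous deletions (three samples), a cluster of eight one-copy losses in
#' one heavily affected sample, additional one-copy losses of catalogue tumor
#' suppressors, and one amplification.
#'
#' @return A tibble with columns `sample_id`, `gene_id`, `cn`.
#' @export
default_cn_events <- function() {
  tibble(
    sample_id = c("Me01", "Me01", "Me02", "Me02",
                  rep("Me05", 8), "Me08", "Me08", "Me12"),
    gene_id = c("CDKN2A", "BRAF", "CDKN2A", "MAP2K4",
                c("AXIN1", "CDKN2A", "JAK2", "KIT", "PDGFRA", "RB1", "TET2",
                  "ZRANB1"),
                "APC", "MAP2K4", "CDKN2A"),
    cn = c(0, 3.5, 0.2, 1.0, rep(1.0, 8), 1.1, 0.9, 0.1)
  )
}

#' Specify a synthetic cohort
#'
#' Collects every generator knob into a validated specification. The defaults
#' are the study conditions the pipeline is modelled on: six samples, ~5,000
#' variants per sample, a C>T/G>A-dominated (UV-signature) spectrum, ~8%
#' novel variants, ~25% of variants in coding sequence, negative-binomial
#' depth around 45x, and a beta-binomial heterozygous allele-fraction model
#' whose expected WES-array heterozygote concordance sustains 90% from 15
#' reads onward.
#'
#' @param n_samples Number of samples (default 6).
#' @param sample_ids Sample identifiers.
#' @param n_variants Variants drawn per sample before deduplication.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @param spectrum_weights Named non-negative weights over the six collapsed
#'   substitution classes, summing to 1.
#' @param novel_fraction Fraction of variants absent from the known-sites
#'   catalogue.
#' @param coding_fraction Fraction of variants placed inside CDS intervals.
#' @param het_fraction Fraction of variants that are truly heterozygous.
#' @param consequence_probs Named probabilities over
#'   missense/nonsense/synonymous for coding variants.
#' @param in_house_fraction Fraction of novel variants also present in the
#'   in-house prior-projects set.
#' @param depth_mu,depth_size Negative-binomial read-depth parameters (mean
#'   reads and dispersion size); depths are truncated below at 1 for variant
#'   sites.
#' @param quality_meanlog,quality_sdlog Lognormal call-quality parameters.
#' @param af_model Heterozygous allele-fraction model: `"betabinom"` (default;
#'   alternate reads ~ BetaBinomial(depth, af_shape1, af_shape2), emulating
#'   aneuploidy-shifted overdispersed allele fractions), `"binomial"` (pure
#'   Binomial(depth, 1/2) allele sampling) or `"exact"` (noise-free 0.5/1).
#' @param af_shape1,af_shape2 Beta shape parameters for `"betabinom"`.
#' @param drivers Driver table as in [default_drivers()]; carriers receive a
#'   deterministic high-confidence call (depth 60, quality 500).
#' @param cn_events Copy-number events as in [default_cn_events()].
#' @param array_sites Array sites per sample (variant plus homozygous-reference
#'   sites).
#' @param array_homref_fraction Fraction of array sites placed at
#'   homozygous-reference positions.
#' @param genes Gene model tibble; defaults to [synthetic_gene_model()].
#' @param config [scope_config()] used to compute the `should_pass_filter`
#'   truth column.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 6L,
                        sample_ids = c("Me01", "Me02", "Me04", "Me05", "Me08", "Me12"),
                        n_variants = 5000L,
                        seed = 1L,
                        spectrum_weights = c("C>T/G>A" = 0.55, "C>A/G>T" = 0.17,
                                             "C>G/G>C" = 0.08, "T>C/A>G" = 0.10,
                                             "T>A/A>T" = 0.06, "T>G/A>C" = 0.04),
                        novel_fraction = 0.08,
                        coding_fraction = 0.25,
                        het_fraction = 0.70,
                        consequence_probs = c(missense = 0.62, nonsense = 0.035,
                                              synonymous = 0.345),
                        in_house_fraction = 0.05,
                        depth_mu = 45,
                        depth_size = 5,
                        quality_meanlog = log(250),
                        quality_sdlog = 0.8,
                        af_model = c("betabinom", "binomial", "exact"),
                        af_shape1 = 12,
                        af_shape2 = 7.5,
                        drivers = default_drivers(),
                        cn_events = default_cn_events(),
                        array_sites = 4000L,
                        array_homref_fraction = 0.5,
                        genes = NULL,
                        config = scope_config()) {
  af_model <- match.arg(af_model)
  n_samples <- as.integer(n_samples)
  if (n_samples < 1) abort("cohort_spec: n_samples must be >= 1")
  if (length(sample_ids) != n_samples) {
    sample_ids <- sprintf("S%02d", seq_len(n_samples))
  }
  if (!setequal(names(spectrum_weights), SPECTRUM_LEVELS)) {
    abort("cohort_spec: spectrum_weights must be named by the six collapsed classes")
  }
  spectrum_weights <- spectrum_weights[SPECTRUM_LEVELS]
  if (any(spectrum_weights < 0) || abs(sum(spectrum_weights) - 1) > 1e-9) {
    abort("cohort_spec: spectrum_weights must be non-negative and sum to 1")
  }
  for (f in c(novel_fraction, coding_fraction, het_fraction, in_house_fraction,
              array_homref_fraction)) {
    if (f < 0 || f > 1) abort("cohort_spec: fractions must be in [0, 1]")
  }
  if (!setequal(names(consequence_probs), c("missense", "nonsense", "synonymous"))) {
    abort("cohort_spec: consequence_probs must cover missense/nonsense/synonymous")
  }
  if (abs(sum(consequence_probs) - 1) > 1e-9) {
    abort("cohort_spec: consequence_probs must sum to 1")
  }
  structure(list(
    n_samples = n_samples, sample_ids = sample_ids,
    n_variants = as.integer(n_variants), seed = as.integer(seed),
    spectrum_weights = spectrum_weights,
    novel_fraction = novel_fraction, coding_fraction = coding_fraction,
    het_fraction = het_fraction,
    consequence_probs = consequence_probs[c("missense", "nonsense", "synonymous")],
    in_house_fraction = in_house_fraction,
    depth_mu = depth_mu, depth_size = depth_size,
    quality_meanlog = quality_meanlog, quality_sdlog = quality_sdlog,
    af_model = af_model, af_shape1 = af_shape1, af_shape2 = af_shape2,
    drivers = drivers, cn_events = cn_events,
    array_sites = as.integer(array_sites),
    array_homref_fraction = array_homref_fraction,
    genes = genes, config = as_scope_config(config)
  ), class = "cohort_spec")
}

chrom_lengths <- function(genes) {
  agg <- stats::aggregate(end ~ chrom, data = genes[c("chrom", "end")], FUN = max)
  tibble(chrom = agg$chrom, length = as.integer(agg$end + 50000L))
}

# Draw n coding positions uniformly over all CDS base pairs.
draw_coding_positions <- function(n, cds) {
  widths <- cds$end - cds$start + 1L
  cum <- cumsum(widths)
  u <- sample.int(cum[length(cum)], n, replace = TRUE)
  i <- findInterval(u - 1L, c(0L, cum), rightmost.closed = FALSE)
  tibble(chrom = cds$chrom[i], pos = cds$start[i] + (u - 1L - c(0L, cum)[i]),
         gene_id = cds$gene_id[i])
}

# Draw n positions outside every CDS interval (intergenic or intronic).
draw_noncoding_positions <- function(n, cds, chroms) {
  out_chrom <- character(0); out_pos <- integer(0)
  need <- n
  while (need > 0) {
    i <- sample.int(nrow(chroms), need, replace = TRUE)
    chrom <- chroms$chrom[i]
    pos <- as.integer(floor(runif(need, 1, chroms$length[i] + 1)))
    bad <- positions_in_regions(chrom, pos, cds)
    out_chrom <- c(out_chrom, chrom[!bad]); out_pos <- c(out_pos, pos[!bad])
    need <- n - length(out_pos)
  }
  tibble(chrom = out_chrom[seq_len(n)], pos = out_pos[seq_len(n)],
         gene_id = NA_character_)
}

draw_alt_reads <- function(depth, het, spec) {
  alt <- depth  # homozygous: every sampled read carries the alternate allele
  if (any(het)) {
    d <- depth[het]
    alt[het] <- switch(spec$af_model,
      betabinom = rbinom(length(d), d, rbeta(length(d), spec$af_shape1, spec$af_shape2)),
      binomial = rbinom(length(d), d, 0.5),
      exact = NA_integer_
    )
  }
  alt
}

generate_sample_variants <- function(spec, sid, genes, cds, chroms, blacklist) {
  n <- spec$n_variants
  novel <- runif(n) < spec$novel_fraction
  coding <- runif(n) < spec$coding_fraction
  n_cod <- sum(coding)
  loc <- empty_variants()[, c("chrom", "pos", "gene_id")]
  loc_cod <- if (n_cod > 0) draw_coding_positions(n_cod, cds) else NULL
  loc_non <- if (n - n_cod > 0) draw_noncoding_positions(n - n_cod, cds, chroms) else NULL
  loc <- tibble(chrom = character(n), pos = integer(n), gene_id = NA_character_)
  if (n_cod > 0) loc[coding, ] <- loc_cod
  if (n - n_cod > 0) loc[!coding, ] <- loc_non

  cls <- sample(SPECTRUM_LEVELS, n, replace = TRUE, prob = spec$spectrum_weights)
  member <- sample.int(2L, n, replace = TRUE)
  ra <- t(mapply(function(cl, m) SPECTRUM_MEMBERS[[cl]][[m]], cls, member))

  het <- runif(n) < spec$het_fraction
  depth <- pmax(1L, rnbinom(n, size = spec$depth_size, mu = spec$depth_mu))
  quality <- round(rlnorm(n, spec$quality_meanlog, spec$quality_sdlog), 1)
  alt_reads <- draw_alt_reads(depth, het, spec)
  af <- if (spec$af_model == "exact") ifelse(het, 0.5, 1) else alt_reads / depth

  cons <- character(n)
  cons[coding] <- sample(names(spec$consequence_probs), n_cod, replace = TRUE,
                         prob = spec$consequence_probs)
  cons[!coding] <- "noncoding"
  in_house <- novel & runif(n) < spec$in_house_fraction

  tibble(
    sample_id = sid, chrom = loc$chrom, pos = loc$pos,
    ref = unname(ra[, 1]), alt = unname(ra[, 2]),
    depth = as.integer(depth), quality = quality, af = af,
    known = !novel, in_house = in_house,
    gene_id = loc$gene_id, consequence = cons,
    zygosity_truth = ifelse(het, "heterozygous", "homozygous")
  )
}

driver_records <- function(spec, genes) {
  if (is.null(spec$drivers) || nrow(spec$drivers) == 0) {
    return(NULL)
  }
  cat <- synthetic_catalogue(genes)
  d <- spec$drivers
  miss <- setdiff(d$gene_id, genes$gene_id)
  if (length(miss) > 0) {
    abort(sprintf("drivers reference gene(s) outside the gene model: %s",
                  paste(unique(miss), collapse = ", ")))
  }
  k <- match(d$gene_id, cat$gene_id)
  if (anyNA(k)) {
    abort("drivers must target genes present in the synthetic catalogue")
  }
  depth <- 60L
  tibble(
    sample_id = d$sample_id, chrom = cat$chrom[k], pos = cat$pos[k],
    ref = cat$ref_allele[k], alt = cat$alt_allele[k],
    depth = depth, quality = 500,
    af = ifelse(d$zygosity == "homozygous", 1, 0.5),
    known = FALSE, in_house = FALSE,
    gene_id = d$gene_id, consequence = "missense",
    zygosity_truth = d$zygosity
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Deterministically (given `spec$seed`) generates the full input bundle the
#' pipeline consumes — per-sample variant calls, known-sites and in-house
#' catalogues, array genotypes with WES-side evidence, copy-number segments,
#' gene model, blacklist, cancer catalogues and curated gene list — together
#' with per-variant ground truth (`zygosity_truth`, `should_pass_filter`).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `melanoma_cohort`: a list with elements
#'   `spec`, `genes`, `blacklist`, `variants` (including truth columns),
#'   `known_sites`, `in_house_sites`, `array_genotypes`, `array_wes`,
#'   `segments`, `catalogue`, `cosmic_deleted`, `curated_genes`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_variants = 200, array_sites = 100, seed = 7))
#' dplyr::count(cohort$variants, sample_id)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  genes <- if (is.null(spec$genes)) synthetic_gene_model() else spec$genes
  validate_gene_model(genes)
  cds <- unnest_cds(genes)
  chroms <- chrom_lengths(genes)
  blacklist <- synthetic_blacklist(genes)
  cfg <- spec$config

  with_seed(spec$seed, {
    vars <- lapply(spec$sample_ids, function(sid) {
      generate_sample_variants(spec, sid, genes, cds, chroms, blacklist)
    })
    vars <- bind_rows(vars)

    drv <- driver_records(spec, genes)
    if (!is.null(drv)) {
      # clear random variants colliding with driver positions, then inject
      drv_key <- unique(paste(drv$chrom, drv$pos))
      vars <- vars[!(paste(vars$chrom, vars$pos) %in% drv_key), , drop = FALSE]
      vars <- bind_rows(vars, drv)
    }
    vars <- vars[!duplicated(vars[c("sample_id", "chrom", "pos")]), , drop = FALSE]
    vars <- arrange(vars, .data$sample_id, .data$chrom, .data$pos)

    vars$should_pass_filter <-
      !vars$known & !vars$in_house &
      vars$consequence %in% CODING_CONSEQUENCES &
      !positions_in_regions(vars$chrom, vars$pos, blacklist) &
      vars$depth >= cfg$min_depth &
      vars$quality > cfg$min_quality &
      vars$af > cfg$min_af

    known_sites <- distinct(vars[vars$known, c("chrom", "pos", "ref", "alt")])
    in_house_sites <- distinct(vars[vars$in_house, c("chrom", "pos", "ref", "alt")])

    arr <- generate_array_block(spec, vars, chroms)
    segments <- build_cn_segments(spec, genes, chroms)

    structure(list(
      spec = spec, genes = genes, blacklist = blacklist,
      variants = as_tibble(vars),
      known_sites = known_sites, in_house_sites = in_house_sites,
      array_genotypes = arr$array, array_wes = arr$wes,
      segments = segments,
      catalogue = synthetic_catalogue(genes),
      cosmic_deleted = cosmic_deleted_gene_set(),
      curated_genes = melanoma_gene_list()
    ), class = "melanoma_cohort")
  })
}

generate_array_block <- function(spec, vars, chroms) {
  if (spec$array_sites == 0) {
    empty_arr <- tibble(sample_id = character(), chrom = character(),
                        pos = integer(), genotype = character(),
                        ref = character(), alt = character())
    empty_wes <- tibble(sample_id = character(), chrom = character(),
                        pos = integer(), depth = integer(), af = numeric(),
                        ref = character(), alt = character())
    return(list(array = empty_arr, wes = empty_wes))
  }
  out_arr <- list(); out_wes <- list()
  n_hr <- as.integer(round(spec$array_sites * spec$array_homref_fraction))
  n_var <- spec$array_sites - n_hr
  for (sid in spec$sample_ids) {
    sv <- vars[vars$sample_id == sid, , drop = FALSE]
    if (n_var > nrow(sv)) {
      abort("array_sites exceeds the number of available variant positions")
    }
    pick <- sv[sort(sample.int(nrow(sv), n_var)), , drop = FALSE]
    geno <- ifelse(pick$zygosity_truth == "heterozygous", "het", "hom_alt")
    arr_v <- tibble(sample_id = sid, chrom = pick$chrom, pos = pick$pos,
                    genotype = geno, ref = pick$ref, alt = pick$alt)
    wes_v <- tibble(sample_id = sid, chrom = pick$chrom, pos = pick$pos,
                    depth = pick$depth, af = pick$af,
                    ref = pick$ref, alt = pick$alt)
    hr <- draw_noncoding_positions(n_hr, sv[c("chrom", "pos")] |>
                                     mutate(start = .data$pos, end = .data$pos,
                                            gene_id = NA_character_) |>
                                     select("gene_id", "chrom", "start", "end"),
                                   chroms)
    hr <- hr[!duplicated(paste(hr$chrom, hr$pos)), , drop = FALSE]
    n_h <- nrow(hr)
    ref <- sample(DNA_BASES, n_h, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    arr_h <- tibble(sample_id = sid, chrom = hr$chrom, pos = hr$pos,
                    genotype = "hom_ref", ref = ref, alt = unname(alt))
    wes_h <- tibble(sample_id = sid, chrom = hr$chrom, pos = hr$pos,
                    depth = as.integer(rnbinom(n_h, size = spec$depth_size,
                                               mu = spec$depth_mu)),
                    af = 0, ref = ref, alt = unname(alt))
    out_arr[[sid]] <- bind_rows(arr_v, arr_h)
    out_wes[[sid]] <- bind_rows(wes_v, wes_h)
  }
  list(
    array = arrange(bind_rows(out_arr), .data$sample_id, .data$chrom, .data$pos),
    wes = arrange(bind_rows(out_wes), .data$sample_id, .data$chrom, .data$pos)
  )
}

#' Generate array genotypes for an existing variant table
#'
#' Standalone surface over the array block of the generator: array sites
#' overlap a subset of each sample's variant positions plus
#' homozygous-reference sites, and the array call equals the truth genotype
#' (the array is treated as the gold standard).
#'
#' @param spec A [cohort_spec()].
#' @param variants Variant tibble carrying a `zygosity_truth` column.
#' @return A list with `array` (array genotype calls) and `wes` (WES-side
#'   depth and allele-fraction evidence at the same sites).
#' @export
generate_array_genotypes <- function(spec, variants) {
  stopifnot(inherits(spec, "cohort_spec"))
  genes <- if (is.null(spec$genes)) synthetic_gene_model() else spec$genes
  with_seed(spec$seed + 1L, generate_array_block(spec, variants, chrom_lengths(genes)))
}

build_cn_segments <- function(spec, genes, chroms) {
  ev <- spec$cn_events
  out <- list()
  if (!is.null(ev) && nrow(ev) > 0) {
    miss <- setdiff(ev$gene_id, genes$gene_id)
    if (length(miss) > 0) {
      abort(sprintf("cn_events reference gene(s) outside the gene model: %s",
                    paste(unique(miss), collapse = ", ")))
    }
    k <- match(ev$gene_id, genes$gene_id)
    ev <- tibble(sample_id = ev$sample_id, chrom = genes$chrom[k],
                 start = pmax(1L, genes$start[k] - 5000L),
                 end = genes$end[k] + 5000L, cn = ev$cn)
  } else {
    ev <- tibble(sample_id = character(), chrom = character(),
                 start = integer(), end = integer(), cn = numeric())
  }
  for (sid in spec$sample_ids) {
    for (ci in seq_len(nrow(chroms))) {
      cur <- chroms$chrom[ci]; len <- chroms$length[ci]
      e <- ev[ev$sample_id == sid & ev$chrom == cur, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)])) {
        abort(sprintf("overlapping cn_events for %s on %s", sid, cur))
      }
      starts <- c(1L, e$end + 1L); ends <- c(e$start - 1L, len)
      bg <- tibble(sample_id = sid, chrom = cur, start = starts, end = ends,
                   cn = 2)
      bg <- bg[bg$start <= bg$end, , drop = FALSE]
      seg <- bind_rows(bg, tibble(sample_id = sid, chrom = cur, start = e$start,
                                  end = e$end, cn = e$cn))
      out[[paste(sid, cur)]] <- seg
    }
  }
  validate_segments(arrange(bind_rows(out), .data$sample_id, .data$chrom,
                            .data$start))
}

#' Generate copy-number segments for a cohort specification
#'
#' Embeds the requested gene-anchored copy-number events in a diploid (cn = 2)
#' background tiling each chromosome; segments never overlap within a sample.
#'
#' @param spec A [cohort_spec()].
#' @return A validated segment tibble.
#' @export
generate_cn_segments <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  genes <- if (is.null(spec$genes)) synthetic_gene_model() else spec$genes
  build_cn_segments(spec, genes, chrom_lengths(genes))
}

#' Write a cohort bundle to disk
#'
#' Writes every component in the standard formats the readers consume:
#' one VCF per sample under `vcf/`, BED for the blacklist, and TSV for all
#' tables (including the per-variant truth table). Byte-identical across
#' repeated calls on the same cohort.
#'
#' @param cohort A `melanoma_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "melanoma_cohort"))
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  v <- cohort$variants
  for (sid in unique(v$sample_id)) {
    write_variants_vcf(v[v$sample_id == sid,
                         setdiff(names(v), c("zygosity_truth", "should_pass_filter"))],
                       file.path(dir, "vcf", paste0(sid, ".vcf")))
  }
  readr::write_tsv(v[c("sample_id", "chrom", "pos", "ref", "alt", "known",
                       "in_house", "gene_id", "consequence", "zygosity_truth",
                       "should_pass_filter")],
                   file.path(dir, "truth.tsv"), progress = FALSE)
  write_gene_model(cohort$genes, file.path(dir, "genes.tsv"))
  write_blacklist_bed(cohort$blacklist, file.path(dir, "blacklist.bed"))
  readr::write_tsv(cohort$known_sites, file.path(dir, "known_sites.tsv"), progress = FALSE)
  readr::write_tsv(cohort$in_house_sites, file.path(dir, "in_house_sites.tsv"), progress = FALSE)
  readr::write_tsv(cohort$array_genotypes, file.path(dir, "array_genotypes.tsv"), progress = FALSE)
  readr::write_tsv(cohort$array_wes, file.path(dir, "array_wes.tsv"), progress = FALSE)
  readr::write_tsv(cohort$segments, file.path(dir, "segments.tsv"), progress = FALSE)
  readr::write_tsv(cohort$catalogue, file.path(dir, "catalogue.tsv"), progress = FALSE)
  readr::write_tsv(tibble(gene_id = cohort$cosmic_deleted),
                   file.path(dir, "cosmic_deleted.tsv"), progress = FALSE)
  readr::write_tsv(cohort$curated_genes, file.path(dir, "curated_genes.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a cohort bundle from disk
#'
#' Inverse of [write_cohort()]: reads the per-sample VCFs through
#' [read_variants()], re-flags known and in-house sites from the emitted
#' catalogues, and loads every table through its validating reader.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `melanoma_cohort` list (without `spec`; with `truth` when the
#'   truth table is present).
#' @export
read_cohort <- function(dir) {
  vcfs <- sort(list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                          full.names = TRUE))
  known <- readr::read_tsv(file.path(dir, "known_sites.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  in_house <- readr::read_tsv(file.path(dir, "in_house_sites.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  variants <- bind_rows(lapply(vcfs, function(f) {
    flag_known_sites(read_variants(f), known, in_house)
  }))
  truth_path <- file.path(dir, "truth.tsv")
  structure(list(
    genes = read_gene_model(file.path(dir, "genes.tsv")),
    blacklist = read_blacklist(file.path(dir, "blacklist.bed")),
    variants = variants,
    known_sites = as_tibble(known), in_house_sites = as_tibble(in_house),
    array_genotypes = read_array_genotypes(file.path(dir, "array_genotypes.tsv")),
    array_wes = readr::read_tsv(file.path(dir, "array_wes.tsv"),
                                show_col_types = FALSE, progress = FALSE),
    segments = read_segments(file.path(dir, "segments.tsv")),
    catalogue = read_catalogue(file.path(dir, "catalogue.tsv")),
    cosmic_deleted = readr::read_tsv(file.path(dir, "cosmic_deleted.tsv"),
                                     show_col_types = FALSE, progress = FALSE)$gene_id,
    curated_genes = read_gene_list(file.path(dir, "curated_genes.tsv")),
    truth = if (file.exists(truth_path)) {
      readr::read_tsv(truth_path, show_col_types = FALSE, progress = FALSE)
    }
  ), class = "melanoma_cohort")
}

#' @export
print.melanoma_cohort <- function(x, ...) {
  cat("<melanoma_cohort>\n")
  cat(sprintf("  samples:  %s\n", paste(unique(x$variants$sample_id), collapse = ", ")))
  cat(sprintf("  variants: %d  array sites: %d  segments: %d  genes: %d\n",
              nrow(x$variants), nrow(x$array_genotypes), nrow(x$segments),
              nrow(x$genes)))
  invisible(x)
}
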