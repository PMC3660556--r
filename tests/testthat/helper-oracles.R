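# Shared fixtures (built in code) and independent brute-force oracles the
# module tests check the implementation against.

# A small deterministic gene model: three genes on two chromosomes, two CDS
# blocks each, with an intron in between.
make_test_genes <- function() {
  tibble::tibble(
    gene_id = c("G1", "G2", "G3"),
    chrom = c("chrA", "chrA", "chrB"),
    start = c(100L, 1000L, 500L),
    end = c(399L, 1299L, 799L),
    strand = c("+", "-", "+"),
    cds_starts = c("100,300", "1000,1200", "500,700"),
    cds_ends = c("199,399", "1099,1299", "599,799"),
    class_tags = c("familyX", "familyX;familyY", "")
  )
}

make_test_blacklist <- function() {
  tibble::tibble(chrom = "chrA", start = 1000L, end = 1299L, name = "bl1")
}

# Random variant records over the test gene model, roughly half inside CDS.
random_variants <- function(n, seed = 1) {
  withr::with_seed(seed, {
    genes <- make_test_genes()
    cds <- melascope:::unnest_cds(genes)
    in_cds <- runif(n) < 0.5
    pos <- integer(n)
    chrom <- character(n)
    pick <- sample.int(nrow(cds), n, replace = TRUE)
    pos[in_cds] <- mapply(function(s, e) sample(s:e, 1L),
                          cds$start[pick[in_cds]], cds$end[pick[in_cds]])
    chrom[in_cds] <- cds$chrom[pick[in_cds]]
    pos[!in_cds] <- sample(c(1:99, 400:499, 1300:2000), sum(!in_cds), replace = TRUE)
    chrom[!in_cds] <- sample(c("chrA", "chrB"), sum(!in_cds), replace = TRUE)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    tibble::tibble(
      sample_id = sample(c("s1", "s2", "s3"), n, replace = TRUE),
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
      depth = sample(0:60, n, replace = TRUE),
      quality = round(runif(n, 0, 400), 1),
      af = round(runif(n), 3),
      known = runif(n) < 0.3,
      in_house = runif(n) < 0.1,
      gene_id = NA_character_,
      consequence = sample(c("synonymous", "missense", "nonsense", "noncoding",
                             "unannotated"), n, replace = TRUE,
                           prob = c(0.25, 0.35, 0.05, 0.3, 0.05))
    )
  })
}

# Brute-force linear-scan CDS overlap: returns list(coding, gene_id).
oracle_coding <- function(chrom, pos, genes) {
  cds <- melascope:::unnest_cds(genes)
  coding <- logical(length(pos))
  gene <- rep(NA_character_, length(pos))
  for (i in seq_along(pos)) {
    for (j in seq_len(nrow(cds))) {
      if (chrom[i] == cds$chrom[j] && pos[i] >= cds$start[j] && pos[i] <= cds$end[j]) {
        coding[i] <- TRUE
        gene[i] <- cds$gene_id[j]
        break
      }
    }
  }
  list(coding = coding, gene_id = gene)
}

oracle_in_regions <- function(chrom, pos, regions) {
  hit <- logical(length(pos))
  for (i in seq_along(pos)) {
    for (j in seq_len(nrow(regions))) {
      if (chrom[i] == regions$chrom[j] && pos[i] >= regions$start[j] &&
            pos[i] <= regions$end[j]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  hit
}

# The HQ predicate evaluated independently per variant.
oracle_hq_keep <- function(variants, genes, blacklist, cfg) {
  cod <- oracle_coding(variants$chrom, variants$pos, genes)
  bl <- if (is.null(blacklist) || nrow(blacklist) == 0) {
    logical(nrow(variants))
  } else {
    oracle_in_regions(variants$chrom, variants$pos, blacklist)
  }
  !variants$known & !variants$in_house &
    cod$coding & variants$consequence %in% c("synonymous", "missense", "nonsense") &
    !bl &
    variants$depth >= cfg$min_depth &
    variants$quality > cfg$min_quality &
    variants$af > cfg$min_af
}

# Brute-force sustained-plateau scan over the defined het bins of a curve.
oracle_depth_threshold <- function(curve, level) {
  het <- curve[curve$stratum == "het" & !is.na(curve$concordance), ]
  het <- het[order(het$depth), ]
  for (i in seq_len(nrow(het))) {
    if (all(het$concordance[i:nrow(het)] >= level)) return(as.integer(het$depth[i]))
  }
  NA_integer_
}

variant_key <- function(x) paste(x$sample_id, x$chrom, x$pos, x$ref, x$alt)
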