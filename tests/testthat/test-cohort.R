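# Synthetic cohort generator: determinism, parameter recovery, driver and
# copy-number truth, and self-consistency with the downstream filter.

test_that("the same spec and seed reproduce the cohort byte for byte", {
  spec <- cohort_spec(n_variants = 200, array_sites = 100, seed = 5)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_equal(c1$variants, c2$variants)
  expect_equal(c1$array_genotypes, c2$array_genotypes)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, files))),
                   unname(tools::md5sum(file.path(d2, files))))
})

test_that("generator knobs are recovered within 3 standard errors", {
  spec <- cohort_spec(n_samples = 1, sample_ids = "s1", n_variants = 5000,
                      array_sites = 0, seed = 17,
                      drivers = default_drivers()[0, ], cn_events = default_cn_events()[0, ])
  co <- generate_cohort(spec)
  v <- co$variants
  n <- nrow(v)
  se <- function(p) sqrt(p * (1 - p) / n)

  novel <- mean(!v$known)
  expect_lt(abs(novel - spec$novel_fraction), 3 * se(spec$novel_fraction))

  coding <- mean(v$consequence %in% c("synonymous", "missense", "nonsense"))
  expect_lt(abs(coding - spec$coding_fraction), 3 * se(spec$coding_fraction))

  het <- mean(v$zygosity_truth == "heterozygous")
  expect_lt(abs(het - spec$het_fraction), 3 * se(spec$het_fraction))

  spec_frac <- mutation_spectrum(v)
  for (cl in names(spec$spectrum_weights)) {
    w <- spec$spectrum_weights[[cl]]
    obs <- spec_frac$fraction[spec_frac$class == cl]
    expect_lt(abs(obs - w), 3 * se(w))
  }
})

test_that("injected drivers appear in their carriers with the right zygosity", {
  co <- generate_cohort(cohort_spec(n_variants = 300, array_sites = 0, seed = 9))
  cat <- co$catalogue
  braf <- co$variants[co$variants$gene_id %in% "BRAF" &
                        co$variants$pos == cat$pos[cat$gene_id == "BRAF"], ]
  expect_setequal(braf$sample_id, c("Me01", "Me04", "Me08", "Me12"))
  expect_equal(braf$zygosity_truth[braf$sample_id == "Me04"], "homozygous")
  expect_true(all(braf$should_pass_filter))
  nras <- co$variants[co$variants$gene_id %in% "NRAS" &
                        co$variants$pos == cat$pos[cat$gene_id == "NRAS"], ]
  expect_equal(nras$sample_id, "Me02")
  expect_equal(nras$af, 1)
})

test_that("a driver gene outside the gene model is an error", {
  bad <- default_drivers()
  bad$gene_id[1] <- "NOT_A_GENE"
  expect_error(generate_cohort(cohort_spec(n_variants = 50, array_sites = 0,
                                           seed = 1, drivers = bad)),
               "gene model")
})

test_that("copy-number segments embed exactly the requested events in a diploid background", {
  spec <- cohort_spec(seed = 2)
  segs <- generate_cn_segments(spec)
  non_bg <- segs[segs$cn != 2, ]
  expect_equal(nrow(non_bg), nrow(default_cn_events()))
  expect_equal(validate_segments(segs), segs)
  # no events: everything diploid
  spec0 <- cohort_spec(seed = 2, cn_events = default_cn_events()[0, ])
  expect_true(all(generate_cn_segments(spec0)$cn == 2))
  # overlapping events in one sample are rejected
  ev <- tibble::tibble(sample_id = "Me01", gene_id = c("BRAF", "BRAF"), cn = c(0, 3))
  expect_error(generate_cn_segments(cohort_spec(seed = 2, cn_events = ev)),
               "overlap")
})

test_that("array sites mirror truth genotypes and zero sites give empty output", {
  spec <- cohort_spec(n_variants = 400, array_sites = 200, seed = 23)
  co <- generate_cohort(spec)
  arr <- co$array_genotypes
  v <- co$variants
  m <- dplyr::inner_join(arr, v, by = c("sample_id", "chrom", "pos"))
  expect_true(all(m$genotype == ifelse(m$zygosity_truth == "heterozygous",
                                       "het", "hom_alt")))
  expect_true(all(arr$genotype %in% c("hom_ref", "het", "hom_alt")))

  co0 <- generate_cohort(cohort_spec(n_variants = 400, array_sites = 0, seed = 23))
  expect_equal(nrow(co0$array_genotypes), 0L)

  expect_error(generate_cohort(cohort_spec(n_variants = 20, array_sites = 400,
                                           seed = 23, array_homref_fraction = 0)),
               "exceeds")
})

test_that("the downstream filter recovers exactly the should_pass_filter truth", {
  co <- generate_cohort(cohort_spec(n_variants = 1500, array_sites = 0, seed = 31))
  hq <- apply_hq_filter(co$variants, co$genes, co$blacklist, co$spec$config)
  expect_setequal(variant_key(hq$variants),
                  variant_key(co$variants[co$variants$should_pass_filter, ]))
})

test_that("spec validation catches malformed inputs", {
  expect_error(cohort_spec(spectrum_weights = c("C>T/G>A" = 1)), "named")
  w <- c("C>T/G>A" = 0.5, "C>A/G>T" = 0.2, "C>G/G>C" = 0.1, "T>C/A>G" = 0.1,
         "T>A/A>T" = 0.05, "T>G/A>C" = 0.1)  # sums to 1.05
  expect_error(cohort_spec(spectrum_weights = w), "sum to 1")
  expect_error(cohort_spec(novel_fraction = 1.2), "fractions")
  expect_error(cohort_spec(n_samples = 0), "n_samples")
})
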