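# WES-vs-array concordance: pairing rules, closed-form heterozygote
# concordance under read sampling, and sustained-plateau depth selection.

test_that("pairing follows coverage and allele-identity rules", {
  wes <- tibble::tibble(
    sample_id = "s1", chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
    depth = c(30L, 0L, 30L, 30L), af = c(0.5, 0.5, 0, 0.5),
    ref = c("A", "A", "C", "G"), alt = c("C", "C", "T", "T")
  )
  arr <- tibble::tibble(
    sample_id = "s1", chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
    genotype = c("het", "het", "hom_ref", "het"),
    ref = c("A", "A", "C", "G"), alt = c("C", "C", "T", "A")
  )
  pairs <- suppressMessages(match_sites(wes, arr))
  # pos 20 dropped (no coverage), pos 40 dropped (allele mismatch)
  expect_equal(sort(pairs$pos), c(10L, 30L))
  expect_true(all(pairs$concordant))
  expect_equal(attr(pairs, "n_allele_mismatch"), 1L)
})

test_that("noise-free cohorts give perfect concordance in every defined bin", {
  spec <- cohort_spec(n_variants = 2000, array_sites = 1200, seed = 19,
                      af_model = "exact")
  co <- generate_cohort(spec)
  pairs <- match_sites(co$array_wes, co$array_genotypes)
  curve <- concordance_by_depth(pairs, depth_bins = 1:80, min_sites = 5)
  defined <- curve[!is.na(curve$concordance), ]
  expect_gt(nrow(defined), 0)
  expect_true(all(defined$concordance == 1))
})

test_that("binomial het sampling at depth 4 reproduces the enumerated 0.875", {
  # exhaustive enumeration over the 2^4 equally likely read outcomes: only
  # all-ref and all-alt miscall under the unanimity caller
  unanimity <- scope_config(min_af = 1e-9, hom_af_cutoff = 1)
  k <- 0:4
  p_k <- choose(4, k) / 2^4
  calls <- call_genotype(k / 4, unanimity)
  expected <- sum(p_k[calls == "het"])
  expect_equal(expected, 1 - 2 * (1 / 2)^4)  # 0.875

  withr::with_seed(11, {
    pairs <- simulate_concordance_pairs(4, 20000, af_model = "binomial",
                                        config = unanimity)
  })
  mc <- mean(pairs$concordant)
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(mc - expected), 3 * se)
})

test_that("het concordance matches 1 - 2 (1/2)^d across depths; hom stays 1", {
  unanimity <- scope_config(min_af = 1e-9, hom_af_cutoff = 1)
  depths <- c(1L, 2L, 4L, 6L, 8L, 10L)
  withr::with_seed(29, {
    pairs <- simulate_concordance_pairs(depths, 10000, af_model = "binomial",
                                        config = unanimity)
  })
  curve <- concordance_by_depth(pairs, depth_bins = depths)
  het <- curve[curve$stratum == "het", ]
  for (d in depths) {
    closed <- 1 - 2 * (1 / 2)^d
    se <- sqrt(max(closed * (1 - closed), 1e-12) / 10000)
    obs <- het$concordance[het$depth == d]
    expect_lt(abs(obs - closed), 3 * se + 1e-12)
  }
  withr::with_seed(31, {
    hom <- simulate_concordance_pairs(depths, 2000, af_model = "binomial",
                                      stratum = "hom_alt", config = unanimity)
  })
  expect_true(all(hom$concordant))
})

test_that("bins below the site minimum are undefined, not zero", {
  pairs <- tibble::tibble(
    sample_id = "s", chrom = "c", pos = 1:30, depth = rep(c(5L, 6L), 15),
    array_genotype = "het", wes_genotype = "het", concordant = TRUE
  )
  curve <- concordance_by_depth(pairs, depth_bins = 5:7, min_sites = 20)
  expect_true(all(is.na(curve$concordance[curve$stratum == "het"])))
  expect_equal(curve$n[curve$stratum == "het" & curve$depth == 5], 15L)
  expect_error(concordance_by_depth(pairs[0, ]), "no pairs")
})

test_that("sustained-plateau selection matches a brute-force suffix scan", {
  mk_curve <- function(conc, depths = seq_along(conc)) {
    structure(tibble::tibble(depth = depths, stratum = "het",
                             n = 100L, concordance = conc),
              class = c("concordance_curve", "tbl_df", "tbl", "data.frame"))
  }
  # mirror of the calibration shape: crosses 0.90 at 15 and stays above
  rising <- mk_curve(c(seq(0.5, 0.89, length.out = 14), seq(0.91, 0.99,
                                                            length.out = 36)),
                     1:50)
  expect_equal(as.integer(select_depth_threshold(rising)), 15L)
  # flat at 1 from the first bin
  expect_equal(as.integer(select_depth_threshold(mk_curve(rep(1, 10)))), 1L)
  # a dip below the level after the first crossing pushes the threshold out
  dip <- mk_curve(c(0.95, 0.95, 0.85, 0.96, 0.97))
  expect_equal(as.integer(select_depth_threshold(dip)), 4L)
  # never sustained
  low <- mk_curve(rep(0.5, 10))
  expect_warning(thr <- select_depth_threshold(low), "never sustains")
  expect_true(is.na(thr))

  withr::with_seed(37, {
    for (i in 1:25) {
      conc <- round(runif(30, 0.7, 1), 3)
      conc[sample.int(30, 5)] <- NA  # undefined bins are skipped
      curve <- mk_curve(conc, depths = sort(sample.int(60, 30)))
      got <- suppressWarnings(select_depth_threshold(curve))
      expect_equal(as.integer(got), oracle_depth_threshold(curve, 0.9))
    }
  })
})

test_that("the default het model sustains the plateau from 15 reads", {
  withr::with_seed(41, {
    pairs <- simulate_concordance_pairs(1:50, 4000)
  })
  curve <- concordance_by_depth(pairs)
  thr <- select_depth_threshold(curve)
  expect_true(abs(as.integer(thr) - 15L) <= 1L)
})
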