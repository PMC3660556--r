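# Catalogue matching, curated-list screening, mutation-state annotation,
# recurrence and de novo discovery.

test_that("catalogue matching is exact-position (and exact-allele by default)", {
  cat <- tibble::tibble(gene_id = "BRAF", chrom = "chr1", pos = 100L,
                        ref_allele = "A", alt_allele = "T",
                        source_label = "melanoma")
  v <- tibble::tibble(
    sample_id = "s1", chrom = "chr1", pos = c(100L, 101L, 100L),
    ref = c("A", "A", "A"), alt = c("T", "T", "C"),
    gene_id = "BRAF", consequence = "missense"
  )
  m <- match_catalogue(v, cat)
  expect_equal(m$matched, c(TRUE, FALSE, FALSE))  # 1 bp off and wrong allele miss
  m2 <- match_catalogue(v, cat, require_allele_match = FALSE)
  expect_equal(m2$matched, c(TRUE, FALSE, TRUE))
})

test_that("reference catalogue confirmations give 13 entries over 9 genes", {
  recs <- ref_cosmic_variant_records()
  m <- match_catalogue(recs, synthetic_catalogue())
  expect_equal(sum(m$matched), 13L)
  expect_equal(dplyr::n_distinct(m$catalogue_gene[m$matched]), 9L)
})

test_that("special mutation states are flagged per definition", {
  v <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2"),
    gene_id = c("GENEA", "GENEA", "GENEB", "GENEA"),
    consequence = c("missense", "missense", "synonymous", "nonsense"),
    zygosity = c("heterozygous", "heterozygous", "heterozygous", "homozygous")
  )
  a <- annotate_states(v)
  expect_equal(a$is_truncating, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(a$is_homozygous, c(FALSE, FALSE, FALSE, TRUE))
  # both missense hits in GENEA/s1 are double-mutated; the synonymous and the
  # single-sample records are not
  expect_equal(a$is_double_mutated, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("curated screening replicates genes into each of their classes", {
  gl <- melanoma_gene_list()
  v <- tibble::tibble(
    sample_id = "s1", gene_id = c("GRM5", "BRAF", "GENE999"),
    consequence = c("missense", "missense", "missense")
  )
  sc <- screen_curated(v, gl)
  expect_equal(sort(sc$class[sc$gene_id == "GRM5"]),
               sort(c("G protein-coupled receptors", "Glutamate signalling")))
  expect_false("GENE999" %in% sc$gene_id)
  expect_equal(nrow(screen_curated(v, gl[0, ])), 0L)
  cc <- curated_class_counts(sc)
  expect_true(all(cc$n_ns >= 1))
})

test_that("recurrence matches a brute-force group-by on randomized cohorts", {
  v <- random_variants(600, seed = 61)
  v$gene_id <- sample(sprintf("G%02d", 1:15), 600, replace = TRUE)
  got <- find_recurrent(v, min_samples = 2)
  ns <- v[v$consequence %in% c("missense", "nonsense"), ]
  for (g in unique(ns$gene_id)) {
    rows <- ns[ns$gene_id == g, ]
    k <- length(unique(rows$sample_id))
    if (k >= 2) {
      expect_equal(got$n_samples[got$gene_id == g], k)
      expect_equal(got$n_ns_mutations[got$gene_id == g], nrow(rows))
    } else {
      expect_false(g %in% got$gene_id)
    }
  }
  expect_true(all(diff(got$n_samples) <= 0))
})

test_that("the de novo screen excludes catalogued and curated genes exhaustively", {
  recs <- ref_de_novo_variant_records()
  recs <- dplyr::bind_rows(recs, tibble::tibble(
    sample_id = c("Me01", "Me02"), gene_id = "BRAF", chrom = "chr0",
    pos = 1:2, consequence = "missense"
  ))
  cosmic <- unique(c(synthetic_catalogue()$gene_id, cosmic_deleted_gene_set()))
  curated <- unique(melanoma_gene_list()$gene_id)
  dn <- find_de_novo(recs, cosmic, curated)
  expect_equal(nrow(dn), 10L)
  expect_false("BRAF" %in% dn$gene_id)   # recurrent but catalogued
  for (g in dn$gene_id) {
    expect_false(g %in% cosmic)
    expect_false(g %in% curated)
  }
  ref <- ref_de_novo_genes()
  expect_setequal(dn$gene_id, ref$gene_id)
  expect_equal(dn$n_ns_mutations[order(dn$gene_id)],
               ref$n_ns[order(ref$gene_id)])
})

test_that("driver frequencies floor to printed percentages", {
  m <- ref_cosmic_mutations()
  expect_equal(driver_frequency(m, "BRAF", 6)$percent, 66L)
  expect_equal(driver_frequency(m, "NRAS", 6)$percent, 16L)
  expect_equal(driver_frequency(m, "ABSENT", 6)$percent, 0L)
  expect_error(driver_frequency(m, "BRAF", 0), "n_samples")
})

test_that("gene-pair co-occurrence is computed exactly", {
  recs <- ref_cosmic_variant_records()
  co <- co_mutated_samples(recs, "BRAF", "NRAS",
                           sample_ids = c("Me01", "Me02", "Me04", "Me05",
                                          "Me08", "Me12"))
  expect_equal(co$both, character(0))             # mutually exclusive
  expect_setequal(co$only_a, c("Me01", "Me04", "Me08", "Me12"))
  expect_equal(co$only_b, "Me02")
  expect_equal(co$neither, "Me05")
})
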