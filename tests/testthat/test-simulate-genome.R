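test_that("ancestral genome has the configured shape", {
  cfg <- tiny_config(n_chromosomes = 10, n_genes = 4216, codon_length = 5)
  g <- simulate_ancestral_genome(cfg)
  expect_equal(nrow(g$genes), 4216)
  expect_equal(dplyr::n_distinct(g$genes$chromosome), 10)
  expect_length(g$cds, 4216)
  expect_true(all(nchar(g$cds) == 15))
  # round-robin: chromosome sizes differ by at most one gene
  sizes <- table(g$genes$chromosome)
  expect_lte(diff(range(sizes)), 1)
  # truth is the identity at the start
  expect_equal(g$genes$ancestral_id, g$genes$gene_id)

  one <- simulate_ancestral_genome(tiny_config(n_chromosomes = 1,
                                               n_genes = 1))
  expect_equal(one$genes$rank, 0L)
})

test_that("ranks are consecutive from 0 and coordinates are half-open", {
  g <- simulate_ancestral_genome(tiny_config(n_genes = 21,
                                             n_chromosomes = 3))
  by_chrom <- split(g$genes, g$genes$chromosome)
  for (tbl in by_chrom) {
    expect_equal(sort(tbl$rank), seq_len(nrow(tbl)) - 1L)
  }
  expect_true(all(g$genes$start < g$genes$end))
})

test_that("no CDS contains an internal stop codon", {
  g <- simulate_ancestral_genome(tiny_config(n_genes = 50))
  aa <- vapply(g$cds, function(s) {
    paste(paleodup:::codon_aa()[paleodup:::codon_index(
      paleodup:::split_codons(s))], collapse = "")
  }, character(1))
  expect_false(any(grepl("\\*", aa)))
})

test_that("the seed contract holds", {
  cfg1 <- tiny_config(seed = 1)
  g1 <- simulate_ancestral_genome(cfg1)
  g1b <- simulate_ancestral_genome(cfg1)
  g2 <- simulate_ancestral_genome(tiny_config(seed = 2))
  expect_identical(g1, g1b)
  expect_false(identical(g1$cds, g2$cds))
  expect_equal(nrow(g1$genes), nrow(g2$genes))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_chromosomes = 0), "n_genes >= n_chromosomes")
  expect_error(sim_config(n_genes = 2, n_chromosomes = 5),
               "n_genes >= n_chromosomes")
  expect_error(sim_config(wgd_times = c(77.8, 112.1)), "decreasing")
  expect_error(sim_config(loss_prob = 1), "loss_prob")
  expect_error(sim_config(subst_rate_r = 0), "subst_rate_r")
})

test_that("a lossless WGD doubles the genome and conserves truth pairs", {
  g <- simulate_ancestral_genome(tiny_config(n_genes = 100,
                                             n_chromosomes = 2))
  g2 <- apply_wgd(g, event_age = 77.8, loss_prob = 0, seed = 9)
  expect_equal(nrow(g2$genes), 200)
  truth <- sim_truth(g2)
  expect_equal(sum(truth$event == "wgd1"), 100)
  # every ancestral locus has exactly one new copy
  expect_equal(unname(table(truth$ancestral_id)), rep(2L, 100),
               ignore_attr = TRUE)
  # chromosomes doubled too
  expect_equal(dplyr::n_distinct(g2$genes$chromosome), 4)

  g4 <- apply_wgd(g2, event_age = 50, loss_prob = 0, seed = 10)
  expect_equal(unname(table(sim_truth(g4)$ancestral_id)), rep(4L, 100),
               ignore_attr = TRUE)
})

test_that("duplicate retention follows the configured loss probability", {
  g <- simulate_ancestral_genome(tiny_config(n_genes = 1000,
                                             n_chromosomes = 2,
                                             codon_length = 5))
  g2 <- apply_wgd(g, event_age = 77.8, loss_prob = 0.2, seed = 42)
  retained <- sum(sim_truth(g2)$event == "wgd1")
  # binomial(1000, 0.8) oracle: mean 800, sd sqrt(1000*0.8*0.2) = 12.6
  expect_lt(abs(retained - 800), 3 * sqrt(1000 * 0.8 * 0.2))
  expect_error(apply_wgd(g, 77.8, loss_prob = 1), "loss_prob")
})

test_that("rearrangements shuffle structure but not gene content", {
  g <- simulate_ancestral_genome(tiny_config(n_genes = 60,
                                             n_chromosomes = 2))
  g2 <- apply_rearrangements(g, n = 5, seed = 3)
  expect_setequal(g2$genes$gene_id, g$genes$gene_id)
  expect_identical(g2$cds[sort(names(g2$cds))], g$cds[sort(names(g$cds))])
  by_chrom <- split(g2$genes, g2$genes$chromosome)
  for (tbl in by_chrom) {
    expect_equal(sort(tbl$rank), seq_len(nrow(tbl)) - 1L)
  }
})

test_that("tandem copies are rank-adjacent to their parents", {
  g <- simulate_ancestral_genome(tiny_config(n_genes = 50,
                                             n_chromosomes = 1))
  g2 <- apply_tandem(g, tandem_prob = 0.3, seed = 7)
  truth <- sim_truth(g2)
  copies <- truth[truth$event == "tandem", ]
  expect_gt(nrow(copies), 0)
  pos <- g2$genes
  for (i in seq_len(nrow(copies))) {
    r_child <- pos$rank[pos$gene_id == copies$gene_id[i]]
    r_parent <- pos$rank[pos$gene_id == copies$parent_id[i]]
    expect_equal(abs(r_child - r_parent), 1)
  }
})

test_that("simulate_lineage is a pure function of its config", {
  cfg <- tiny_config(seed = 5, n_genes = 20, loss_prob = 0.2,
                     ks_sd = 0.12)
  g1 <- simulate_lineage(cfg)
  g2 <- simulate_lineage(cfg)
  expect_identical(g1, g2)
})
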