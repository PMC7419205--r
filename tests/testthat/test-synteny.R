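make_genes <- function(n, chrom = "c1", prefix = "g") {
  tibble::tibble(
    gene_id = paste0(prefix, seq_len(n)),
    chromosome = chrom,
    rank = seq_len(n) - 1L,
    start = (seq_len(n) - 1L) * 1000L,
    end = (seq_len(n) - 1L) * 1000L + 500L,
    strand = "+"
  )
}

hit <- function(q, s, score = 100) {
  tibble::tibble(qseqid = q, sseqid = s, bitscore = score)
}

test_that("find_anchors keeps reciprocal hits and drops self-hits", {
  ga <- make_genes(3, prefix = "a")
  gb <- make_genes(3, prefix = "b")
  a <- find_anchors(ga, gb, hit("a1", "b1"))
  expect_equal(nrow(a), 1)
  expect_equal(a$gene_a, "a1")
  expect_equal(a$gene_b, "b1")

  self <- find_anchors(ga, ga, hit("a1", "a1"))
  expect_equal(nrow(self), 0)

  expect_error(find_anchors(ga, gb, hit("a1", "zz")), "zz")
})

test_that("find_anchors applies the top-k score cut (sort oracle)", {
  ga <- make_genes(1, prefix = "q")
  gb <- make_genes(10, prefix = "s")
  hits <- hit(rep("q1", 10), paste0("s", 1:10), score = c(5, 90, 40, 70, 10,
                                                          95, 60, 20, 80, 30))
  a <- find_anchors(ga, gb, hits, top_k = 5)
  expect_equal(nrow(a), 5)
  expect_setequal(a$score, sort(hits$bitscore, decreasing = TRUE)[1:5])

  strict <- find_anchors(ga, gb, hits, top_k = 5, min_score = 85)
  expect_setequal(strict$score, c(90, 95))
})

test_that("a perfect diagonal chains into a single block", {
  ga <- make_genes(6, prefix = "a")
  gb <- make_genes(6, prefix = "b")
  anchors <- tibble::tibble(gene_a = paste0("a", 1:6),
                            gene_b = paste0("b", 1:6), score = 50)
  blocks <- chain_blocks(anchors, ga, gb, min_anchors = 5)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$n_anchors, 6)
  expect_equal(blocks$orientation, "same")
  expect_equal(blocks$score, 6)

  short <- chain_blocks(anchors[1:4, ], ga, gb, min_anchors = 5)
  expect_equal(nrow(short), 0)
})

test_that("inverted diagonals are chained with inverted orientation", {
  ga <- make_genes(6, prefix = "a")
  gb <- make_genes(6, prefix = "b")
  anchors <- tibble::tibble(gene_a = paste0("a", 1:6),
                            gene_b = paste0("b", 6:1), score = 50)
  blocks <- chain_blocks(anchors, ga, gb, min_anchors = 5)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$orientation, "inverted")
  expect_equal(blocks$n_anchors, 6)
})

test_that("chaining matches the exhaustive enumeration oracle", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      n <- sample(8:16, 1)
      ra <- sample(0:30, n)
      rb <- sample(0:30, n)
    })
    ga <- make_genes(31, prefix = "a")
    gb <- make_genes(31, prefix = "b")
    anchors <- tibble::tibble(gene_a = paste0("a", ra + 1),
                              gene_b = paste0("b", rb + 1), score = 1)
    best <- paleodup:::best_chain(ra, rb, "same", max_gap = 25)
    best_inv <- paleodup:::best_chain(ra, rb, "inverted", max_gap = 25)
    expect_equal(max(best$score, best_inv$score),
                 oracle_best_chain_score(ra, rb, max_gap = 25))
  }
})

test_that("max_gap splits distant runs into separate blocks", {
  ga <- make_genes(60, prefix = "a")
  gb <- make_genes(60, prefix = "b")
  idx <- c(1:6, 41:46)  # two diagonal runs separated by > max_gap
  anchors <- tibble::tibble(gene_a = paste0("a", idx),
                            gene_b = paste0("b", idx), score = 10)
  blocks <- chain_blocks(anchors, ga, gb, min_anchors = 5, max_gap = 25)
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$n_anchors, c(6, 6))
})

test_that("duplicate classes partition pairs with block precedence", {
  g <- make_genes(30)
  anchors <- tibble::tibble(
    gene_a = c("g8", "g2", "g1", "g5"),
    gene_b = c("g9", "g7", "g20", "g6"),
    score = 10
  )
  # g5-g6 sits inside a synthetic block; classify must rank block
  # membership above rank adjacency
  blocks <- tibble::tibble(
    block_id = "block_0001", chrom_a = "c1", chrom_b = "c1",
    orientation = "same", n_anchors = 5L, score = 5,
    anchors = list(tibble::tibble(gene_a = paste0("g", 3:7),
                                  gene_b = paste0("g", 4:8),
                                  rank_a = 2:6, rank_b = 3:7))
  )
  cl <- classify_duplications(g, anchors, blocks)
  expect_equal(nrow(cl), 4)
  got <- stats::setNames(as.character(cl$class),
                         paste(cl$gene_a, cl$gene_b))
  expect_equal(got[["g8 g9"]], "tandem")
  expect_equal(got[["g2 g7"]], "proximal")
  expect_equal(got[["g1 g20"]], "dispersed")
  expect_equal(got[["g5 g6"]], "wgd_segmental")
  expect_false(anyNA(cl$class))
})

test_that("a genome against itself has depth ratio 1:1", {
  cfg <- tiny_config(seed = 2, n_genes = 60, n_chromosomes = 2,
                     wgd_times = numeric(0))
  pair <- simulate_lineage_pair(cfg, numeric(0), numeric(0))
  hits <- homology_hits(pair$a$cds, pair$b$cds)
  anchors <- find_anchors(pair$a$genes, pair$b$genes, hits)
  blocks <- chain_blocks(anchors, pair$a$genes, pair$b$genes)
  dp <- syntenic_depth(blocks, pair$a$genes, pair$b$genes)
  expect_equal(dp$modal_depth_a, 1)
  expect_equal(dp$modal_depth_b, 1)
})

test_that("no blocks gives an all-zero profile", {
  g <- make_genes(10)
  dp <- syntenic_depth(paleodup:::empty_blocks(), g, g)
  expect_equal(dp$modal_depth_a, 0)
  expect_equal(dp$ratio_label, "0:0")
})

test_that("WGD count drives the modal depth of a sister comparison", {
  cfg <- tiny_config(seed = 6, n_genes = 300, n_chromosomes = 2,
                     loss_prob = 0.2, codon_length = 30)
  depth_after <- function(wgd_b) {
    pair <- simulate_lineage_pair(cfg, numeric(0), wgd_b)
    hits <- homology_hits(pair$a$cds, pair$b$cds)
    anchors <- find_anchors(pair$a$genes, pair$b$genes, hits)
    blocks <- chain_blocks(anchors, pair$a$genes, pair$b$genes)
    syntenic_depth(blocks, pair$a$genes, pair$b$genes)
  }
  one <- depth_after(77.8)
  two <- depth_after(c(112.1, 77.8))
  expect_equal(one$modal_depth_a, 2)  # 1:2 against a one-WGD sister
  expect_equal(one$modal_depth_b, 1)
  expect_equal(two$modal_depth_a, 4)  # 1:4 against a two-WGD sister
  expect_equal(two$modal_depth_b, 1)
  # depth monotonicity: an extra WGD never lowers the sister's modal depth
  expect_gte(two$modal_depth_a, one$modal_depth_a)
})

test_that("blocks are symmetric under genome swap", {
  cfg <- tiny_config(seed = 9, n_genes = 80, n_chromosomes = 2,
                     loss_prob = 0.2)
  pair <- simulate_lineage_pair(cfg, numeric(0), 77.8)
  hits <- homology_hits(pair$a$cds, pair$b$cds)
  anchors_ab <- find_anchors(pair$a$genes, pair$b$genes, hits)
  anchors_ba <- dplyr::rename(anchors_ab, gene_a = "gene_b",
                              gene_b = "gene_a")
  b_ab <- chain_blocks(anchors_ab, pair$a$genes, pair$b$genes)
  b_ba <- chain_blocks(anchors_ba, pair$b$genes, pair$a$genes)
  expect_equal(nrow(b_ab), nrow(b_ba))
  pairs_ab <- blocks_to_table(b_ab)
  pairs_ba <- blocks_to_table(b_ba)
  expect_setequal(paste(pairs_ab$gene_a, pairs_ab$gene_b),
                  paste(pairs_ba$gene_b, pairs_ba$gene_a))
})
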