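test_that("NG86 counts match the hand-computed oracle", {
  # A = (TTT)x10 vs B = (TTT)x9 + TTC: Phe third positions carry 1/3 of a
  # synonymous site each (only T->C is silent), so S = 10/3, Sd = 1,
  # ps = 0.3, ks = -0.75 ln(0.6), ka = 0.
  est <- kaks_pair(strrep("TTT", 10), paste0(strrep("TTT", 9), "TTC"))
  expect_equal(est$S, 10 / 3)
  expect_equal(est$N, 30 - 10 / 3)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$ps, 0.3)
  expect_equal(est$ks, -0.75 * log(0.6))
  expect_equal(est$ka, 0)
  expect_false(est$saturated)
})

test_that("NG86 handles multi-position codon differences by pathway averaging", {
  # GCT (Ala) vs GTA (Val): positions 2 and 3 differ; the two minimal
  # pathways pass through GTT (Val) or GCA (Ala), neither a stop:
  #  GCT->GTT (nonsyn) ->GTA (syn); GCT->GCA (syn) ->GTA (nonsyn)
  # so Sd = Nd = 1.
  est <- kaks_pair("GCT", "GTA")
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 1)
})

test_that("identical sequences give zero divergence", {
  cds <- random_sense_cds(40, seed = 2)
  est <- kaks_pair(cds, cds)
  expect_equal(est$Sd, 0)
  expect_equal(est$ks, 0)
  expect_equal(est$ka, 0)
})

test_that("NG86 is symmetric and conserves sites", {
  for (seed in 1:5) {
    a <- random_sense_cds(30, seed = seed)
    b <- paleodup:::idx_to_seq(
      paleodup:::mutate_n(paleodup:::seq_to_idx(a), 10))
    ab <- kaks_pair(a, b)
    ba <- kaks_pair(b, a)
    expect_equal(ab, ba)
    expect_identical(ab$S + ab$N, 3 * ab$n_codons)
  }
})

test_that("randomised third positions saturate the synonymous estimate", {
  # All-Ala codons: every third position is four-fold degenerate, so
  # forcing each one to a different base drives ps to 1.
  withr::with_seed(1, {
    third <- sample(c("T", "C", "A", "G"), 100, replace = TRUE)
    other <- vapply(third, function(b) sample(setdiff(c("T", "C", "A", "G"),
                                                      b), 1), character(1))
    a <- paste(paste0("GC", third), collapse = "")
    b <- paste(paste0("GC", other), collapse = "")
  })
  est <- kaks_pair(a, b)
  expect_true(est$saturated)
  expect_true(is.na(est$ks))
  expect_gte(est$ps, 0.75)
})

test_that("mean estimated Ks recovers targets across the clock range", {
  # targets 0.1 / 0.3 / 0.655 correspond to 2rT at increasing event ages
  for (target in c(0.1, 0.3, 0.655)) {
    ks <- vapply(1:25, function(s) {
      a <- paleodup:::seq_to_idx(random_sense_cds(200, seed = 100 + s))
      b <- withr::with_seed(200 + s,
                            paleodup:::mutate_to_target(a, a, target))
      ng86_kaks(list(aln_a = paleodup:::idx_to_seq(a),
                     aln_b = paleodup:::idx_to_seq(b)))$ks
    }, numeric(1))
    expect_lt(abs(mean(ks) - target), 0.02)
  }
})

test_that("codon alignment back-translates protein gaps", {
  a <- "ATGGCTAAAGGT"
  aln0 <- align_codons(a, a)
  expect_equal(aln0$aln_a, aln0$aln_b)
  expect_false(grepl("-", aln0$aln_a))

  b <- "ATGGCTGGT"  # AAA codon deleted
  aln <- align_codons(a, b)
  expect_equal(nchar(aln$aln_b), 12)
  expect_equal(stringr::str_count(aln$aln_b, "-"), 3)
  expect_equal(aln$n_codons_compared, 3)
  gaps <- gregexpr("-+", aln$aln_b)[[1]]
  expect_equal(attr(gaps, "match.length"), 3)  # one whole-codon gap

  expect_error(align_codons("ATGTAAGGT", a), "stop")
  expect_error(align_codons("ATGG", a), "multiple of 3")
})

test_that("protein alignment score matches an independent Gotoh oracle", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  for (seed in 1:4) {
    a <- random_sense_cds(50, seed = 300 + seed)
    b <- random_sense_cds(48, seed = 400 + seed)
    aln <- align_codons(a, b)
    pa <- paleodup:::translate_cds(a, "a")
    pb <- paleodup:::translate_cds(b, "b")
    expect_equal(aln$score, oracle_nw_score(pa, pb, BLOSUM62))
  }
})

test_that("kaks_table emits one deterministic row per anchor pair", {
  cfg <- tiny_config(seed = 4, n_chromosomes = 1, n_genes = 12,
                     wgd_times = 30, codon_length = 60)
  g <- simulate_lineage(cfg)
  hits <- homology_hits(g$cds)
  anchors <- find_anchors(g$genes, g$genes, hits)
  blocks <- chain_blocks(anchors, g$genes, g$genes, min_anchors = 5)
  expect_gt(nrow(blocks), 0)
  tbl <- kaks_table(blocks, g$cds)
  expect_equal(nrow(tbl), sum(blocks$n_anchors))
  expect_identical(tbl, kaks_table(blocks, g$cds))
  expect_error(kaks_table(blocks, g$cds[-1]), "missing")
})
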