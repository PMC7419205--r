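# Shared fixtures and independent oracles used across test files.

tiny_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2, n_genes = 40,
                   wgd_times = 77.8, subst_rate_r = 4.21e-9, ks_sd = 0,
                   loss_prob = 0, n_rearrangements = 0, tandem_prob = 0,
                   codon_length = 30)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Exhaustive best-chain oracle: depth-first enumeration of every collinear
# chain under the same gap constraint and scoring rule (anchors - 0.5 per
# gapped step), independent of the package's dynamic programme.
oracle_best_chain_score <- function(rank_a, rank_b, max_gap = 25) {
  n <- length(rank_a)
  best <- -Inf
  for (orient in c(1, -1)) {
    rb <- orient * rank_b
    extend <- function(last, score) {
      best <<- max(best, score)
      for (j in seq_len(n)) {
        da <- rank_a[j] - rank_a[last]
        db <- rb[j] - rb[last]
        if (da <= 0 || db <= 0 || da > max_gap || db > max_gap) next
        extend(j, score + 1 - 0.5 * (da > 1 || db > 1))
      }
    }
    for (s in seq_len(n)) extend(s, 1)
  }
  best
}

# Gotoh affine-gap global alignment score, written independently of
# Biostrings, for protein strings under a supplied substitution matrix.
oracle_nw_score <- function(a, b, submat, gap_open = 10, gap_ext = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -gap_open - i * gap_ext
  for (j in seq_len(m)) Iy[1, j + 1] <- -gap_open - j * gap_ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                              Ix[i, j + 1] - gap_ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                              Iy[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Random sense-codon CDS for alignment/Ka-Ks tests.
random_sense_cds <- function(n_codons, seed) {
  withr::with_seed(seed, {
    sense <- paleodup:::codon_strings()[paleodup:::codon_aa() != "*"]
    paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  })
}

# Inverse of the Jukes-Cantor correction: the mismatch proportion that maps
# to distance K.
jc_lambda <- function(K) 0.75 * (1 - exp(-4 * K / 3))
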