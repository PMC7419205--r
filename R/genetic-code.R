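# Standard-genetic-code lookup tables used by the NG86 estimator and by the
# synonymous-substitution simulator. Everything is precomputed once per
# session and cached: per-codon synonymous site fractions, and 64 x 64
# pathway-averaged synonymous/nonsynonymous difference matrices.

the <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

#' @noRd
codon_strings <- function() {
  if (is.null(the$codons)) {
    g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES, stringsAsFactors = FALSE)
    the$codons <- paste0(g$p1, g$p2, g$p3)
  }
  the$codons
}

#' @noRd
codon_aa <- function() {
  if (is.null(the$aa)) {
    gc <- Biostrings::GENETIC_CODE
    the$aa <- unname(gc[codon_strings()])
  }
  the$aa
}

codon_index <- function(codons) match(codons, codon_strings())

is_stop_codon <- function(idx) codon_aa()[idx] == "*"

# Single-nucleotide neighbours of codon `idx` at position `pos` (three of them).
codon_neighbours <- function(idx, pos) {
  cod <- codon_strings()[idx]
  base <- substr(cod, pos, pos)
  vapply(setdiff(BASES, base), function(b) {
    out <- cod
    substr(out, pos, pos) <- b
    match(out, codon_strings())
  }, integer(1))
}

# Fraction of synonymous sites per codon (NG86): at each position the fraction
# of the three possible single-nucleotide changes that preserve the amino
# acid, summed over positions. Changes to stop codons count as nonsynonymous.
# Stop codons themselves get NA and are excluded upstream.
#' @noRd
syn_site_counts <- function() {
  if (is.null(the$syn_sites)) {
    aa <- codon_aa()
    s <- vapply(seq_len(64), function(i) {
      if (aa[i] == "*") return(NA_real_)
      sum(vapply(1:3, function(pos) {
        nb <- codon_neighbours(i, pos)
        mean(aa[nb] == aa[i])
      }, numeric(1)))
    }, numeric(1))
    the$syn_sites <- s
  }
  the$syn_sites
}

# Pathway-averaged synonymous / nonsynonymous difference counts for every
# codon pair. All minimal substitution pathways between the two codons are
# enumerated; pathways passing through a stop codon are excluded (if every
# pathway is blocked, all are used -- the standard fallback). Pairs involving
# a stop codon are NA.
#' @noRd
diff_matrices <- function() {
  if (!is.null(the$sd_mat)) {
    return(list(sd = the$sd_mat, nd = the$nd_mat))
  }
  aa <- codon_aa()
  cods <- codon_strings()
  sd_mat <- matrix(NA_real_, 64, 64)
  nd_mat <- matrix(NA_real_, 64, 64)

  step_codon <- function(idx, pos, base) {
    out <- cods[idx]
    substr(out, pos, pos) <- base
    match(out, cods)
  }

  for (i in seq_len(64)) {
    if (aa[i] == "*") next
    sd_mat[i, i] <- 0
    nd_mat[i, i] <- 0
    for (j in seq_len(64)) {
      if (j <= i || aa[j] == "*") next
      ci <- cods[i]; cj <- cods[j]
      pos <- which(strsplit(ci, "")[[1]] != strsplit(cj, "")[[1]])
      perms <- permutations(pos)
      path_sd <- numeric(0)
      path_nd <- numeric(0)
      path_ok <- logical(0)
      for (p in seq_len(nrow(perms))) {
        cur <- i
        sd <- 0; nd <- 0; ok <- TRUE
        for (pp in perms[p, ]) {
          nxt <- step_codon(cur, pp, substr(cj, pp, pp))
          if (aa[nxt] == "*") ok <- FALSE
          if (aa[nxt] == aa[cur]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        path_sd <- c(path_sd, sd)
        path_nd <- c(path_nd, nd)
        path_ok <- c(path_ok, ok)
      }
      use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_ok))
      sd_mat[i, j] <- sd_mat[j, i] <- mean(path_sd[use])
      nd_mat[i, j] <- nd_mat[j, i] <- mean(path_nd[use])
    }
  }
  the$sd_mat <- sd_mat
  the$nd_mat <- nd_mat
  list(sd = sd_mat, nd = nd_mat)
}

# All orderings of a small position vector (length 1..3).
permutations <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1, 1))
  if (n == 2) return(rbind(x, rev(x)))
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- permutations(x[-k])
    cbind(x[k], rest, deparse.level = 0)
  }))
}

# Synonymous single-nucleotide substitution options for each codon: a list of
# (pos, replacement codon index) matrices. Used by the simulator to place
# synonymous-only changes.
#' @noRd
syn_options <- function() {
  if (is.null(the$syn_opts)) {
    aa <- codon_aa()
    the$syn_opts <- lapply(seq_len(64), function(i) {
      if (aa[i] == "*") return(matrix(integer(0), 0, 2))
      out <- NULL
      for (pos in 1:3) {
        nb <- codon_neighbours(i, pos)
        syn <- nb[aa[nb] == aa[i]]
        if (length(syn)) out <- rbind(out, cbind(pos, syn))
      }
      if (is.null(out)) matrix(integer(0), 0, 2) else out
    })
  }
  the$syn_opts
}

# Jukes-Cantor multiple-hit correction of an observed proportion of
# differences; NA once the log argument is non-positive (p >= 3/4).
jc_correct <- function(p) {
  arg <- 1 - 4 * p / 3
  ifelse(arg > 0, -0.75 * log(arg), NA_real_)
}
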