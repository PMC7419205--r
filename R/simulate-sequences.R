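# Synonymous sequence divergence for simulated duplicate families.
#
# The generative model inverts the dating formula: a duplicate pair whose
# most recent common ancestor is an event of age T (years) should measure an
# NG86 Ks close to 2 r T. Substitutions are synonymous-only (single-
# nucleotide codon changes that preserve the amino acid), so Ka stays ~0 and
# Ks measurement is not confounded. Placement is *measured-target* driven:
# substitutions are added until the NG86 + Jukes-Cantor estimate against the
# reference sequence crosses the target, taking whichever side of the
# crossing is closer.

#' Diverge duplicate coding sequences toward their event-age Ks targets
#'
#' Two-copy families are diverged directly: the duplicate is mutated until
#' the measured pairwise Ks reaches a target drawn from
#' `Normal(2 r T, sd)` truncated at zero. Larger families are evolved along
#' their duplication tree with per-branch targets proportional to branch
#' time, so that every pair's divergence reflects the age of its most recent
#' common duplication event. Per-branch noise variance is proportional to
#' branch time and calibrated so a pair split at the oldest simulated event
#' has dispersion `ks_sd`.
#'
#' @param genome A `sim_genome` whose truth columns (`parent_id`,
#'   `event_age`) are populated.
#' @param config The [sim_config()] that produced it (supplies
#'   `subst_rate_r`, `ks_sd` and the RNG seed).
#' @return The genome with diverged `cds`.
#' @export
evolve_pair_sequences <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "sim_config"))
  genes <- genome$genes
  ages <- genes$event_age[!is.na(genes$event_age)]
  if (!length(ages)) return(genome)
  r_yr <- config$subst_rate_r
  t_max <- max(ages)
  if (2 * r_yr * t_max * 1e6 > 2.5) {
    stop("target Ks ", round(2 * r_yr * t_max * 1e6, 2),
         " exceeds 2.5: synonymous divergence would be saturated",
         call. = FALSE)
  }

  cds <- genome$cds
  fam <- split(seq_len(nrow(genes)), genes$ancestral_id)
  withr::with_seed(config$seed + 2L, {
    for (rows in fam) {
      if (length(rows) < 2) next
      sub <- genes[rows, , drop = FALSE]
      cds[sub$gene_id] <- evolve_family(sub, cds[sub$gene_id],
                                        r_yr, config$ks_sd, t_max)
    }
  })
  new_sim_genome(genes, cds)
}

# Evolve one duplicate family; `sub` has one row per member, `fam_cds` is the
# named CDS vector for exactly those members (all currently identical).
evolve_family <- function(sub, fam_cds, r_yr, ks_sd, t_max) {
  if (nrow(sub) == 2) {
    t_pair <- max(sub$event_age, na.rm = TRUE)
    target <- draw_ks_target(2 * r_yr * t_pair * 1e6,
                             branch_sd(ks_sd, t_pair, t_max))
    child <- which(!is.na(sub$event_age) & sub$event_age == t_pair)[1]
    idx <- seq_to_idx(fam_cds[[child]])
    fam_cds[[child]] <- idx_to_seq(mutate_to_target(idx, idx, target))
    return(fam_cds)
  }

  root <- sub$gene_id[sub$event == "none"]
  if (length(root) != 1) {
    # root copy itself was lost is impossible by construction (loss hits new
    # duplicates only), so this is a malformed truth table
    stop("family without a unique ancestral member", call. = FALSE)
  }
  kids_of <- split(sub$gene_id[!is.na(sub$parent_id)],
                   sub$parent_id[!is.na(sub$parent_id)])
  age_of <- stats::setNames(sub$event_age, sub$gene_id)
  out <- fam_cds
  t_root <- max(sub$event_age, na.rm = TRUE)
  root_idx <- seq_to_idx(fam_cds[[root]])

  # Measured-Ks calibration: the branch budgets live in substitution-count
  # space (which composes additively along the tree for this reversible
  # within-synonym-set chain), so we first record, on a throwaway copy of
  # the root sequence, the measured Ks after every placed substitution.
  # hits_at(K) then inverts that curve.
  curve <- cummax(ks_hit_curve(root_idx, 2 * r_yr * t_root * 1e6))
  hits_at <- function(t_ma) {
    if (t_ma <= 0) return(0)
    target <- 2 * r_yr * t_ma * 1e6
    idx <- findInterval(target, curve)
    min(idx + 1L, length(curve))
  }
  branch_hits <- function(t_hi, t_lo) {
    m <- (hits_at(t_hi) - hits_at(t_lo)) / 2
    sd <- branch_sd(ks_sd, t_hi - t_lo, t_max)
    if (sd > 0) {
      slope <- length(curve) / max(curve[is.finite(curve)])  # hits per unit pair-Ks
      m <- m + stats::rnorm(1, 0, sd) * slope / 2
    }
    max(0L, as.integer(round(m)))
  }

  evolve_node <- function(gene, idx, t_now) {
    kids <- kids_of[[gene]]
    kids <- kids[order(-age_of[kids])]
    for (kid in kids) {
      t_kid <- age_of[[kid]]
      idx <- mutate_n(idx, branch_hits(t_now, t_kid))
      t_now <- t_kid
      evolve_node(kid, idx, t_kid)
    }
    out[[gene]] <<- idx_to_seq(mutate_n(idx, branch_hits(t_now, 0)))
  }

  evolve_node(root, root_idx, t_root)
  out
}

# Record, on a throwaway pair of copies of `ref` evolving on alternating
# sides, the measured pairwise Ks after every placed substitution, up to
# `target`. This is the same stochastic process that generates a duplicate
# pair, so inverting the curve converts a pairwise Ks target into a total
# substitution budget for the pair.
ks_hit_curve <- function(ref, target) {
  s <- syn_site_counts()
  sd_mat <- diff_matrices()$sd
  opts <- syn_options()
  n <- length(ref)
  cur1 <- ref
  cur2 <- ref
  S <- sum(s[ref])
  Sd <- 0
  path <- numeric(0)
  max_iter <- 1000L * n
  for (iter in seq_len(max_iter)) {
    side1 <- iter %% 2L == 1L
    cur <- if (side1) cur1 else cur2
    oth <- if (side1) cur2 else cur1
    j <- sample.int(n, 1L)
    o <- opts[[cur[j]]]
    if (nrow(o) == 0L) next
    new_cod <- o[sample.int(nrow(o), 1L), 2L]
    S <- S + (s[new_cod] - s[cur[j]]) / 2
    Sd <- Sd - sd_mat[oth[j], cur[j]] + sd_mat[oth[j], new_cod]
    if (side1) cur1[j] <- new_cod else cur2[j] <- new_cod
    ks <- jc_ks(Sd, S)
    path <- c(path, if (is.na(ks)) Inf else ks)
    if (is.na(ks) || ks >= target) return(path)
  }
  stop("calibration curve did not reach Ks ", signif(target, 3),
       call. = FALSE)
}

# Apply exactly `m` random synonymous substitutions.
mutate_n <- function(idx, m) {
  if (m <= 0) return(idx)
  opts <- syn_options()
  n <- length(idx)
  placed <- 0L
  while (placed < m) {
    j <- sample.int(n, 1L)
    o <- opts[[idx[j]]]
    if (nrow(o) == 0L) next
    idx[j] <- o[sample.int(nrow(o), 1L), 2L]
    placed <- placed + 1L
  }
  idx
}

branch_sd <- function(ks_sd, dt_ma, t_max) {
  if (ks_sd <= 0 || dt_ma <= 0) 0 else ks_sd * sqrt(dt_ma / (2 * t_max))
}

# Pair-level draw: for a two-copy family both branches collapse into a single
# measured target, so the pair dispersion is sqrt(2) * branch_sd = ks_sd at
# the oldest event.
draw_ks_target <- function(mu, half_sd) {
  sd <- half_sd * sqrt(2)
  if (sd <= 0) return(max(mu, 0))
  repeat {
    x <- stats::rnorm(1, mu, sd)
    if (x >= 0) return(x)
  }
}

evolve_branch <- function(idx, r_yr, ks_sd, dt_ma, t_max) {
  if (dt_ma <= 0) return(idx)
  d <- r_yr * dt_ma * 1e6
  sd <- branch_sd(ks_sd, dt_ma, t_max)
  if (sd > 0) d <- max(stats::rnorm(1, d, sd), 0)
  mutate_to_target(idx, idx, d)
}

seq_to_idx <- function(seq) codon_index(split_codons(seq))
idx_to_seq <- function(idx) paste(codon_strings()[idx], collapse = "")

# Place random synonymous substitutions on a copy of `cur` until its NG86 Ks
# against the frozen `ref` crosses `target`; return whichever of the last
# two states is closer to the target.
mutate_to_target <- function(ref, cur, target) {
  if (target <= 0) return(cur)
  s <- syn_site_counts()
  sd_mat <- diff_matrices()$sd
  opts <- syn_options()
  n <- length(cur)
  S <- sum((s[ref] + s[cur]) / 2)
  Sd <- sum(sd_mat[cbind(ref, cur)])
  ks <- jc_ks(Sd, S)
  max_iter <- 500L * n
  for (iter in seq_len(max_iter)) {
    j <- sample.int(n, 1L)
    o <- opts[[cur[j]]]
    if (nrow(o) == 0L) next
    new_cod <- o[sample.int(nrow(o), 1L), 2L]
    S_new <- S + (s[new_cod] - s[cur[j]]) / 2
    Sd_new <- Sd - sd_mat[ref[j], cur[j]] + sd_mat[ref[j], new_cod]
    ks_new <- jc_ks(Sd_new, S_new)
    if (is.na(ks_new) || ks_new >= target) {
      apply_it <- !is.na(ks_new) && (ks_new - target) <= (target - ks)
      if (apply_it) cur[j] <- new_cod
      return(cur)
    }
    cur[j] <- new_cod
    S <- S_new; Sd <- Sd_new; ks <- ks_new
  }
  warning("synonymous divergence target ", signif(target, 3),
          " not reached after ", max_iter, " proposals")
  cur
}

jc_ks <- function(Sd, S) {
  if (S <= 0) return(0)
  jc_correct(Sd / S)
}
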