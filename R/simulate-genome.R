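#' Configuration for the synthetic-evolution simulator
#'
#' Bundles every parameter of the forward simulation: an ancestral genome is
#' built, passed through the configured whole-genome duplication (WGD)
#' events with stochastic duplicate loss, optionally rearranged and given
#' tandem copies, and finally its coding sequences are diverged so that the
#' synonymous distance (Ks) of a duplicate pair concentrates around
#' `2 * subst_rate_r * event_age` (in years), the relation inverted by the
#' dating stage.
#'
#' @param seed Integer seed; every downstream draw flows from it.
#' @param n_chromosomes,n_genes Size of the ancestral genome.
#' @param wgd_times WGD ages in Ma, strictly decreasing toward the present
#'   (oldest first). `numeric(0)` for no duplication.
#' @param subst_rate_r Synonymous substitution rate, substitutions per
#'   synonymous site per year.
#' @param ks_sd Dispersion of the target Ks around `2 r T` for a pair
#'   diverged at the oldest simulated event; younger pairs scale as
#'   `sqrt(T / T_oldest)`.
#' @param loss_prob Probability that a newly created WGD duplicate is lost,
#'   independently per gene; in `[0, 1)`.
#' @param n_rearrangements Number of chromosome fission/fusion operations
#'   applied after the duplications.
#' @param tandem_prob Per-gene probability of a tandem copy.
#' @param codon_length Codons per simulated gene.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 5L,
                       n_genes = 1000L,
                       wgd_times = c(112.1, 77.8),
                       subst_rate_r = 4.21e-9,
                       ks_sd = 0.12,
                       loss_prob = 0.2,
                       n_rearrangements = 0L,
                       tandem_prob = 0,
                       codon_length = 300L) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    n_genes = as.integer(n_genes), wgd_times = as.numeric(wgd_times),
    subst_rate_r = subst_rate_r, ks_sd = ks_sd, loss_prob = loss_prob,
    n_rearrangements = as.integer(n_rearrangements),
    tandem_prob = tandem_prob, codon_length = as.integer(codon_length)
  )
  if (cfg$n_chromosomes < 1 || cfg$n_genes < cfg$n_chromosomes) {
    stop("need n_genes >= n_chromosomes >= 1", call. = FALSE)
  }
  if (length(cfg$wgd_times) > 1 && any(diff(cfg$wgd_times) >= 0)) {
    stop("wgd_times must be strictly decreasing toward the present",
         call. = FALSE)
  }
  if (any(cfg$wgd_times <= 0)) stop("wgd_times must be positive", call. = FALSE)
  if (cfg$loss_prob < 0 || cfg$loss_prob >= 1) {
    stop("loss_prob must be in [0, 1)", call. = FALSE)
  }
  if (cfg$subst_rate_r <= 0) stop("subst_rate_r must be > 0", call. = FALSE)
  if (cfg$codon_length < 1) stop("codon_length must be >= 1", call. = FALSE)
  if (cfg$tandem_prob < 0 || cfg$tandem_prob >= 1) {
    stop("tandem_prob must be in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

GENE_SPACER <- 200L

#' Simulate an ancestral genome
#'
#' Genes are distributed round-robin across chromosomes, ranked
#' consecutively from 0 within each chromosome, and given random sense-codon
#' CDS with no internal stops. The truth mapping starts out as the identity:
#' each gene is its own ancestral locus.
#'
#' @param config A [sim_config()].
#' @return A `sim_genome`: a list with `genes` (tibble with `gene_id`,
#'   `chromosome`, `rank`, `start`, `end` (0-based half-open), `strand`,
#'   `ancestral_id`, `parent_id`, `event`, `event_age`) and `cds` (named
#'   character vector).
#' @export
#' @examples
#' g <- simulate_ancestral_genome(sim_config(seed = 1, n_chromosomes = 2,
#'                                           n_genes = 10, codon_length = 20))
#' g$genes
simulate_ancestral_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    ids <- sprintf("g%05d", seq_len(n))
    chrom <- sprintf("chr%02d", rep_len(seq_len(config$n_chromosomes), n))
    genes <- tibble::tibble(
      gene_id = ids,
      chromosome = chrom,
      strand = sample(c("+", "-"), n, replace = TRUE),
      ancestral_id = ids,
      parent_id = NA_character_,
      event = "none",
      event_age = NA_real_
    ) |>
      dplyr::arrange(.data$chromosome) |>
      dplyr::group_by(.data$chromosome) |>
      dplyr::mutate(rank = dplyr::row_number() - 1L) |>
      dplyr::ungroup()
    genes <- recompute_coordinates(genes, config$codon_length)
    cds <- random_cds(n, config$codon_length)
    names(cds) <- ids
    new_sim_genome(genes, cds)
  })
}

new_sim_genome <- function(genes, cds) {
  structure(list(genes = genes, cds = cds), class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome> ", nrow(x$genes), " genes on ",
      dplyr::n_distinct(x$genes$chromosome), " chromosomes\n", sep = "")
  invisible(x)
}

recompute_coordinates <- function(genes, codon_length) {
  len <- codon_length * 3L
  genes |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::row_number() - 1L,
      start = .data$rank * (len + GENE_SPACER),
      end = .data$start + len
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chromosome, .data$rank)
}

# Random sense-codon CDS (uniform over the 61 sense codons).
random_cds <- function(n, codon_length) {
  sense <- codon_strings()[codon_aa() != "*"]
  vapply(seq_len(n), function(i) {
    paste(sample(sense, codon_length, replace = TRUE), collapse = "")
  }, character(1))
}

#' Apply one whole-genome duplication
#'
#' Every chromosome is duplicated; each newly created gene is then deleted
#' independently with probability `loss_prob` (the pre-existing copy is
#' always retained, i.e. loss acts on the new duplicate only). The event
#' index, age and parent gene of every surviving duplicate are recorded so
#' that sequence evolution and downstream truth checks can reconstruct the
#' duplication tree.
#'
#' @param genome A `sim_genome`.
#' @param event_age Age of the event in Ma.
#' @param loss_prob Per-duplicate loss probability in `[0, 1)`.
#' @param codon_length Codons per gene (used to recompute coordinates).
#' @param seed Optional seed; by default the current RNG state is used so
#'   that [simulate_lineage()] stays a pure function of its config.
#'
#' @return The duplicated `sim_genome`.
#' @export
apply_wgd <- function(genome, event_age, loss_prob, codon_length = NULL,
                      seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"), nrow(genome$genes) > 0)
  if (loss_prob < 0 || loss_prob >= 1) {
    stop("loss_prob must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) {
    return(withr::with_seed(seed, apply_wgd(genome, event_age, loss_prob,
                                            codon_length)))
  }
  codon_length <- codon_length %||% nchar(genome$cds[[1]]) %/% 3L
  k <- sum(grepl("^wgd", unique(genome$genes$event))) + 1L
  tag <- paste0("wgd", k)

  dup <- genome$genes |>
    dplyr::mutate(
      parent_id = .data$gene_id,
      gene_id = paste0(.data$gene_id, ".w", k),
      chromosome = paste0(.data$chromosome, ".w", k),
      event = tag,
      event_age = .env$event_age
    )
  keep <- stats::runif(nrow(dup)) >= loss_prob
  dup <- dup[keep, , drop = FALSE]

  genes <- dplyr::bind_rows(genome$genes, dup) |>
    recompute_coordinates(codon_length)
  cds <- c(genome$cds, stats::setNames(genome$cds[dup$parent_id], dup$gene_id))
  new_sim_genome(genes, cds[genes$gene_id])
}

#' Add tandem duplicates
#'
#' Each gene receives, with probability `tandem_prob`, a rank-adjacent copy.
#' Tandem ages are drawn uniformly between 0 and the youngest configured
#' event age (tandem duplication is an ongoing process, so recent ages are
#' as likely as older ones).
#'
#' @inheritParams apply_wgd
#' @param tandem_prob Per-gene copy probability.
#' @param max_age_ma Upper bound for the tandem age draw, in Ma.
#' @return The augmented `sim_genome`.
#' @export
apply_tandem <- function(genome, tandem_prob, max_age_ma = 10,
                         codon_length = NULL, seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  if (tandem_prob <= 0) return(genome)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, apply_tandem(genome, tandem_prob,
                                               max_age_ma, codon_length)))
  }
  codon_length <- codon_length %||% nchar(genome$cds[[1]]) %/% 3L
  pick <- stats::runif(nrow(genome$genes)) < tandem_prob
  if (!any(pick)) return(genome)
  src <- genome$genes[pick, , drop = FALSE]
  copies <- src |>
    dplyr::mutate(
      parent_id = .data$gene_id,
      gene_id = paste0(.data$gene_id, ".t"),
      event = "tandem",
      event_age = stats::runif(dplyr::n(), 0, max_age_ma),
      rank = .data$rank + 0.5  # slot in next to the parent, then re-rank
    )
  genes <- dplyr::bind_rows(genome$genes, copies) |>
    recompute_coordinates(codon_length)
  cds <- c(genome$cds, stats::setNames(genome$cds[copies$parent_id],
                                       copies$gene_id))
  new_sim_genome(genes, cds[genes$gene_id])
}

#' Apply random chromosome fissions and fusions
#'
#' Each operation is, with equal probability, a fission (a chromosome is
#' split at a uniformly chosen rank) or a fusion (two random chromosomes are
#' concatenated). Gene content and sequences are untouched; only chromosome
#' assignment, ranks and coordinates change.
#'
#' @inheritParams apply_wgd
#' @param n Number of operations.
#' @return The rearranged `sim_genome`.
#' @export
apply_rearrangements <- function(genome, n, codon_length = NULL, seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  if (n <= 0) return(genome)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, apply_rearrangements(genome, n,
                                                       codon_length)))
  }
  codon_length <- codon_length %||% nchar(genome$cds[[1]]) %/% 3L
  genes <- genome$genes
  for (i in seq_len(n)) {
    chroms <- unique(genes$chromosome)
    do_fission <- length(chroms) < 2 ||
      (stats::runif(1) < 0.5 && any(table(genes$chromosome) >= 2))
    if (do_fission) {
      sizes <- table(genes$chromosome)
      eligible <- names(sizes)[sizes >= 2]
      if (!length(eligible)) next
      ch <- sample(eligible, 1)
      n_ch <- sizes[[ch]]
      cut <- sample(seq_len(n_ch - 1), 1)  # genes with rank >= cut move
      sel <- genes$chromosome == ch & genes$rank >= cut
      genes$chromosome[sel] <- paste0(ch, ".f", i)
    } else {
      pair <- sample(chroms, 2)
      offset <- max(genes$rank[genes$chromosome == pair[1]]) + 1L
      sel <- genes$chromosome == pair[2]
      genes$rank[sel] <- genes$rank[sel] + offset
      genes$chromosome[sel] <- pair[1]
    }
    genes <- recompute_coordinates(genes, codon_length)
  }
  new_sim_genome(genes, genome$cds[genes$gene_id])
}

#' Truth table of a simulated genome
#'
#' @param genome A `sim_genome`.
#' @return A tibble with `gene_id`, `ancestral_id`, `event` (`"none"`,
#'   `"wgd<k>"` or `"tandem"`), `parent_id` and `event_age`.
#' @export
sim_truth <- function(genome) {
  dplyr::select(genome$genes, "gene_id", "ancestral_id", "event",
                "parent_id", "event_age")
}

#' Simulate a full lineage from a configuration
#'
#' Runs, in order: ancestral genome construction, every configured WGD
#' (oldest first) with duplicate loss, tandem duplication, chromosome
#' rearrangements, and synonymous sequence divergence via
#' [evolve_pair_sequences()]. Identical config (including seed) gives
#' byte-identical output.
#'
#' @param config A [sim_config()].
#' @param evolve_sequences If `FALSE`, skip the (comparatively expensive)
#'   sequence-divergence stage; duplicate CDS then stay identical to their
#'   parents. Synteny-only analyses do not need divergence.
#' @return A `sim_genome`.
#' @export
simulate_lineage <- function(config, evolve_sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  genome <- simulate_ancestral_genome(config)
  withr::with_seed(config$seed + 1L, {
    for (age in config$wgd_times) {
      genome <- apply_wgd(genome, age, config$loss_prob, config$codon_length)
    }
    if (config$tandem_prob > 0) {
      max_age <- if (length(config$wgd_times)) min(config$wgd_times) else 10
      genome <- apply_tandem(genome, config$tandem_prob, max_age,
                             config$codon_length)
    }
    if (config$n_rearrangements > 0) {
      genome <- apply_rearrangements(genome, config$n_rearrangements,
                                     config$codon_length)
    }
  })
  if (evolve_sequences && any(genome$genes$event != "none")) {
    genome <- evolve_pair_sequences(genome, config)
  }
  genome
}

#' Rename a simulated genome into a lineage
#'
#' Prefixes gene, parent and chromosome identifiers so that two genomes
#' descended from the same ancestor can be compared without id collisions.
#' Ancestral locus ids are left untouched (they encode cross-lineage
#' orthology truth).
#'
#' @param genome A `sim_genome`.
#' @param prefix Lineage label, e.g. `"A"`.
#' @return The renamed `sim_genome`.
#' @export
rename_lineage <- function(genome, prefix) {
  tag <- function(x) ifelse(is.na(x), x, paste0(prefix, "_", x))
  genes <- genome$genes |>
    dplyr::mutate(gene_id = tag(.data$gene_id),
                  parent_id = tag(.data$parent_id),
                  chromosome = tag(.data$chromosome))
  cds <- genome$cds
  names(cds) <- tag(names(cds))
  new_sim_genome(genes, cds)
}

#' Simulate two lineages descending from one ancestor
#'
#' Builds the ancestral genome from `config`, then lets two lineages evolve
#' independently: each receives its own set of post-divergence WGD events
#' (with the configured duplicate loss) and, optionally, synonymous sequence
#' divergence. Lineage identifiers are prefixed `"A"` and `"B"`.
#'
#' @param config A [sim_config()]; its `wgd_times` are ignored in favour of
#'   the per-lineage arguments.
#' @param wgd_times_a,wgd_times_b WGD ages (Ma, strictly decreasing) for
#'   each lineage; `numeric(0)` for none.
#' @param evolve_sequences Diverge duplicate CDS (see [simulate_lineage()]).
#' @return A list with `sim_genome` elements `a` and `b`.
#' @export
simulate_lineage_pair <- function(config, wgd_times_a = numeric(0),
                                  wgd_times_b = config$wgd_times,
                                  evolve_sequences = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  ancestor <- simulate_ancestral_genome(config)
  evolve_one <- function(genome, times, seed_offset) {
    withr::with_seed(config$seed + seed_offset, {
      for (age in times) {
        genome <- apply_wgd(genome, age, config$loss_prob,
                            config$codon_length)
      }
      genome
    })
  }
  a <- evolve_one(rename_lineage(ancestor, "A"), wgd_times_a, 11L)
  b <- evolve_one(rename_lineage(ancestor, "B"), wgd_times_b, 12L)
  if (evolve_sequences) {
    cfg_a <- config; cfg_a$wgd_times <- as.numeric(wgd_times_a)
    cfg_b <- config; cfg_b$wgd_times <- as.numeric(wgd_times_b)
    if (length(wgd_times_a)) a <- evolve_pair_sequences(a, cfg_a)
    if (length(wgd_times_b)) b <- evolve_pair_sequences(b, cfg_b)
  }
  list(a = a, b = b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
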