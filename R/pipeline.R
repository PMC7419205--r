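# Orchestration: one configuration drives simulation, synteny, Ka/Ks, peak
# fitting, WGD/LTR dating and the k-mer survey, writing self-describing
# artefacts into a run directory. Rerunning the same configuration
# reproduces the outputs byte for byte.

PIPELINE_STAGES <- c("simulate", "synteny", "kaks", "peaks", "date_wgd",
                     "date_ltr", "survey")

STAGE_DEPS <- list(
  synteny = "simulate", kaks = "synteny", peaks = "kaks",
  date_wgd = "peaks"
)

DEFAULT_CONFIG <- list(
  seed = 1L,
  stages = PIPELINE_STAGES,
  simulate = list(n_chromosomes = 5L, n_genes = 1000L,
                  wgd_times = c(112.1, 77.8), subst_rate_r = 4.21e-9,
                  ks_sd = 0.12, loss_prob = 0.2, n_rearrangements = 0L,
                  tandem_prob = 0, codon_length = 300L,
                  evolve_sequences = TRUE),
  synteny = list(min_anchors = 5, max_gap = 25, top_k = 5, min_score = 0),
  kaks = list(ks_window = c(0.01, 2.5), min_pairs = 3),
  peaks = list(max_components = 4L, bandwidth = NULL, n_grid = 512L,
               criterion = "aicc"),
  date_wgd = list(rate = 4.21e-9),
  date_ltr = list(n = 500L, age_mode_ma = 9.9, age_sd_ma = 2,
                  rate = 1.51e-9, ltr_length = 1000L),
  survey = list(genome_bp = 100000L, coverage = 30, read_length = 150L,
                k = 17L)
)

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order on a synthetic
#' dataset: `simulate` builds a lineage with the configured WGD history;
#' `synteny` detects anchors and chains syntenic blocks within it; `kaks`
#' estimates Ka/Ks for every anchor pair; `peaks` fits the block-median Ks
#' density; `date_wgd` converts fitted peaks to ages; `date_ltr` simulates
#' and dates an LTR cohort; `survey` simulates reads and estimates genome
#' size from k-mers. Every output file carries the package version, a
#' configuration hash and the seed in a header comment.
#'
#' @param config A nested list (see `paleodup:::DEFAULT_CONFIG` for the
#'   schema) or the path of an equivalent YAML file. Unknown keys are
#'   rejected. `config$stages` selects stages; dependencies must be
#'   included.
#' @param outdir Run directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a list of stage results (`genome`, `blocks`, `kaks`,
#'   `medians`, `fit`, `wgd_ages`, `ltr`, `survey`) plus `config` and
#'   `outdir`.
#' @export
run_pipeline <- function(config = list(), outdir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(DEFAULT_CONFIG, config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stages <- match.arg(config$stages, PIPELINE_STAGES, several.ok = TRUE)
  for (st in stages) {
    missing_dep <- setdiff(STAGE_DEPS[[st]], stages)
    if (length(missing_dep)) {
      stop("stage '", st, "' requires stage(s) ",
           paste(missing_dep, collapse = ", "), call. = FALSE)
    }
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- function(tbl, file) {
    write_tsv_report(tbl, file.path(outdir, file), config, config$seed)
  }
  json_out <- function(x, file) {
    x$provenance <- list(
      version = as.character(utils::packageVersion("paleodup")),
      config_hash = rlang::hash(config), seed = config$seed)
    jsonlite::write_json(x, file.path(outdir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  res <- list(config = config, outdir = outdir)

  if ("simulate" %in% stages) {
    sc <- config$simulate
    cfg <- sim_config(seed = config$seed, n_chromosomes = sc$n_chromosomes,
                      n_genes = sc$n_genes, wgd_times = sc$wgd_times,
                      subst_rate_r = sc$subst_rate_r, ks_sd = sc$ks_sd,
                      loss_prob = sc$loss_prob,
                      n_rearrangements = sc$n_rearrangements,
                      tandem_prob = sc$tandem_prob,
                      codon_length = sc$codon_length)
    genome <- simulate_lineage(cfg, evolve_sequences = sc$evolve_sequences)
    res$genome <- genome
    write_fasta(genome$cds, file.path(outdir, "cds.fasta"))
    write_gene_positions(genome$genes, file.path(outdir, "genes.gff3"),
                         "gff3")
    write_gene_positions(genome$genes, file.path(outdir, "genes.bed"),
                         "bed")
    hdr(sim_truth(genome), "truth.tsv")
  }

  if ("synteny" %in% stages) {
    sy <- config$synteny
    genome <- res$genome
    hits <- homology_hits(genome$cds)
    anchors <- find_anchors(genome$genes, genome$genes, hits,
                            top_k = sy$top_k, min_score = sy$min_score)
    blocks <- chain_blocks(anchors, genome$genes, genome$genes,
                           min_anchors = sy$min_anchors,
                           max_gap = sy$max_gap)
    res$anchors <- anchors
    res$blocks <- blocks
    res$classes <- classify_duplications(genome$genes, anchors, blocks)
    if (nrow(blocks)) {
      hdr(blocks_to_table(blocks), "blocks.tsv")
      write_collinearity(blocks, file.path(outdir, "blocks.collinearity"))
    }
    hdr(res$classes, "duplication_classes.tsv")
  }

  if ("kaks" %in% stages) {
    res$kaks <- kaks_table(res$blocks, res$genome$cds)
    hdr(res$kaks, "kaks.tsv")
  }

  if ("peaks" %in% stages) {
    pk <- config$peaks
    res$medians <- block_median_ks(res$kaks,
                                   ks_window = config$kaks$ks_window,
                                   min_pairs = config$kaks$min_pairs)
    curve <- ks_kde(res$medians, bandwidth = pk$bandwidth,
                    n_grid = pk$n_grid)
    res$fit <- fit_gaussian_peaks(curve, max_components = pk$max_components,
                                  criterion = pk$criterion)
    hdr(tibble::as_tibble(curve), "ks_density.tsv")
    json_out(list(components = tidy(res$fit),
                  selection = res$fit$selection), "ks_peaks.json")
  }

  if ("date_wgd" %in% stages) {
    res$wgd_ages <- date_wgd(res$fit, rate = config$date_wgd$rate)
    json_out(list(rate = config$date_wgd$rate, ages = res$wgd_ages),
             "wgd_dating.json")
  }

  if ("date_ltr" %in% stages) {
    dl <- config$date_ltr
    cohort <- simulate_ltr_cohort(dl$n, dl$age_mode_ma, dl$age_sd_ma,
                                  rate = dl$rate,
                                  ltr_length = dl$ltr_length,
                                  seed = config$seed + 20L)
    write_ltr_pairs(cohort, file.path(outdir, "ltr_pairs.fasta"))
    dated <- date_ltr_cohort(cohort, rate = dl$rate)
    burst <- ltr_burst_profile(dated)
    res$ltr <- list(cohort = cohort, dated = dated, burst = burst)
    hdr(dated, "ltr_insertion_times.tsv")
    json_out(list(peak_k = burst$peak_k,
                  peak_age_ma = burst$peak_k / (2 * dl$rate) / 1e6),
             "ltr_burst.json")
  }

  if ("survey" %in% stages) {
    sv <- config$survey
    genome_seq <- simulate_genome_sequence(sv$genome_bp,
                                           seed = config$seed + 30L)
    reads <- simulate_reads(genome_seq, sv$coverage, sv$read_length,
                            seed = config$seed + 31L)
    write_fastq(reads, file.path(outdir, "reads.fastq"))
    h <- count_kmers(reads, k = sv$k)
    res$survey <- estimate_genome_size(h)
    hdr(tibble::as_tibble(h), "kmer_histogram.tsv")
    json_out(as.list(res$survey), "genome_size.json")
  }

  invisible(res)
}

# Recursive default merge; unknown keys are an error so typos do not pass
# silently.
merge_config <- function(defaults, user, path = character()) {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(c(paste(path, collapse = "$"), unknown), collapse = "$"),
         call. = FALSE)
  }
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      user[[nm]]
    }
  }
  defaults
}
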