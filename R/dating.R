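#' Cross-lineage Ks correction coefficients
#'
#' Lineages evolve at different synonymous rates, so paralog Ks peaks are
#' not directly comparable across species. Using ortholog Ks peaks against a
#' common outgroup, each lineage's observables are rescaled by
#' `rho = ks_out_ref / ks_out_i`: after correction every lineage's
#' outgroup-ortholog peak coincides with the reference's, so corrected
#' paralog peaks share one time scale.
#'
#' @param ortholog_peaks A tibble/data.frame with columns `species` and
#'   `ks_out` (ortholog Ks peak against the common outgroup), or a named
#'   numeric vector.
#' @param reference Species label used as the rate reference.
#'
#' @return A tibble: `reference_species`, `species`, `ks_out_ref`,
#'   `ks_out`, `rho`. Multiply a species' observed Ks by its `rho` to
#'   correct it.
#' @export
#' @examples
#' correction_coefficient(c(ref = 0.8, other = 1.0), reference = "ref")
correction_coefficient <- function(ortholog_peaks, reference) {
  if (is.numeric(ortholog_peaks)) {
    ortholog_peaks <- tibble::tibble(species = names(ortholog_peaks),
                                     ks_out = unname(ortholog_peaks))
  }
  stopifnot(all(c("species", "ks_out") %in% names(ortholog_peaks)))
  if (!reference %in% ortholog_peaks$species) {
    stop("reference species '", reference, "' not present", call. = FALSE)
  }
  if (any(ortholog_peaks$ks_out <= 0)) {
    stop("ortholog peak Ks must be positive", call. = FALSE)
  }
  ref_ks <- ortholog_peaks$ks_out[ortholog_peaks$species == reference][1]
  ortholog_peaks |>
    tibble::as_tibble() |>
    dplyr::transmute(
      reference_species = reference,
      species = .data$species,
      ks_out_ref = ref_ks,
      ks_out = .data$ks_out,
      rho = ref_ks / .data$ks_out
    )
}

#' Calibrate a synonymous substitution rate
#'
#' Inverts the molecular-clock relation `Ks = 2 r T` at a node of known age:
#' `r = Ks / (2 T)`.
#'
#' @param corrected_ks Rate-corrected Ks of the calibration node.
#' @param calibration_age_ma Age of the node in Ma.
#' @param label Optional node label.
#' @return A one-row tibble: `r` (substitutions/site/year), `corrected_ks`,
#'   `calibration_age_ma`, `label`.
#' @export
#' @examples
#' calibrate_rate(0.944, 112.1)  # ~4.21e-9, the Laurales rate
calibrate_rate <- function(corrected_ks, calibration_age_ma,
                           label = NA_character_) {
  if (corrected_ks <= 0 || calibration_age_ma <= 0) {
    stop("corrected_ks and calibration_age_ma must be positive",
         call. = FALSE)
  }
  tibble::tibble(
    r = corrected_ks / (2 * calibration_age_ma * 1e6),
    corrected_ks = corrected_ks,
    calibration_age_ma = calibration_age_ma,
    label = label
  )
}

#' Date whole-genome duplication events from fitted Ks peaks
#'
#' Converts Ks peak positions to ages via `T = Ks / (2 r)`.
#'
#' @param peak_ks Numeric vector of (rate-corrected) Ks peak positions, or a
#'   `ks_peak_fit`, in which case the fitted component means are dated.
#' @param rate Synonymous substitution rate (substitutions/site/year) as a
#'   scalar or a [calibrate_rate()] row.
#' @return A tibble: `peak_ks`, `rate`, `age_ma`, ordered by age.
#' @export
#' @examples
#' date_wgd(c(0.655, 0.944), rate = 4.21e-9)  # ~77.8 and ~112.1 Ma
date_wgd <- function(peak_ks, rate) {
  if (inherits(peak_ks, "ks_peak_fit")) peak_ks <- peak_ks$components$mean
  if (is.data.frame(rate)) rate <- rate$r[1]
  if (any(peak_ks <= 0)) stop("peak_ks must be positive", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  tibble::tibble(
    peak_ks = sort(peak_ks),
    rate = rate,
    age_ma = sort(peak_ks) / (2 * rate) / 1e6
  )
}

#' Divergence of an element's two long terminal repeats
#'
#' The 5' and 3' LTRs of a retrotransposon are identical at insertion;
#' their present-day divergence dates the element. The two copies are
#' globally aligned and the nucleic-acid diversity `lambda` is the mismatch
#' proportion over non-gap alignment columns.
#'
#' @param ltr_5p,ltr_3p The two LTR sequences (character or
#'   [Biostrings::DNAString]).
#' @return A one-row tibble: `lambda`, `n_columns` (non-gap columns
#'   compared).
#' @export
ltr_divergence <- function(ltr_5p, ltr_3p) {
  a <- toupper(as.character(ltr_5p))
  b <- toupper(as.character(ltr_3p))
  if (nchar(a) == 0 || nchar(b) == 0) {
    stop("both LTR sequences must be nonempty", call. = FALSE)
  }
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
  } else {
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                        Biostrings::DNAString(b),
                                        type = "global")
    ca <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    cb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  }
  ok <- ca != "-" & cb != "-"
  if (!any(ok)) stop("no comparable alignment columns", call. = FALSE)
  tibble::tibble(lambda = mean(ca[ok] != cb[ok]), n_columns = sum(ok))
}

#' LTR insertion time from nucleic-acid diversity
#'
#' Applies the Jukes-Cantor correction `K = -0.75 ln(1 - 4 lambda / 3)` and
#' the clock `T = K / (2 r)`. Elements with `lambda >= 3/4` are reported as
#' saturated with no age.
#'
#' @param lambda Mismatch proportion(s) from [ltr_divergence()], or a tibble
#'   containing a `lambda` column (extra columns are carried through).
#' @param rate Substitution rate per site per year (default the conifer-to-
#'   angiosperm LTR clock commonly used for magnoliid genomes).
#' @return A tibble with `lambda`, `K`, `T_ma` and `saturated`.
#' @export
#' @examples
#' ltr_insertion_time(0.0297, rate = 1.51e-9)  # ~9.9 Ma
ltr_insertion_time <- function(lambda, rate = 1.51e-9) {
  extra <- NULL
  if (is.data.frame(lambda)) {
    extra <- dplyr::select(lambda, -"lambda")
    lambda <- lambda$lambda
  }
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  K <- jc_correct(lambda)
  out <- tibble::tibble(
    lambda = lambda,
    K = K,
    T_ma = K / (2 * rate) / 1e6,
    saturated = lambda >= 0.75
  )
  if (!is.null(extra) && nrow(extra) == nrow(out)) {
    out <- dplyr::bind_cols(extra, out)
  }
  out
}

#' Date a whole cohort of LTR element pairs
#'
#' Runs [ltr_divergence()] and [ltr_insertion_time()] on every element of a
#' cohort (as simulated by [simulate_ltr_cohort()] or read from a pairs
#' FASTA via [read_ltr_pairs()]).
#'
#' @param cohort Tibble with columns `element_id`, `ltr5`, `ltr3`.
#' @inheritParams ltr_insertion_time
#' @return A tibble: `element_id`, `lambda`, `K`, `T_ma`, `saturated`.
#' @export
date_ltr_cohort <- function(cohort, rate = 1.51e-9) {
  stopifnot(all(c("element_id", "ltr5", "ltr3") %in% names(cohort)))
  div <- purrr::map2_dfr(cohort$ltr5, cohort$ltr3, ltr_divergence)
  dplyr::bind_cols(
    tibble::tibble(element_id = cohort$element_id),
    ltr_insertion_time(div$lambda, rate = rate)
  )
}

#' Density profile of LTR divergence across a cohort
#'
#' Kernel density over per-element Jukes-Cantor distances `K`; the mode
#' locates the insertion burst.
#'
#' @param dated Output of [date_ltr_cohort()] (needs a `K` column), or a
#'   numeric vector of `K` values.
#' @param bandwidth,n_grid Passed to [ks_kde()].
#' @return A list with `curve` (a `density_curve` over `K`) and `peak_k`
#'   (the density mode).
#' @export
ltr_burst_profile <- function(dated, bandwidth = NULL, n_grid = 512) {
  k <- if (is.numeric(dated)) dated else dated$K
  k <- k[!is.na(k) & is.finite(k)]
  if (length(k) < 10) {
    stop("need at least 10 dateable elements for a burst profile",
         call. = FALSE)
  }
  window <- c(0, max(k) * 1.05)
  curve <- ks_kde(k, bandwidth = bandwidth, n_grid = n_grid,
                  window = window)
  list(curve = curve, peak_k = density_mode(curve))
}
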