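#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Ks density curve
#'
#' @param object A `density_curve` from [ks_kde()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$ks, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "Ks (substitutions per synonymous site)",
                  y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a fitted Ks peak model over its density curve
#'
#' Shows the smoothed density, each fitted Gaussian component and their
#' sum, with component means marked.
#'
#' @param object A `ks_peak_fit` from [fit_gaussian_peaks()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ks_peak_fit <- function(object, ...) {
  curve <- tibble::as_tibble(object$curve)
  comp <- object$components
  comp_curves <- purrr::pmap_dfr(
    list(seq_len(nrow(comp)), comp$weight, comp$mean, comp$sd),
    function(i, w, m, s) {
      tibble::tibble(component = factor(i), ks = curve$ks,
                     density = w * stats::dnorm(curve$ks, m, s))
    })
  total <- tibble::tibble(
    ks = curve$ks,
    density = gaussian_mix(curve$ks, comp$weight, comp$mean, comp$sd))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$ks, y = .data$density)) +
    ggplot2::geom_area(fill = "grey85") +
    ggplot2::geom_line(data = comp_curves,
                       ggplot2::aes(colour = .data$component),
                       linewidth = 0.5) +
    ggplot2::geom_line(data = total, linetype = "22", linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = comp$mean, linetype = "dotted") +
    ggplot2::labs(x = "Ks (substitutions per synonymous site)",
                  y = "density", colour = "peak") +
    ggplot2::theme_minimal()
}

#' Plot a syntenic depth profile
#'
#' Bar chart of the per-gene block-coverage depth distribution for both
#' genomes, annotated with the modal depth ratio.
#'
#' @param object A `depth_profile` from [syntenic_depth()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.depth_profile <- function(object, ...) {
  dd <- object$gene_depth |>
    dplyr::filter(.data$depth >= 1) |>
    dplyr::count(.data$genome, .data$depth)
  ggplot2::ggplot(dd, ggplot2::aes(x = factor(.data$depth), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~genome, scales = "free_y") +
    ggplot2::labs(x = "syntenic depth (blocks covering a gene)",
                  y = "genes",
                  title = paste("modal depth ratio", object$ratio_label)) +
    ggplot2::theme_minimal()
}

#' Plot a k-mer depth histogram
#'
#' @param hist A `kmer_histogram` from [count_kmers()].
#' @param result Optional [estimate_genome_size()] row; marks the error
#'   cutoff and coverage peak.
#' @return A ggplot.
#' @export
plot_kmer_histogram <- function(hist, result = NULL) {
  p <- ggplot2::ggplot(tibble::as_tibble(hist),
                       ggplot2::aes(x = .data$depth, y = .data$n_kmers)) +
    ggplot2::geom_col(width = 0.9, fill = "grey40") +
    ggplot2::labs(x = "k-mer depth", y = "distinct k-mers") +
    ggplot2::theme_minimal()
  if (!is.null(result)) {
    p <- p +
      ggplot2::geom_vline(xintercept = result$peak_depth,
                          colour = "firebrick") +
      ggplot2::geom_vline(xintercept = result$error_cutoff + 0.5,
                          linetype = "dotted")
  }
  p
}

#' Plot the LTR insertion burst profile
#'
#' @param burst Output of [ltr_burst_profile()].
#' @return A ggplot with the K density and its mode marked.
#' @export
plot_ltr_burst <- function(burst) {
  autoplot.density_curve(burst$curve) +
    ggplot2::geom_vline(xintercept = burst$peak_k, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = "Jukes-Cantor distance K between 5' and 3' LTR")
}
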