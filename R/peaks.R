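#' Per-block median Ks distribution
#'
#' The representative Ks of a syntenic block is the median over its
#' unsaturated anchor-pair estimates inside the Ks window; blocks with fewer
#' than `min_pairs` usable pairs are dropped. Using one value per block
#' (rather than per pair) keeps large blocks from dominating the mixture
#' fit.
#'
#' @param kaks A Ka/Ks tibble from [kaks_table()] (columns `block_id`, `ks`,
#'   `saturated`).
#' @param ks_window Numeric length-2: inclusive Ks window. The lower edge
#'   drops allelic near-zero pairs, the upper drops saturated estimates.
#' @param min_pairs Minimum usable pairs per block.
#' @param source_label Label carried on the result (e.g. the comparison
#'   name).
#'
#' @return A `ks_distribution`: a tibble with `block_id`, `n_pairs`, `ks`,
#'   carrying `source_label` and `ks_window` attributes.
#' @export
block_median_ks <- function(kaks, ks_window = c(0.01, 2.5), min_pairs = 3,
                            source_label = "paralogs") {
  stopifnot(all(c("block_id", "ks", "saturated") %in% names(kaks)))
  out <- kaks |>
    dplyr::filter(!.data$saturated, !is.na(.data$ks),
                  .data$ks >= ks_window[1], .data$ks <= ks_window[2]) |>
    dplyr::group_by(.data$block_id) |>
    dplyr::summarise(n_pairs = dplyr::n(), ks = stats::median(.data$ks),
                     .groups = "drop") |>
    dplyr::filter(.data$n_pairs >= min_pairs)
  if (nrow(out) == 0) {
    stop("no block retains >= ", min_pairs,
         " usable Ks estimates inside the window", call. = FALSE)
  }
  new_ks_distribution(out, source_label, ks_window)
}

new_ks_distribution <- function(tbl, source_label, ks_window) {
  structure(tbl, class = c("ks_distribution", class(tbl)),
            source_label = source_label, ks_window = ks_window)
}

#' Build a Ks distribution from raw values
#'
#' @param values Numeric Ks (or substitution-distance) values.
#' @inheritParams block_median_ks
#' @return A `ks_distribution` (with synthetic block ids).
#' @export
ks_distribution <- function(values, ks_window = c(0.01, 2.5),
                            source_label = "values") {
  values <- values[!is.na(values) & values >= ks_window[1] &
                     values <= ks_window[2]]
  new_ks_distribution(
    tibble::tibble(block_id = sprintf("v%05d", seq_along(values)),
                   n_pairs = NA_integer_, ks = values),
    source_label, ks_window
  )
}

#' Kernel density estimate of a Ks distribution
#'
#' Gaussian-kernel density on a uniform grid over the Ks window, with
#' Silverman's rule as the automatic bandwidth and renormalisation over the
#' window so the trapezoid integral is 1 (mass smoothed beyond either edge
#' is folded back proportionally).
#'
#' @param dist A `ks_distribution`, or a bare numeric vector of Ks values.
#' @param bandwidth Kernel bandwidth in Ks units, or `NULL` for Silverman's
#'   rule of thumb.
#' @param n_grid Number of grid points.
#' @param window Grid range; defaults to the distribution's Ks window.
#'
#' @return A `density_curve`: tibble with `ks` (grid) and `density`, plus
#'   `bandwidth` and `window` attributes.
#' @export
ks_kde <- function(dist, bandwidth = NULL, n_grid = 512, window = NULL) {
  values <- if (is.numeric(dist)) dist else dist$ks
  window <- window %||% attr(dist, "ks_window") %||% range(values)
  if (length(values) < 10) {
    stop("need at least 10 Ks values for a density estimate", call. = FALSE)
  }
  bw <- bandwidth %||% stats::bw.nrd0(values)
  if (!is.finite(bw) || bw <= 0) {
    # degenerate spread (e.g. identical values): fall back to a sliver of
    # the window so the density is still a proper curve
    bw <- diff(range(window)) / 200
  }
  d <- stats::density(values, bw = bw, from = window[1], to = window[2],
                      n = n_grid)
  dens <- d$y / trapezoid(d$x, d$y)
  structure(tibble::tibble(ks = d$x, density = dens),
            class = c("density_curve", class(tibble::tibble())),
            bandwidth = bw, window = window)
}

trapezoid <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Mode of a density curve
#'
#' @param curve A `density_curve`.
#' @return The grid position of the density maximum.
#' @export
density_mode <- function(curve) curve$ks[which.max(curve$density)]

#' Fit a multi-Gaussian peak model to a Ks density curve
#'
#' Least-squares fit of a sum of `k` Gaussian components to the smoothed
#' density (the curve is the data, as in curve-fitting toolboxes), for
#' `k = 1..max_components`. Initial component means sit at the `k` largest
#' local maxima of the curve (supplemented with mass quantiles when the
#' curve has fewer maxima); component count is selected by an information
#' criterion on the curve residuals, ties resolved toward fewer components.
#' The procedure is deterministic given the curve.
#'
#' Component counts whose best fit is degenerate are excluded before
#' selection: a fit is degenerate when a component carries less than
#' `min_weight_share` of the total fitted mass (it is chasing smoothing
#' wiggles, not a peak) or when two component means sit closer than 0.75
#' times the sum of their standard deviations (the components describe one
#' peak that the data cannot resolve).
#' These are the usual identifiability constraints of mixture fitting.
#'
#' @param curve A `density_curve` from [ks_kde()].
#' @param max_components Largest component count tried.
#' @param criterion `"aicc"` (small-sample corrected, default), `"bic"` or
#'   `"aic"`.
#' @param min_weight_share Smallest admissible component mass fraction.
#'
#' @return A `ks_peak_fit`: list with `components` (tibble `weight`, `mean`,
#'   `sd`, sorted by mean), `n_components`, `fit_rss`, `selection`
#'   (per-k trace: `k`, `rss`, `score`, `converged`), `criterion`, and the
#'   input `curve`.
#' @export
fit_gaussian_peaks <- function(curve, max_components = 4,
                               criterion = c("aicc", "bic", "aic"),
                               min_weight_share = 0.08) {
  criterion <- match.arg(criterion)
  x <- curve$ks
  y <- curve$density
  n <- length(x)
  fits <- vector("list", max_components)
  trace <- tibble::tibble(k = seq_len(max_components), rss = NA_real_,
                          score = NA_real_, converged = FALSE,
                          degenerate = FALSE)
  for (k in seq_len(max_components)) {
    fit <- fit_k_gaussians(x, y, k)
    fits[[k]] <- fit
    if (is.null(fit)) next
    trace$rss[k] <- fit$rss
    if (degenerate_fit(fit, min_weight_share)) {
      trace$degenerate[k] <- TRUE
      next
    }
    p <- 3 * k
    score <- switch(criterion,
      aic = n * log(fit$rss / n) + 2 * p,
      aicc = n * log(fit$rss / n) + 2 * p + 2 * p * (p + 1) /
        max(n - p - 1, 1),
      bic = n * log(fit$rss / n) + p * log(n)
    )
    trace$score[k] <- score
    trace$converged[k] <- TRUE
  }
  if (!any(trace$converged)) {
    stop("Gaussian peak fitting failed to converge for every component ",
         "count (grid of ", n, " points, max ", max_components,
         " components)", call. = FALSE)
  }
  best_k <- trace$k[trace$converged][which.min(trace$score[trace$converged])]
  best <- fits[[best_k]]
  comp <- tibble::tibble(weight = best$w, mean = best$m, sd = best$s) |>
    dplyr::arrange(.data$mean)
  structure(list(components = comp, n_components = best_k,
                 fit_rss = best$rss, selection = trace,
                 criterion = criterion, curve = curve),
            class = "ks_peak_fit")
}

# Least-squares k-Gaussian fit via Levenberg-Marquardt with positivity
# bounds; returns NULL when no start converges.
fit_k_gaussians <- function(x, y, k) {
  starts <- gaussian_starts(x, y, k)
  step <- x[2] - x[1]
  best <- NULL
  for (st in starts) {
    res_fn <- function(par) {
      w <- par[seq_len(k)]
      m <- par[k + seq_len(k)]
      s <- par[2 * k + seq_len(k)]
      y - gaussian_mix(x, w, m, s)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = res_fn,
        lower = c(rep(1e-8, k), rep(min(x), k), rep(step, k)),
        upper = c(rep(Inf, k), rep(max(x), k), rep(diff(range(x)), k)),
        control = minpack.lm::nls.lm.control(maxiter = 400)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      par <- fit$par
      best <- list(w = par[seq_len(k)], m = par[k + seq_len(k)],
                   s = par[2 * k + seq_len(k)], rss = rss)
    }
  }
  best
}

# Identifiability guards: every component must carry a substantive share of
# the fitted mass and be separated from its neighbours.
degenerate_fit <- function(fit, min_weight_share) {
  share <- fit$w / sum(fit$w)
  if (any(share < min_weight_share)) return(TRUE)
  k <- length(fit$m)
  if (k > 1) {
    ord <- order(fit$m)
    m <- fit$m[ord]; s <- fit$s[ord]
    sep <- diff(m) - 0.75 * (utils::head(s, -1) + utils::tail(s, -1))
    if (any(sep < 0)) return(TRUE)
  }
  FALSE
}

gaussian_mix <- function(x, w, m, s) {
  rowSums(vapply(seq_along(w),
                 function(j) w[j] * stats::dnorm(x, m[j], s[j]),
                 numeric(length(x))))
}

# Deterministic start sets: component means at the k largest local maxima,
# padded with mass quantiles; a second start spreads means over quantiles
# only, guarding against merged peaks.
gaussian_starts <- function(x, y, k) {
  local_max <- which(diff(sign(diff(y))) == -2) + 1L
  local_max <- local_max[order(y[local_max], decreasing = TRUE)]
  cdf <- cumsum(y) / sum(y)
  qpos <- vapply((seq_len(k) - 0.5) / k,
                 function(q) x[which.min(abs(cdf - q))], numeric(1))
  mean_sets <- list(qpos)
  if (length(local_max)) {
    m <- x[utils::head(local_max, k)]
    if (length(m) < k) m <- c(m, qpos[seq_len(k - length(m))])
    mean_sets <- c(list(sort(m)), mean_sets)
  }
  sd_scales <- diff(range(x)) / (c(4, 12, 40) * k)
  starts <- list()
  for (m in unique(mean_sets)) {
    for (sd0 in sd_scales) {
      w0 <- pmax(y[vapply(m, function(mm) which.min(abs(x - mm)),
                          integer(1))],
                 1e-4) * sqrt(2 * pi) * sd0
      starts[[length(starts) + 1L]] <- c(w0, sort(m), rep(sd0, k))
    }
  }
  starts
}

#' @export
print.ks_peak_fit <- function(x, ...) {
  cat("<ks_peak_fit> ", x$n_components, " component(s), rss ",
      signif(x$fit_rss, 4), " [", x$criterion, "]\n", sep = "")
  print(x$components)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Ks peak fit
#'
#' @param x A `ks_peak_fit`.
#' @param ... Unused.
#' @return One row per fitted Gaussian component: `component`, `weight`,
#'   `mean`, `sd`.
#' @export
tidy.ks_peak_fit <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(), .before = 1)
}

#' Glance at a Ks peak fit
#'
#' @param x A `ks_peak_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_components`, `fit_rss`, `criterion`,
#'   `bandwidth`.
#' @export
glance.ks_peak_fit <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, fit_rss = x$fit_rss,
                 criterion = x$criterion,
                 bandwidth = attr(x$curve, "bandwidth"))
}
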