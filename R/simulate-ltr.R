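#' Simulate a cohort of LTR retrotransposon pairs
#'
#' Each element gets an insertion age from a normal distribution truncated
#' at zero, an ancestral LTR of random sequence, and two present-day copies
#' evolved independently from it under the Jukes-Cantor model at `rate`
#' substitutions per site per year, so the expected pairwise distance of a
#' pair is `K = 2 * rate * age`. No indels are introduced: both copies stay
#' the same length.
#'
#' @param n Number of elements.
#' @param age_mode_ma,age_sd_ma Mode and spread (Ma) of the insertion-age
#'   distribution; `age_sd_ma = 0` gives every element exactly the mode.
#' @param rate Substitution rate per site per year.
#' @param ltr_length LTR length in bp (at least 200).
#' @param seed Integer seed.
#'
#' @return An `ltr_cohort` tibble: `element_id`, `ltr5`, `ltr3`,
#'   `age_ma` (the true insertion age).
#' @export
#' @examples
#' simulate_ltr_cohort(3, age_mode_ma = 9.9, age_sd_ma = 2, seed = 1,
#'                     ltr_length = 200)
simulate_ltr_cohort <- function(n, age_mode_ma, age_sd_ma = 0,
                                rate = 1.51e-9, ltr_length = 1000,
                                seed = 1L) {
  if (ltr_length < 200) stop("ltr_length must be >= 200 bp", call. = FALSE)
  if (n == 0) {
    return(tibble::tibble(element_id = character(), ltr5 = character(),
                          ltr3 = character(), age_ma = numeric()))
  }
  withr::with_seed(seed, {
    ages <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        a <- if (age_sd_ma > 0) stats::rnorm(1, age_mode_ma, age_sd_ma) else
          age_mode_ma
        if (a >= 0) break
      }
      ages[i] <- a
    }
    if (any(2 * rate * ages * 1e6 >= 0.75)) {
      stop("expected LTR divergence reaches 0.75: Jukes-Cantor dating is ",
           "undefined at such ages", call. = FALSE)
    }
    ltr5 <- character(n)
    ltr3 <- character(n)
    for (i in seq_len(n)) {
      anc <- sample(BASES, ltr_length, replace = TRUE)
      d <- rate * ages[i] * 1e6  # per-branch JC distance
      ltr5[i] <- paste(jc_evolve(anc, d), collapse = "")
      ltr3[i] <- paste(jc_evolve(anc, d), collapse = "")
    }
    tibble::tibble(element_id = sprintf("ltr%05d", seq_len(n)),
                   ltr5 = ltr5, ltr3 = ltr3, age_ma = ages)
  })
}

# One Jukes-Cantor branch: each site differs from the ancestor with
# probability 3/4 (1 - exp(-4d/3)); changed sites take one of the other
# three bases uniformly.
jc_evolve <- function(seq, d) {
  if (d <= 0) return(seq)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- stats::runif(length(seq)) < p
  if (any(hit)) {
    seq[hit] <- vapply(seq[hit],
                       function(b) sample(setdiff(BASES, b), 1),
                       character(1), USE.NAMES = FALSE)
  }
  seq
}
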