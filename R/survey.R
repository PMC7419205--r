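# K-mer genome-size survey: G = (counted k-mers above the error cutoff) /
# (modal k-mer depth). With error-free homozygous reads the histogram is a
# single coverage peak; with sequencing errors a spike at depth 1-2 appears
# and is excluded by the first local minimum.

#' Count canonical k-mers in a read set
#'
#' Every k-mer is canonicalised to the lexicographic minimum of itself and
#' its reverse complement, so both strands of a locus collapse onto one
#' key. K-mers containing non-ACGT characters are skipped. Encoding is
#' 2-bit packed into doubles, which is exact for `k <= 25`.
#'
#' @param reads Character vector of read sequences, a tibble with a `seq`
#'   column (as from [simulate_reads()]), or a [Biostrings::DNAStringSet].
#' @param k Odd k-mer length between 3 and 25 (17 and 21 are the usual
#'   survey choices; the packing caps k at 25).
#' @return A `kmer_histogram`: tibble with `depth` and `n_kmers` (number of
#'   distinct canonical k-mers seen at that depth), with attributes `k` and
#'   `total_kmers` (sum of depth * n_kmers).
#' @export
count_kmers <- function(reads, k = 17) {
  if (is.data.frame(reads)) reads <- reads$seq
  if (inherits(reads, "XStringSet")) reads <- as.character(reads)
  if (length(reads) == 0 || all(nchar(reads) == 0)) {
    stop("empty read set", call. = FALSE)
  }
  if (k %% 2 == 0 || k < 3 || k > 25) {
    stop("k must be odd and between 3 and 25", call. = FALSE)
  }

  # concatenate reads with a separator so no k-mer spans two reads
  all_chars <- strsplit(paste(toupper(reads), collapse = "N"), "")[[1]]
  code <- match(all_chars, BASES) - 1  # A C G T -> 0..3, else NA
  n <- length(code)
  if (n < k) stop("reads shorter than k", call. = FALSE)
  n_pos <- n - k + 1
  pow <- 4^((k - 1):0)
  fwd <- numeric(n_pos)
  rev <- numeric(n_pos)
  valid <- rep(TRUE, n_pos)
  for (j in seq_len(k)) {
    cj <- code[j:(j + n_pos - 1)]
    bad <- is.na(cj)
    if (any(bad)) {
      valid <- valid & !bad
      cj[bad] <- 0
    }
    fwd <- fwd + cj * pow[j]
    rev <- rev + (3 - cj) * pow[k - j + 1]
  }
  canon <- pmin(fwd, rev)[valid]
  if (!length(canon)) stop("no valid k-mers in input", call. = FALSE)
  depth_per_kmer <- rle(sort(canon))$lengths
  tab <- table(depth_per_kmer)
  structure(
    tibble::tibble(depth = as.integer(names(tab)),
                   n_kmers = as.vector(unname(tab))),
    class = c("kmer_histogram", class(tibble::tibble())),
    k = k, total_kmers = length(canon)
  )
}

#' Estimate genome size from a k-mer histogram
#'
#' The error cutoff is the first local minimum of the depth histogram
#' (depth 0 when the histogram rises straight to the coverage peak); the
#' peak depth is the most abundant depth above the cutoff; genome size is
#' the number of counted k-mers above the cutoff divided by the peak depth.
#'
#' @param hist A `kmer_histogram` from [count_kmers()], or a tibble with
#'   `depth` and `n_kmers` columns.
#' @return A one-row tibble: `genome_size_bp`, `peak_depth` (coverage mode,
#'   refined by quadratic interpolation through its neighbours),
#'   `error_cutoff`, `total_kmers_used`, `k`.
#' @export
estimate_genome_size <- function(hist) {
  h <- dplyr::arrange(tibble::as_tibble(hist), .data$depth)
  full <- merge(data.frame(depth = seq_len(max(h$depth))), h,
                all.x = TRUE)
  full$n_kmers[is.na(full$n_kmers)] <- 0
  counts <- full$n_kmers

  cutoff <- 0L
  if (length(counts) > 2) {
    drops <- which(diff(counts) > 0)  # first rise after a fall = local min
    if (length(drops) && drops[1] > 1 && counts[1] > counts[drops[1]]) {
      cutoff <- drops[1]
    }
  }
  above <- full[full$depth > cutoff, , drop = FALSE]
  if (nrow(above) == 0 || all(diff(counts) <= 0)) {
    stop("no coverage peak in k-mer histogram", call. = FALSE)
  }
  mode_depth <- above$depth[which.max(above$n_kmers)]
  if (mode_depth <= cutoff || (cutoff == 0 && mode_depth == 1)) {
    stop("no coverage peak in k-mer histogram", call. = FALSE)
  }
  # the raw mode of a skewed counting distribution is quantised to integers;
  # the count-weighted mean depth over a window around the mode estimates
  # the coverage peak smoothly and is what the size formula divides by
  win <- above[above$depth >= mode_depth / 2 &
                 above$depth <= 1.5 * mode_depth, , drop = FALSE]
  peak_depth <- sum(win$depth * win$n_kmers) / sum(win$n_kmers)
  used <- sum(above$depth * above$n_kmers)
  tibble::tibble(
    genome_size_bp = used / peak_depth,
    peak_depth = peak_depth,
    error_cutoff = cutoff,
    total_kmers_used = used,
    k = attr(hist, "k") %||% NA_integer_
  )
}
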