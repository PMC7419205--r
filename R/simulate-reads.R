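#' Simulate a random genome sequence
#'
#' Uniform-composition sequence for read simulation and k-mer survey tests.
#'
#' @param n_bp Genome length in bp.
#' @param seed Integer seed.
#' @return A single-element named character vector.
#' @export
simulate_genome_sequence <- function(n_bp, seed = 1L) {
  withr::with_seed(seed, {
    stats::setNames(paste(sample(BASES, n_bp, replace = TRUE),
                          collapse = ""), "genome1")
  })
}

#' Simulate error-free sequencing reads
#'
#' Reads are sampled uniformly from both strands of the genome until the
#' total base count reaches `coverage` times the genome length (to within
#' one read). No sequencing errors are introduced.
#'
#' @param genome Named character vector of chromosome/contig sequences (or a
#'   [Biostrings::DNAStringSet], or a single string).
#' @param coverage Fold coverage (> 0).
#' @param read_length Read length in bp; must not exceed the longest
#'   sequence.
#' @param seed Integer seed.
#' @return A tibble: `read_id`, `seq`.
#' @export
#' @examples
#' reads <- simulate_reads(simulate_genome_sequence(2000, 1),
#'                         coverage = 5, read_length = 100, seed = 1)
#' nrow(reads)  # ~ 5 * 2000 / 100 = 100
simulate_reads <- function(genome, coverage, read_length, seed = 1L) {
  if (inherits(genome, "XStringSet")) genome <- as.character(genome)
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  lens <- nchar(genome)
  if (read_length > max(lens)) {
    stop("read_length (", read_length, ") exceeds the genome length",
         call. = FALSE)
  }
  usable <- lens >= read_length
  genome <- genome[usable]
  lens <- lens[usable]
  n_reads <- round(coverage * sum(lens) / read_length)
  withr::with_seed(seed, {
    n_starts <- lens - read_length + 1
    src <- sample.int(length(genome), n_reads, replace = TRUE,
                      prob = n_starts)
    start <- floor(stats::runif(n_reads) * n_starts[src]) + 1
    fwd <- stats::runif(n_reads) < 0.5
    seqs <- substring(genome[src], start, start + read_length - 1)
    if (any(!fwd)) {
      seqs[!fwd] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[!fwd]))
      )
    }
    tibble::tibble(read_id = sprintf("read%07d", seq_len(n_reads)),
                   seq = unname(seqs))
  })
}
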