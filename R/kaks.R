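#' Codon-aware pairwise alignment of two coding sequences
#'
#' Translates both CDS to protein, aligns the proteins globally (BLOSUM62,
#' affine gaps) and back-translates the gaps so that the nucleotide alignment
#' contains gaps only in whole-codon units. A trailing stop codon on either
#' sequence is removed before alignment; internal stop codons are an error.
#'
#' @param cds_a,cds_b Coding sequences as single character strings (or
#'   anything coercible by [as.character()]), lengths divisible by 3.
#' @param gap_opening,gap_extension Affine gap penalties for the protein
#'   alignment.
#'
#' @return An object of class `codon_alignment`: a list with elements
#'   `aln_a`, `aln_b` (gap-padded nucleotide strings of equal length,
#'   divisible by 3), `n_codons_compared` (gap-free codon columns) and
#'   `score` (protein alignment score; `NA` for the identical-protein fast
#'   path).
#' @export
#' @examples
#' aln <- align_codons("ATGGCTGCT", "ATGGCT")
#' aln$n_codons_compared
align_codons <- function(cds_a, cds_b, gap_opening = 10, gap_extension = 0.5) {
  a <- toupper(as.character(cds_a))
  b <- toupper(as.character(cds_b))
  check_cds(a, "cds_a")
  check_cds(b, "cds_b")
  a <- strip_trailing_stop(a)
  b <- strip_trailing_stop(b)
  prot_a <- translate_cds(a, "cds_a")
  prot_b <- translate_cds(b, "cds_b")

  if (prot_a == prot_b) {
    out <- list(aln_a = a, aln_b = b, n_codons_compared = nchar(a) / 3,
                score = NA_real_)
    class(out) <- "codon_alignment"
    return(out)
  }

  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
    type = "global", substitutionMatrix = BLOSUM62,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  ap <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  out <- list(
    aln_a = backtranslate_gaps(ap, a),
    aln_b = backtranslate_gaps(as_, b),
    n_codons_compared = NA_integer_,
    score = Biostrings::score(pa)
  )
  out$n_codons_compared <- sum(
    split_codons(out$aln_a) != "---" & split_codons(out$aln_b) != "---"
  )
  class(out) <- "codon_alignment"
  out
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", nchar(x$aln_a) / 3, " codon columns, ",
      x$n_codons_compared, " compared\n", sep = "")
  invisible(x)
}

check_cds <- function(seq, label) {
  if (nchar(seq) == 0 || nchar(seq) %% 3 != 0) {
    stop(sprintf("`%s` length (%d) is not a positive multiple of 3",
                 label, nchar(seq)), call. = FALSE)
  }
  invisible(seq)
}

strip_trailing_stop <- function(seq) {
  n <- nchar(seq)
  last <- substr(seq, n - 2, n)
  aa <- codon_aa()[codon_index(last)]
  if (!is.na(aa) && aa == "*") substr(seq, 1, n - 3) else seq
}

translate_cds <- function(seq, label) {
  idx <- codon_index(split_codons(seq))
  if (anyNA(idx)) {
    stop(sprintf("`%s` contains non-ACGT codons", label), call. = FALSE)
  }
  aa <- codon_aa()[idx]
  if (any(aa == "*")) {
    stop(sprintf("internal stop codon in `%s` (codon %d)",
                 label, which(aa == "*")[1]), call. = FALSE)
  }
  paste(aa, collapse = "")
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

# Expand a gapped protein string back to a gapped nucleotide string, consuming
# codons from the ungapped CDS.
backtranslate_gaps <- function(gapped_prot, cds) {
  cod <- split_codons(cds)
  chars <- strsplit(gapped_prot, "")[[1]]
  out <- character(length(chars))
  k <- 0
  for (i in seq_along(chars)) {
    if (chars[i] == "-") {
      out[i] <- "---"
    } else {
      k <- k + 1
      out[i] <- cod[k]
    }
  }
  paste(out, collapse = "")
}

#' Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction
#'
#' Counts synonymous and nonsynonymous sites and differences over the
#' gap-free codon columns of a codon alignment, then applies the
#' Jukes-Cantor multiple-hit correction. Site fractions are averaged over
#' both codons of a column; differences are averaged over all minimal
#' substitution pathways, excluding pathways that pass through a stop codon.
#'
#' @param alignment A `codon_alignment` from [align_codons()], or a list with
#'   elements `aln_a` and `aln_b` (equal-length gap-padded CDS).
#'
#' @return A one-row tibble with columns `n_codons` (gap-free codon columns
#'   compared), `S`, `N` (synonymous / nonsynonymous site counts, fractional;
#'   `S + N` equals `3 * n_codons` exactly), `Sd`, `Nd` (pathway-averaged
#'   difference counts), `ps`, `pn` (proportions), `ks`, `ka` (Jukes-Cantor
#'   corrected rates, `NA` when the correction is undefined) and `saturated`
#'   (`TRUE` when `ps >= 3/4` or `pn >= 3/4`).
#' @export
#' @examples
#' aln <- align_codons(strrep("TTT", 10), paste0(strrep("TTT", 9), "TTC"))
#' ng86_kaks(aln)
ng86_kaks <- function(alignment) {
  ca <- split_codons(alignment$aln_a)
  cb <- split_codons(alignment$aln_b)
  if (length(ca) != length(cb)) {
    stop("aligned sequences differ in codon length", call. = FALSE)
  }
  ia <- codon_index(ca)
  ib <- codon_index(cb)
  s <- syn_site_counts()
  keep <- !is.na(ia) & !is.na(ib) & !is.na(s[ia]) & !is.na(s[ib])
  ia <- ia[keep]; ib <- ib[keep]
  n_codons <- length(ia)
  if (n_codons == 0) {
    stop("no gap-free comparable codon columns in alignment", call. = FALSE)
  }
  mats <- diff_matrices()
  S <- sum((s[ia] + s[ib]) / 2)
  N <- 3 * n_codons - S
  Sd <- sum(mats$sd[cbind(ia, ib)])
  Nd <- sum(mats$nd[cbind(ia, ib)])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  tibble::tibble(
    n_codons = n_codons, S = S, N = N, Sd = Sd, Nd = Nd,
    ps = ps, pn = pn,
    ks = jc_correct(ps), ka = jc_correct(pn),
    saturated = ps >= 0.75 | pn >= 0.75
  )
}

#' Ka/Ks for one pair of coding sequences
#'
#' Convenience wrapper: [align_codons()] followed by [ng86_kaks()].
#'
#' @inheritParams align_codons
#' @return See [ng86_kaks()].
#' @export
kaks_pair <- function(cds_a, cds_b) {
  ng86_kaks(align_codons(cds_a, cds_b))
}

#' Ka/Ks table for every anchor pair of a set of syntenic blocks
#'
#' @param blocks A block tibble from [chain_blocks()] (one row per block with
#'   an `anchors` list-column), or an unnested tibble with columns
#'   `block_id`, `gene_a`, `gene_b`.
#' @param cds A named character vector, named [Biostrings::DNAStringSet] or
#'   named list of CDS covering every gene referenced by the blocks.
#'
#' @return A tibble with one row per anchor pair, ordered by `block_id` then
#'   anchor rank: `gene_a`, `gene_b`, `block_id`, `ka`, `ks`, `saturated`
#'   (saturated pairs carry `NA` in `ks`).
#' @export
kaks_table <- function(blocks, cds) {
  cds <- as_cds_vector(cds)
  pairs <- if ("anchors" %in% names(blocks)) {
    tidyr::unnest(dplyr::select(blocks, "block_id", "anchors"),
                  cols = "anchors")
  } else {
    blocks
  }
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(missing)) {
    stop("CDS missing for gene(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  est <- purrr::map2_dfr(pairs$gene_a, pairs$gene_b, function(ga, gb) {
    kaks_pair(cds[[ga]], cds[[gb]])
  })
  dplyr::bind_cols(
    dplyr::select(pairs, "gene_a", "gene_b", "block_id"),
    dplyr::select(est, "ka", "ks", "saturated")
  )
}

as_cds_vector <- function(cds) {
  if (inherits(cds, "XStringSet")) {
    out <- as.character(cds)
  } else {
    out <- vapply(as.list(cds), as.character, character(1))
  }
  if (is.null(names(out)) || any(names(out) == "")) {
    stop("CDS set must be named by gene id", call. = FALSE)
  }
  out
}
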