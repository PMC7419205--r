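# Readers and writers for the standard interchange formats. Internal
# coordinates are 0-based half-open; GFF3 is 1-based inclusive on disk, BED
# 0-based half-open, and the conversions happen here and nowhere else.

#' Read gene positions from GFF3 or BED
#'
#' `gene`-type features (GFF3) or all intervals (BED) become the internal
#' gene table; ranks are assigned by start position within each chromosome.
#'
#' @param path File path; format inferred from the extension (`.gff`,
#'   `.gff3` or `.bed`) unless `format` is given.
#' @param format `"gff3"`, `"bed"` or `NULL` (infer).
#' @return A tibble: `gene_id`, `chromosome`, `rank` (0-based), `start`,
#'   `end` (0-based half-open), `strand`.
#' @export
read_gene_positions <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
     else if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
     else stop("cannot infer format of '", path, "'", call. = FALSE))
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    ids <- gr$ID %||% gr$Name
  } else {
    ids <- gr$name
  }
  if (is.null(ids) || anyNA(ids)) {
    stop("missing gene identifiers in ", path, call. = FALSE)
  }
  tbl <- tibble::tibble(
    gene_id = as.character(ids),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  tbl$strand[!tbl$strand %in% c("+", "-")] <- "+"
  tbl |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number() - 1L) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "chromosome", "rank", "start", "end", "strand")
}

#' Write gene positions as GFF3 or BED
#'
#' @param genes Gene tibble (internal 0-based half-open coordinates).
#' @inheritParams read_gene_positions
#' @return `path`, invisibly.
#' @export
write_gene_positions <- function(genes, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  if (format == "gff3") {
    gr$type <- "gene"
    gr$ID <- genes$gene_id
    gr$source <- "paleodup"
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr$name <- genes$gene_id
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] returning plain named character vectors.
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fasta
#' @param seqs Named character vector (or coercible sequence set).
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read / write FASTQ reads
#'
#' @param path File path.
#' @return `read_fastq()`: a tibble with `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 seq = unname(as.character(x)))
}

#' @rdname read_fastq
#' @param reads Tibble with `read_id` and `seq` (e.g. [simulate_reads()]).
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  qual <- Biostrings::PhredQuality(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read BLAST tabular (outfmt 6) homology hits
#'
#' Standard 12-column BLAST tabular output; only query, subject and
#' bitscore are retained, but all 12 columns are parsed and named.
#'
#' @param path File path.
#' @return A tibble with the 12 standard columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`).
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  readr::read_tsv(path, col_names = cols, comment = "#",
                  show_col_types = FALSE)
}

#' Read / write LTR pair FASTA
#'
#' The on-disk convention is one FASTA with two records per element,
#' `<element>_5p` and `<element>_3p`.
#'
#' @param path File path.
#' @return `read_ltr_pairs()`: a tibble `element_id`, `ltr5`, `ltr3`.
#' @export
read_ltr_pairs <- function(path) {
  seqs <- read_fasta(path)
  ids <- sub("_[53]p$", "", names(seqs))
  side <- sub("^.*_([53]p)$", "\\1", names(seqs))
  tibble::tibble(element_id = ids, side = side, seq = unname(seqs)) |>
    tidyr::pivot_wider(names_from = "side", values_from = "seq") |>
    dplyr::rename(ltr5 = "5p", ltr3 = "3p") |>
    dplyr::select("element_id", "ltr5", "ltr3")
}

#' @rdname read_ltr_pairs
#' @param cohort Tibble with `element_id`, `ltr5`, `ltr3`.
#' @export
write_ltr_pairs <- function(cohort, path) {
  seqs <- c(stats::setNames(cohort$ltr5, paste0(cohort$element_id, "_5p")),
            stats::setNames(cohort$ltr3, paste0(cohort$element_id, "_3p")))
  ord <- order(names(seqs))
  write_fasta(seqs[ord], path)
}

#' Write a TSV report with provenance header
#'
#' Prepends `#`-comment lines carrying the package version, a hash of the
#' generating configuration and the seed, so every artefact of a pipeline
#' run is self-describing.
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @param config Arbitrary R object hashed into the header (optional).
#' @param seed Seed recorded in the header (optional).
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(tbl, path, config = NULL, seed = NULL) {
  writeLines(provenance_header(config, seed), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

provenance_header <- function(config = NULL, seed = NULL) {
  c(paste0("# paleodup ",
           as.character(utils::packageVersion("paleodup"))),
    if (!is.null(config)) paste0("# config_hash=", rlang::hash(config)),
    if (!is.null(seed)) paste0("# seed=", seed))
}

#' Write syntenic blocks as a collinearity-style text report
#'
#' A compact MCScanX-`.collinearity`-like listing: one header line per
#' block, one indented line per anchor pair.
#'
#' @param blocks Blocks tibble from [chain_blocks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collinearity <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    writeLines(sprintf("## %s: score=%.1f %s&%s %s n=%d",
                       b$block_id, b$score, b$chrom_a, b$chrom_b,
                       b$orientation, b$n_anchors), con)
    a <- b$anchors[[1]]
    writeLines(sprintf("  %s\t%s", a$gene_a, a$gene_b), con)
  }
  invisible(path)
}

#' Flatten a blocks tibble for TSV output
#'
#' @param blocks Blocks tibble from [chain_blocks()].
#' @return One row per anchor with block metadata columns.
#' @export
blocks_to_table <- function(blocks) {
  blocks |>
    dplyr::select("block_id", "chrom_a", "chrom_b", "orientation",
                  "n_anchors", "anchors") |>
    tidyr::unnest(cols = "anchors")
}
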