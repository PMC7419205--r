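#' Anchor pairs from homology hits
#'
#' Filters a homology hit table (BLAST outfmt-6 style: query id, subject id,
#' bitscore) down to the anchor pairs used for collinearity chaining: per
#' query gene the `top_k` best-scoring partners with score at least
#' `min_score` are kept, self-hits are removed and the symmetric closure is
#' taken, so an anchor survives if either gene ranks the other among its
#' best partners.
#'
#' @param genes_a,genes_b Gene tibbles (columns `gene_id`, `chromosome`,
#'   `rank` at minimum), e.g. `sim_genome$genes` or [read_gene_positions()]
#'   output. For a self-comparison pass the same tibble twice.
#' @param hits A tibble/data.frame of homology hits with columns `qseqid`,
#'   `sseqid` and `bitscore` (extra columns are ignored), e.g. from
#'   [read_blast_tab()] or [homology_hits()].
#' @param top_k Maximum number of partners kept per query gene.
#' @param min_score Minimum score for a hit to be considered.
#'
#' @return A tibble of anchors: `gene_a`, `gene_b`, `score`, one row per
#'   unordered pair (for self-comparisons `gene_a` is the lower-ranked
#'   member).
#' @export
find_anchors <- function(genes_a, genes_b, hits, top_k = 5, min_score = 0) {
  stopifnot(all(c("qseqid", "sseqid", "bitscore") %in% names(hits)))
  known <- union(genes_a$gene_id, genes_b$gene_id)
  unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), known)
  if (length(unknown)) {
    stop("hit table references unknown gene id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  self_cmp <- identical(genes_a$gene_id, genes_b$gene_id)

  # per-query top-k cut on the directed hits as given, then symmetric
  # closure: an anchor survives if either gene ranked the other
  h <- tibble::as_tibble(hits) |>
    dplyr::filter(.data$qseqid != .data$sseqid,
                  .data$bitscore >= min_score) |>
    dplyr::distinct(.data$qseqid, .data$sseqid, .keep_all = TRUE) |>
    dplyr::group_by(.data$qseqid) |>
    dplyr::slice_max(.data$bitscore, n = top_k, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("qseqid", "sseqid", "bitscore")

  if (nrow(h) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          score = numeric()))
  }
  if (self_cmp) {
    pairs <- h |>
      dplyr::mutate(gene_a = pmin(.data$qseqid, .data$sseqid),
                    gene_b = pmax(.data$qseqid, .data$sseqid))
  } else {
    in_a <- h$qseqid %in% genes_a$gene_id
    pairs <- tibble::tibble(
      gene_a = ifelse(in_a, h$qseqid, h$sseqid),
      gene_b = ifelse(in_a, h$sseqid, h$qseqid),
      bitscore = h$bitscore
    ) |>
      dplyr::filter(.data$gene_a %in% genes_a$gene_id,
                    .data$gene_b %in% genes_b$gene_id)
  }
  pairs |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(score = max(.data$bitscore), .groups = "drop")
}

#' Homology hits from coding sequences
#'
#' Generates a BLAST-like hit table by comparing protein translations.
#' Sequences whose translations are identical are reported as reciprocal
#' hits with score proportional to protein length; for mixed inputs an
#' optional global-alignment pass scores non-identical pairs by alignment
#' identity (only pairs with identity at or above `min_identity` are
#' reported). The exact-translation path is what the simulator needs
#' (synonymous-only divergence leaves proteins identical); real data should
#' come in as an external BLAST tabular file instead.
#'
#' @param cds_a,cds_b Named CDS sets (character vector or
#'   [Biostrings::DNAStringSet]). Omit `cds_b` for a self-comparison.
#' @param method `"translation"` (group identical proteins; fast) or
#'   `"alignment"` (all-vs-all global protein alignment; quadratic, for
#'   small inputs).
#' @param min_identity Identity threshold for the alignment method.
#' @return A tibble with `qseqid`, `sseqid`, `bitscore`.
#' @export
homology_hits <- function(cds_a, cds_b = NULL,
                          method = c("translation", "alignment"),
                          min_identity = 0.5) {
  method <- match.arg(method)
  a <- as_cds_vector(cds_a)
  b <- if (is.null(cds_b)) a else as_cds_vector(cds_b)
  prot_a <- vapply(a, function(x) translate_cds(strip_trailing_stop(x), "cds"),
                   character(1))
  prot_b <- if (is.null(cds_b)) prot_a else {
    vapply(b, function(x) translate_cds(strip_trailing_stop(x), "cds"),
           character(1))
  }
  if (method == "translation") {
    key_b <- split(names(prot_b), prot_b)
    out <- purrr::imap_dfr(prot_a, function(p, id) {
      partners <- setdiff(key_b[[p]], id)
      if (!length(partners)) return(NULL)
      tibble::tibble(qseqid = id, sseqid = partners,
                     bitscore = 2 * nchar(p))
    })
    return(out)
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  grid <- tidyr::expand_grid(q = names(prot_a), s = names(prot_b)) |>
    dplyr::filter(.data$q != .data$s)
  purrr::pmap_dfr(grid, function(q, s) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(prot_a[[q]]), Biostrings::AAString(prot_b[[s]]),
      type = "global", substitutionMatrix = BLOSUM62,
      gapOpening = 10, gapExtension = 0.5)
    ident <- Biostrings::pid(pa) / 100
    if (ident < min_identity) return(NULL)
    tibble::tibble(qseqid = q, sseqid = s,
                   bitscore = ident * nchar(prot_a[[q]]) * 2)
  })
}

#' Chain anchors into syntenic blocks
#'
#' Dynamic-programming collinearity chaining in the style of MCScanX: within
#' each chromosome pair, maximal-score chains of anchors with strictly
#' increasing ranks on one side and strictly monotone ranks on the other
#' (both orientations searched) are extracted greedily, highest score
#' first; each anchor joins at most one block. Consecutive anchors may be
#' separated by at most `max_gap` gene ranks on either chromosome. The chain
#' score is the number of anchors minus 0.5 per gapped step (a step whose
#' rank gap exceeds 1 on either side).
#'
#' @inheritParams find_anchors
#' @param anchors Anchor tibble from [find_anchors()].
#' @param min_anchors Minimum anchors per reported block.
#' @param max_gap Maximum rank gap between consecutive anchors.
#'
#' @return A tibble of blocks ordered by chromosome pair: `block_id`,
#'   `chrom_a`, `chrom_b`, `orientation` (`"same"` or `"inverted"`),
#'   `n_anchors`, `score`, and an `anchors` list-column of tibbles
#'   (`gene_a`, `gene_b`, `rank_a`, `rank_b`, in chain order).
#' @export
chain_blocks <- function(anchors, genes_a, genes_b, min_anchors = 5,
                         max_gap = 25) {
  if (nrow(anchors) == 0) return(empty_blocks())
  pos_a <- dplyr::select(genes_a, gene_a = "gene_id", chrom_a = "chromosome",
                         rank_a = "rank")
  pos_b <- dplyr::select(genes_b, gene_b = "gene_id", chrom_b = "chromosome",
                         rank_b = "rank")
  tab <- anchors |>
    dplyr::inner_join(pos_a, by = "gene_a") |>
    dplyr::inner_join(pos_b, by = "gene_b")
  self_cmp <- identical(genes_a$gene_id, genes_b$gene_id)

  blocks <- tab |>
    dplyr::group_by(.data$chrom_a, .data$chrom_b) |>
    dplyr::group_split() |>
    purrr::map(chain_chrom_pair, min_anchors = min_anchors,
               max_gap = max_gap, self_cmp = self_cmp) |>
    purrr::list_rbind()
  if (nrow(blocks) == 0) return(empty_blocks())
  blocks |>
    dplyr::arrange(.data$chrom_a, .data$chrom_b, dplyr::desc(.data$score)) |>
    dplyr::mutate(block_id = sprintf("block_%04d", dplyr::row_number()),
                  .before = 1)
}

empty_blocks <- function() {
  tibble::tibble(block_id = character(), chrom_a = character(),
                 chrom_b = character(), orientation = character(),
                 n_anchors = integer(), score = numeric(),
                 anchors = list())
}

# Greedy best-chain extraction for the anchors of one chromosome pair. In a
# self-comparison, anchors on the diagonal of one chromosome would chain a
# segment with itself, so only the upper triangle is kept there.
chain_chrom_pair <- function(tab, min_anchors, max_gap, self_cmp = FALSE) {
  if (self_cmp && tab$chrom_a[1] == tab$chrom_b[1]) {
    tab <- tab[tab$rank_a < tab$rank_b, , drop = FALSE]
  }
  out <- list()
  while (nrow(tab) >= min_anchors) {
    best <- NULL
    for (orient in c("same", "inverted")) {
      ch <- best_chain(tab$rank_a, tab$rank_b, orient, max_gap)
      if (is.null(best) || ch$score > best$score) {
        best <- ch
        best$orientation <- orient
      }
    }
    if (length(best$idx) < min_anchors) break
    out[[length(out) + 1L]] <- tibble::tibble(
      chrom_a = tab$chrom_a[1], chrom_b = tab$chrom_b[1],
      orientation = best$orientation,
      n_anchors = length(best$idx), score = best$score,
      anchors = list(dplyr::select(tab[best$idx, ], "gene_a", "gene_b",
                                   "rank_a", "rank_b"))
    )
    tab <- tab[-best$idx, , drop = FALSE]
  }
  purrr::list_rbind(out)
}

# Single best collinear chain by dynamic programming over anchors ordered by
# rank_a. Chain score = anchors - 0.5 per step with a rank gap > 1 on either
# side; steps longer than max_gap ranks on either side are forbidden.
best_chain <- function(rank_a, rank_b, orientation, max_gap) {
  rb <- if (orientation == "inverted") -rank_b else rank_b
  ord <- order(rank_a, rb)
  ra <- rank_a[ord]
  rb <- rb[ord]
  n <- length(ra)
  score <- rep(1, n)
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      da <- ra[j] - ra[i]
      db <- rb[j] - rb[i]
      if (da <= 0 || db <= 0 || da > max_gap || db > max_gap) next
      step <- 1 - 0.5 * (da > 1 || db > 1)
      cand <- score[i] + step
      if (cand > score[j]) {
        score[j] <- cand
        prev[j] <- i
      }
    }
  }
  end <- which.max(score)
  idx <- integer(0)
  k <- end
  while (!is.na(k)) {
    idx <- c(k, idx)
    k <- prev[k]
  }
  list(idx = ord[idx], score = score[end])
}

#' Classify duplicate gene pairs by origin
#'
#' Mirrors the MCScanX duplicate-mode hierarchy: a pair inside a syntenic
#' block is `wgd_segmental`; otherwise a rank-adjacent pair on one
#' chromosome is `tandem`; otherwise a pair within `proximal_max` ranks is
#' `proximal`; everything else is `dispersed`. Precedence is in that order,
#' so every pair gets exactly one class.
#'
#' @inheritParams chain_blocks
#' @param genes Gene tibble covering both members of every anchor pair.
#' @param blocks Blocks from [chain_blocks()] on the same gene set.
#' @param proximal_max Maximum rank separation for the `proximal` class.
#' @return The anchor tibble with a `class` factor column.
#' @export
classify_duplications <- function(genes, anchors, blocks, proximal_max = 10) {
  in_block <- if (nrow(blocks) > 0) {
    blocks |>
      dplyr::select("anchors") |>
      tidyr::unnest(cols = "anchors") |>
      dplyr::mutate(key = paste(.data$gene_a, .data$gene_b)) |>
      dplyr::pull("key")
  } else {
    character(0)
  }
  pos <- dplyr::select(genes, "gene_id", "chromosome", "rank")
  anchors |>
    dplyr::left_join(dplyr::rename(pos, gene_a = "gene_id",
                                   chrom_a = "chromosome", rank_a = "rank"),
                     by = "gene_a") |>
    dplyr::left_join(dplyr::rename(pos, gene_b = "gene_id",
                                   chrom_b = "chromosome", rank_b = "rank"),
                     by = "gene_b") |>
    dplyr::mutate(
      same_chrom = .data$chrom_a == .data$chrom_b,
      drank = abs(.data$rank_a - .data$rank_b),
      class = factor(dplyr::case_when(
        paste(.data$gene_a, .data$gene_b) %in% in_block ~ "wgd_segmental",
        .data$same_chrom & .data$drank == 1 ~ "tandem",
        .data$same_chrom & .data$drank <= proximal_max ~ "proximal",
        TRUE ~ "dispersed"
      ), levels = c("wgd_segmental", "tandem", "proximal", "dispersed"))
    ) |>
    dplyr::select("gene_a", "gene_b", "score", "class")
}

#' Syntenic depth profile between two genomes
#'
#' For every gene of each genome, counts the number of distinct syntenic
#' blocks (with at least `min_cov_anchors` anchors) whose rank span on that
#' genome covers the gene. The modal depth over covered genes summarises how
#' many duplicated regions of the other genome correspond to one region
#' here: an unduplicated outgroup against a two-round paleopolyploid shows a
#' `1:4` profile. The ratio is labelled outgroup:target, i.e. modal coverage
#' of target genes by outgroup regions first.
#'
#' @inheritParams chain_blocks
#' @param blocks Blocks from [chain_blocks()] computed between `genes_a`
#'   (reference/outgroup) and `genes_b` (target).
#' @param min_cov_anchors Minimum anchors for a block to contribute
#'   coverage.
#' @return An object of class `depth_profile`: a list with `gene_depth` (a
#'   tibble: `genome` (`"a"`/`"b"`), `gene_id`, `depth`), `modal_depth_a`,
#'   `modal_depth_b` (modal depth over covered genes of each genome) and
#'   `ratio_label` (`"modal_b:modal_a"`, outgroup:target; smallest first
#'   for a self-comparison).
#' @export
syntenic_depth <- function(blocks, genes_a, genes_b, min_cov_anchors = 5) {
  use <- blocks[blocks$n_anchors >= min_cov_anchors, , drop = FALSE]
  spans <- if (nrow(use) > 0) {
    use |>
      dplyr::select("block_id", "chrom_a", "chrom_b", "anchors") |>
      tidyr::unnest(cols = "anchors") |>
      dplyr::group_by(.data$block_id, .data$chrom_a, .data$chrom_b) |>
      dplyr::summarise(lo_a = min(.data$rank_a), hi_a = max(.data$rank_a),
                       lo_b = min(.data$rank_b), hi_b = max(.data$rank_b),
                       .groups = "drop")
  } else {
    tibble::tibble(block_id = character(), chrom_a = character(),
                   chrom_b = character(), lo_a = integer(), hi_a = integer(),
                   lo_b = integer(), hi_b = integer())
  }
  depth_a <- gene_block_depth(genes_a, spans, "a")
  depth_b <- gene_block_depth(genes_b, spans, "b")
  modal_a <- modal_depth(depth_a$depth)
  modal_b <- modal_depth(depth_b$depth)
  self_cmp <- identical(genes_a$gene_id, genes_b$gene_id)
  lab <- if (self_cmp) {
    paste(sort(c(modal_a, modal_b)), collapse = ":")
  } else {
    paste0(modal_b, ":", modal_a)
  }
  structure(list(
    gene_depth = dplyr::bind_rows(depth_a, depth_b),
    modal_depth_a = modal_a, modal_depth_b = modal_b,
    ratio_label = lab
  ), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("<depth_profile> modal depths a=", x$modal_depth_a,
      " b=", x$modal_depth_b, " ratio ", x$ratio_label, "\n", sep = "")
  invisible(x)
}

gene_block_depth <- function(genes, spans, side) {
  chrom_col <- paste0("chrom_", side)
  lo <- spans[[paste0("lo_", side)]]
  hi <- spans[[paste0("hi_", side)]]
  span_chrom <- spans[[chrom_col]]
  depth <- vapply(seq_len(nrow(genes)), function(i) {
    sum(span_chrom == genes$chromosome[i] &
          lo <= genes$rank[i] & hi >= genes$rank[i])
  }, numeric(1))
  tibble::tibble(genome = side, gene_id = genes$gene_id, depth = depth)
}

modal_depth <- function(depth) {
  depth <- depth[depth >= 1]
  if (!length(depth)) return(0L)
  tab <- table(depth)
  as.integer(names(tab)[which.max(tab)])
}
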