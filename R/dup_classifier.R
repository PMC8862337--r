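# Duplicate-gene classification: singleton / dispersed / proximal / tandem /
# WGD-or-segmental, from homolog pairs and gene positions. Collinear blocks
# are found by dynamic-programming anchor chaining on gene ranks.

DUP_CATEGORIES <- c("singleton", "dispersed", "proximal", "tandem",
                    "wgd_segmental")

#' Read gene models from a GFF3 file
#'
#' Imports `gene` features with `rtracklayer` and returns the columns the
#' classifier needs.
#'
#' @param path GFF3 path.
#' @return data frame `gene_id`, `chromosome`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type == "gene", , drop = FALSE]
  ids <- if (!is.null(df$ID)) df$ID else df$Name
  data.frame(
    gene_id = as.character(ids),
    chromosome = as.character(df$seqnames),
    start = df$start,
    end = df$end,
    strand = as.character(df$strand),
    stringsAsFactors = FALSE
  )
}

#' Assign per-chromosome gene ranks
#'
#' Ranks are 0-based ordinals along each chromosome, sorted by start position
#' (ties by end, then gene id, so overlapping models order deterministically).
#'
#' @param genes data frame with `gene_id`, `chromosome`, `start`, `end`
#'   (e.g. from [read_gene_models()]), or a GFF3 path.
#' @return the input with a `rank` column added, sorted by chromosome and
#'   rank.
#' @export
assign_ranks <- function(genes) {
  if (is.character(genes)) genes <- read_gene_models(genes)
  if (anyDuplicated(genes$gene_id)) {
    stop_validation("assign_ranks: duplicate gene ids")
  }
  if (any(genes$start > genes$end)) {
    stop_validation("assign_ranks: start must be <= end")
  }
  genes <- genes[order(genes$chromosome, genes$start, genes$end,
                       genes$gene_id), , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chromosome,
                           FUN = function(i) seq_along(i) - 1L)
  rownames(genes) <- NULL
  genes
}

# anchors for one chromosome pair, as (rank_a, rank_b) with gene ids
pair_anchors <- function(pairs, genes) {
  idx_a <- match(pairs$gene_a, genes$gene_id)
  idx_b <- match(pairs$gene_b, genes$gene_id)
  if (anyNA(idx_a) || anyNA(idx_b)) {
    stop_validation("pairs reference genes absent from the catalogue")
  }
  data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    chr_a = genes$chromosome[idx_a], chr_b = genes$chromosome[idx_b],
    rank_a = genes$rank[idx_a], rank_b = genes$rank[idx_b],
    start_a = genes$start[idx_a],
    stringsAsFactors = FALSE
  )
}

# normalise a pair table: drop self pairs, deduplicate unordered pairs
normalize_pairs <- function(pairs) {
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  key <- ifelse(pairs$gene_a < pairs$gene_b,
                paste(pairs$gene_a, pairs$gene_b, sep = "\r"),
                paste(pairs$gene_b, pairs$gene_a, sep = "\r"))
  pairs[!duplicated(key), , drop = FALSE]
}

# longest chain (most anchors) with both rank increments in (0, max_gap];
# direction = -1 searches descending rank_b (inverted blocks)
best_chain <- function(rank_a, rank_b, max_gap, direction = 1) {
  n <- length(rank_a)
  ord <- order(rank_a, direction * rank_b)
  ra <- rank_a[ord]
  rb <- rank_b[ord] * direction
  score <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      da <- ra[i] - ra[j]
      db <- rb[i] - rb[j]
      if (da > 0 && da <= max_gap && db > 0 && db <= max_gap &&
          score[j] + 1L > score[i]) {
        score[i] <- score[j] + 1L
        prev[i] <- j
      }
    }
  }
  best <- which.max(score)
  chain <- integer(0)
  at <- best
  while (!is.na(at)) {
    chain <- c(at, chain)
    at <- prev[at]
  }
  list(idx = ord[chain], length = score[best])
}

#' Find collinear blocks by anchor chaining
#'
#' Homolog pairs are grouped per chromosome pair and chained by dynamic
#' programming over gene ranks: a chain extends when both rank increments lie
#' in `(0, max_rank_gap]` (rank on the second chromosome may run consistently
#' backwards, for inverted blocks). Chains with at least `min_anchors`
#' anchors are emitted greedily by size; each anchor joins at most one block.
#' Same-chromosome anchors closer than `self_exclude_gap` ranks are excluded
#' from chaining: those near-diagonal pairs are tandem/proximal candidates,
#' not segmental evidence.
#'
#' @param pairs data frame `gene_a`, `gene_b`.
#' @param genes ranked gene catalogue from [assign_ranks()].
#' @param min_anchors minimum anchors per block (default 5).
#' @param max_rank_gap maximum rank gap between consecutive anchors
#'   (default 25).
#' @param self_exclude_gap same-chromosome rank distance excluded from
#'   chaining (default 10, the proximal window).
#' @return list of blocks, each with `block_id`, `anchors` (data frame of
#'   gene pairs), `chromosomes`, `orientation` (+1 or -1).
#' @export
find_collinear_blocks <- function(pairs, genes, min_anchors = 5,
                                  max_rank_gap = 25, self_exclude_gap = 10) {
  pairs <- normalize_pairs(pairs)
  if (nrow(pairs) == 0) return(list())
  anchors <- pair_anchors(pairs, genes)
  # orient each anchor so chr_a <= chr_b (rank order must follow the swap)
  swap <- anchors$chr_a > anchors$chr_b |
    (anchors$chr_a == anchors$chr_b & anchors$rank_a > anchors$rank_b)
  anchors[swap, c("gene_a", "gene_b", "chr_a", "chr_b", "rank_a", "rank_b")] <-
    anchors[swap, c("gene_b", "gene_a", "chr_b", "chr_a", "rank_b", "rank_a")]
  near_diag <- anchors$chr_a == anchors$chr_b &
    abs(anchors$rank_a - anchors$rank_b) <= self_exclude_gap
  anchors <- anchors[!near_diag, , drop = FALSE]
  if (nrow(anchors) == 0) return(list())

  blocks <- list()
  bid <- 0L
  for (cp in split(anchors, paste(anchors$chr_a, anchors$chr_b, sep = "\r"))) {
    remaining <- cp
    repeat {
      if (nrow(remaining) == 0) break
      fwd <- best_chain(remaining$rank_a, remaining$rank_b, max_rank_gap, 1)
      rev <- best_chain(remaining$rank_a, remaining$rank_b, max_rank_gap, -1)
      use <- if (rev$length > fwd$length) rev else fwd
      orientation <- if (rev$length > fwd$length) -1L else 1L
      if (use$length < min_anchors) break
      chain <- remaining[use$idx, , drop = FALSE]
      bid <- bid + 1L
      blocks[[bid]] <- list(
        block_id = bid,
        anchors = chain[c("gene_a", "gene_b", "rank_a", "rank_b")],
        chromosomes = c(chain$chr_a[1], chain$chr_b[1]),
        orientation = orientation
      )
      remaining <- remaining[-use$idx, , drop = FALSE]
    }
  }
  blocks
}

#' Classify genes into duplication categories
#'
#' Category priority: `wgd_segmental` (gene anchors a collinear block) >
#' `tandem` (same-chromosome homolog within `tandem_max_gap` ranks) >
#' `proximal` (within `proximal_max_gap` ranks) > `dispersed` (any other
#' homolog) > `singleton` (no homolog). Every gene gets exactly one category.
#'
#' @param genes ranked catalogue from [assign_ranks()].
#' @param pairs homolog pairs (`gene_a`, `gene_b`).
#' @param blocks blocks from [find_collinear_blocks()] over the same pairs.
#' @param tandem_max_gap rank distance for tandem calls (default 1:
#'   consecutive genes).
#' @param proximal_max_gap rank distance for proximal calls (default 10).
#' @return data frame `gene_id`, `category`.
#' @export
classify_duplicates <- function(genes, pairs, blocks = NULL,
                                tandem_max_gap = 1, proximal_max_gap = 10) {
  pairs <- normalize_pairs(pairs)
  if (is.null(blocks)) {
    blocks <- find_collinear_blocks(pairs, genes,
                                    self_exclude_gap = proximal_max_gap)
  }
  anchors <- if (nrow(pairs) > 0) pair_anchors(pairs, genes) else NULL
  block_genes <- unique(unlist(lapply(blocks, function(b) {
    c(b$anchors$gene_a, b$anchors$gene_b)
  })))

  category <- stats::setNames(rep("singleton", nrow(genes)), genes$gene_id)
  if (!is.null(anchors) && nrow(anchors) > 0) {
    same <- anchors$chr_a == anchors$chr_b
    gap <- abs(anchors$rank_a - anchors$rank_b)
    level <- ifelse(same & gap <= tandem_max_gap, "tandem",
                    ifelse(same & gap <= proximal_max_gap, "proximal",
                           "dispersed"))
    rank_of <- c(singleton = 0, dispersed = 1, proximal = 2, tandem = 3,
                 wgd_segmental = 4)
    for (i in seq_len(nrow(anchors))) {
      for (gid in c(anchors$gene_a[i], anchors$gene_b[i])) {
        if (rank_of[[level[i]]] > rank_of[[category[[gid]]]]) {
          category[[gid]] <- level[i]
        }
      }
    }
  }
  category[names(category) %in% block_genes] <- "wgd_segmental"
  data.frame(gene_id = genes$gene_id,
             category = unname(category[genes$gene_id]),
             stringsAsFactors = FALSE)
}

#' Count tandem pairs and the genes they involve
#'
#' A tandem pair is a homolog pair on one chromosome with rank distance at
#' most `tandem_max_gap`. Arrays of three consecutive copies yield two pairs
#' but three genes, so `2 * n_pairs` can exceed `n_genes`.
#'
#' @param pairs homolog pairs.
#' @param genes ranked catalogue.
#' @param tandem_max_gap rank distance (default 1).
#' @return list `n_pairs`, `n_genes`.
#' @export
tandem_pair_count <- function(pairs, genes, tandem_max_gap = 1) {
  pairs <- normalize_pairs(pairs)
  if (nrow(pairs) == 0) return(list(n_pairs = 0L, n_genes = 0L))
  anchors <- pair_anchors(pairs, genes)
  tandem <- anchors$chr_a == anchors$chr_b &
    abs(anchors$rank_a - anchors$rank_b) <= tandem_max_gap
  list(
    n_pairs = sum(tandem),
    n_genes = length(unique(c(anchors$gene_a[tandem], anchors$gene_b[tandem])))
  )
}

#' Per-category duplication counts
#'
#' @param calls output of [classify_duplicates()].
#' @return data frame `category`, `n`, in fixed category order, including
#'   zero rows; counts sum to the gene total.
#' @export
duplication_summary <- function(calls) {
  n <- vapply(DUP_CATEGORIES, function(ct) sum(calls$category == ct), 0L)
  data.frame(category = DUP_CATEGORIES, n = unname(n),
             stringsAsFactors = FALSE)
}
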