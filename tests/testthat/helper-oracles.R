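# Independent brute-force oracles used across the suite. These re-derive the
# quantities from first principles (enumeration, exhaustive search) and never
# call the implementation they check.

GENCODE <- as.character(Biostrings::GENETIC_CODE)
names(GENCODE) <- names(Biostrings::GENETIC_CODE)
SENSE <- names(GENCODE)[GENCODE != "*"]

# enumeration oracle for synonymous site fractions
oracle_syn_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  aa <- GENCODE[[codon]]
  hits <- 0
  for (pos in 1:3) for (nt in c("A", "C", "G", "T")) {
    if (nt == chars[pos]) next
    m <- chars
    m[pos] <- nt
    if (GENCODE[[paste(m, collapse = "")]] == aa) hits <- hits + 1
  }
  hits / 3
}

# exhaustive pathway enumerator for codon differences
oracle_differences <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0) return(c(0, 0))
  orders <- if (length(pos) == 1) list(pos) else {
    idx <- seq_along(pos)
    prm <- list()
    recurse <- function(prefix, rest) {
      if (length(rest) == 0) {
        prm[[length(prm) + 1]] <<- pos[prefix]
        return()
      }
      for (r in rest) recurse(c(prefix, r), setdiff(rest, r))
    }
    recurse(integer(0), idx)
    prm
  }
  counts <- matrix(NA_real_, length(orders), 2)
  blocked <- logical(length(orders))
  for (oi in seq_along(orders)) {
    cur <- a
    sc <- 0
    nc <- 0
    for (p in orders[[oi]]) {
      nxt <- cur
      nxt[p] <- b[p]
      aa1 <- GENCODE[[paste(cur, collapse = "")]]
      aa2 <- GENCODE[[paste(nxt, collapse = "")]]
      if (aa1 == "*" || aa2 == "*") blocked[oi] <- TRUE
      if (aa1 == aa2) sc <- sc + 1 else nc <- nc + 1
      cur <- nxt
    }
    counts[oi, ] <- c(sc, nc)
  }
  use <- if (all(blocked)) seq_along(orders) else which(!blocked)
  colMeans(counts[use, , drop = FALSE])
}

# exhaustive top-k reciprocal pairing over all ordered gene pairs
oracle_rbh <- function(fwd, rev, k, evalue_max) {
  topk <- function(hits, q) {
    h <- hits[hits$query_id == q & hits$e_value <= evalue_max &
                hits$query_id != hits$subject_id, , drop = FALSE]
    if (nrow(h) == 0) return(character(0))
    h <- h[order(-h$bit_score, h$e_value, h$subject_id), , drop = FALSE]
    utils::head(h$subject_id, k)
  }
  out <- list()
  for (a in unique(fwd$query_id)) {
    for (b in topk(fwd, a)) {
      if (a %in% topk(rev, b)) {
        out[[length(out) + 1]] <- data.frame(gene_a = a, gene_b = b,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$gene_a, res$gene_b), , drop = FALSE]
}

# exhaustive best chain over all anchor subsets (bitmask, n <= 12 anchors):
# a valid chain, sorted by rank_a, has both rank increments in (0, max_gap]
# (rank_b consistently ascending or descending)
oracle_best_chain_size <- function(rank_a, rank_b, max_gap) {
  n <- length(rank_a)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    m <- length(idx)
    if (m <= best) next
    ord <- idx[order(rank_a[idx])]
    valid_dir <- function(dir) {
      if (m == 1) return(TRUE)
      for (i in 2:m) {
        da <- rank_a[ord[i]] - rank_a[ord[i - 1]]
        db <- dir * (rank_b[ord[i]] - rank_b[ord[i - 1]])
        if (!(da > 0 && da <= max_gap && db > 0 && db <= max_gap)) return(FALSE)
      }
      TRUE
    }
    if (valid_dir(1) || valid_dir(-1)) best <- m
  }
  best
}

# random BLAST hit table over n genes per side
random_hits <- function(n_q, n_s, prefix_q, prefix_s, density = 0.5) {
  q <- sprintf("%s%02d", prefix_q, seq_len(n_q))
  s <- sprintf("%s%02d", prefix_s, seq_len(n_s))
  grid <- expand.grid(query_id = q, subject_id = s, stringsAsFactors = FALSE)
  grid <- grid[stats::runif(nrow(grid)) < density, , drop = FALSE]
  grid$percent_identity <- round(stats::runif(nrow(grid), 30, 100), 1)
  grid$alignment_length <- sample(100:500, nrow(grid), replace = TRUE)
  grid$e_value <- 10^(-stats::runif(nrow(grid), 5, 50))
  grid$bit_score <- round(stats::runif(nrow(grid), 50, 900), 1)
  grid
}
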