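# Reciprocal-best-hit homolog pairing from tabular BLAST output, generalised
# to top-k candidate sets (the screen used "the best two hits" per species).

BLAST6_COLS <- c("query_id", "subject_id", "percent_identity",
                 "alignment_length", "mismatches", "gap_opens", "q_start",
                 "q_end", "s_start", "s_end", "e_value", "bit_score")

#' Parse BLAST tabular output (outfmt 6)
#'
#' Reads the standard 12-column tab-separated BLAST format. Self hits
#' (query == subject) are removed; when a query-subject pair has several HSPs
#' only the best-scoring one (highest bit score, then lowest e-value) is kept.
#'
#' @param path path to a BLAST `-outfmt 6` file, or a data frame already in
#'   that shape.
#' @return data frame of typed hits with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `e_value`, `bit_score`.
#' @export
parse_blast_tab <- function(path) {
  if (is.data.frame(path)) {
    df <- path
  } else {
    if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0) {
      df <- as.data.frame(stats::setNames(
        replicate(12, character(0), simplify = FALSE), BLAST6_COLS))
    } else {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(lengths(fields) != 12)
      if (length(bad) > 0) {
        stop_format(sprintf("%s: line %d has %d columns (12 expected)",
                            path, bad[1], lengths(fields)[bad[1]]))
      }
      df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
      names(df) <- BLAST6_COLS
    }
  }
  num_cols <- c("percent_identity", "alignment_length", "e_value", "bit_score")
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  if (any(!is.finite(df$e_value) | df$e_value < 0) ||
      any(!is.finite(df$bit_score) | df$bit_score <= 0)) {
    stop_format("blast hits: e_value must be >= 0 and bit_score > 0")
  }
  df <- df[df$query_id != df$subject_id,
           c("query_id", "subject_id", "percent_identity",
             "alignment_length", "e_value", "bit_score"), drop = FALSE]
  # best HSP per query-subject pair
  ord <- order(df$query_id, df$subject_id, -df$bit_score, df$e_value)
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df[c("query_id", "subject_id")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Per-query top-k hit candidates
#'
#' Hits passing the e-value threshold are ranked per query by bit score
#' (descending), ties by e-value (ascending) then subject id
#' (lexicographic); the top `k` are kept.
#'
#' @param hits data frame from [parse_blast_tab()].
#' @param k candidates kept per query (default 2).
#' @param evalue_max e-value threshold (default 1e-20, the protein screen;
#'   use 1e-5 for nucleotide-library searches).
#' @return data frame `query_id`, `subject_id`, `e_value`, `bit_score`,
#'   `rank` (1 = best).
#' @export
best_hits <- function(hits, k = 2, evalue_max = 1e-20) {
  if (k < 1) stop_validation("best_hits: k must be >= 1")
  hits <- hits[hits$e_value <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      e_value = numeric(0), bit_score = numeric(0),
                      rank = integer(0)))
  }
  ord <- order(hits$query_id, -hits$bit_score, hits$e_value, hits$subject_id)
  hits <- hits[ord, , drop = FALSE]
  rnk <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                    FUN = seq_along)
  hits$rank <- as.integer(rnk)
  out <- hits[hits$rank <= k,
              c("query_id", "subject_id", "e_value", "bit_score", "rank"),
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal best-hit homolog pairs
#'
#' `(a, b)` is a pair iff `b` is among `a`'s top-`k` forward candidates and
#' `a` is among `b`'s top-`k` reverse candidates. With `k = 1` this is
#' classical reciprocal-best-hit pairing; `k = 2` reproduces the "best two
#' hits" candidate expansion. Output is sorted by `gene_a` then `gene_b`.
#'
#' @param forward_hits,reverse_hits data frames from [parse_blast_tab()], the
#'   two search directions.
#' @param k candidate depth applied to both directions.
#' @param evalue_max e-value threshold applied to both directions.
#' @return data frame `gene_a`, `gene_b`, `forward_evalue`, `reverse_evalue`.
#' @export
reciprocal_best_pairs <- function(forward_hits, reverse_hits, k = 2,
                                  evalue_max = 1e-20) {
  fwd <- best_hits(forward_hits, k = k, evalue_max = evalue_max)
  rev <- best_hits(reverse_hits, k = k, evalue_max = evalue_max)
  if (nrow(fwd) == 0 || nrow(rev) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      forward_evalue = numeric(0), reverse_evalue = numeric(0)))
  }
  rev_key <- paste(rev$query_id, rev$subject_id, sep = "\r")
  keep <- paste(fwd$subject_id, fwd$query_id, sep = "\r") %in% rev_key
  pairs <- fwd[keep, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      forward_evalue = numeric(0), reverse_evalue = numeric(0)))
  }
  rev_e <- rev$e_value[match(paste(pairs$subject_id, pairs$query_id,
                                   sep = "\r"), rev_key)]
  out <- data.frame(gene_a = pairs$query_id, gene_b = pairs$subject_id,
                    forward_evalue = pairs$e_value, reverse_evalue = rev_e,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
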