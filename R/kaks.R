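# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, protein-guided
# codon alignment, Fisher significance, p-value filtering and divergence-time
# dating (T = Ks / 2 lambda).

NUCS <- c("A", "C", "G", "T")

# codon -> amino acid under the standard genetic code; "*" marks stops
codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  tab <- as.character(gc)
  names(tab) <- names(gc)
  tab
})

STOP_CODONS <- names(codon_table)[codon_table == "*"]
SENSE_CODONS <- names(codon_table)[codon_table != "*"]

translate_codon <- function(codon) {
  aa <- codon_table[codon]
  if (anyNA(aa)) stop_validation(sprintf("invalid codon: %s", codon[is.na(aa)][1]))
  unname(aa)
}

check_sense <- function(codon, what) {
  aa <- codon_table[codon]
  if (anyNA(aa)) stop_validation(sprintf("%s: invalid codon '%s'", what, codon))
  if (any(aa == "*")) stop_validation(sprintf("%s: stop codon '%s'", what, codon))
  invisible(codon)
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each codon position, the fraction of the three possible single
#' nucleotide changes that leave the amino acid unchanged is its synonymous
#' site contribution; mutations creating stop codons count as nonsynonymous.
#' `S + N = 3` for every sense codon.
#'
#' @param codon a 3-letter sense codon (A/C/G/T).
#' @return named numeric vector `c(S = ..., N = ...)`.
#' @examples
#' ng86_sites("TTA") # Leu: S = 2/3
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  check_sense(codon, "ng86_sites")
  c(S = SYN_SITES[[codon]], N = 3 - SYN_SITES[[codon]])
}

ng86_sites_compute <- function(codon) {
  aa <- codon_table[[codon]]
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, chars[pos])) {
      mutant <- chars
      mutant[pos] <- nt
      if (codon_table[[paste(mutant, collapse = "")]] == aa) {
        syn <- syn + 1 / 3
      }
    }
  }
  syn
}

# synonymous site counts for all sense codons, computed once at load
SYN_SITES <- local({
  v <- vapply(SENSE_CODONS, ng86_sites_compute, 0)
  names(v) <- SENSE_CODONS
  v
})

# pathway-difference cache, filled lazily (at most 61 x 61 entries)
.ng86_diff_cache <- new.env(parent = emptyenv())

#' Synonymous and nonsynonymous differences between two codons (NG86)
#'
#' Zero differences give `(0, 0)`; a single difference is classified
#' directly; for two or three differences the synonymous / nonsynonymous
#' split is averaged over all orderings of the mutation pathway (2 or 6),
#' skipping pathways that pass through a stop codon. If every pathway is
#' blocked, the average is over all pathways.
#'
#' @param codon_a,codon_b 3-letter sense codons.
#' @return named numeric vector `c(Sd = ..., Nd = ...)`.
#' @examples
#' ng86_differences("TTT", "GTA") # two pathways -> (0.5, 1.5)
#' @export
ng86_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  check_sense(codon_a, "ng86_differences")
  check_sense(codon_b, "ng86_differences")
  key <- paste0(codon_a, codon_b)
  cached <- .ng86_diff_cache[[key]]
  if (!is.null(cached)) return(cached)
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(a != b)
  nd <- length(diff_pos)
  if (nd == 0) return(c(Sd = 0, Nd = 0))

  paths <- perms(diff_pos)
  path_counts <- matrix(NA_real_, nrow = nrow(paths), ncol = 2)
  blocked <- logical(nrow(paths))
  for (pi in seq_len(nrow(paths))) {
    cur <- a
    sd_i <- 0
    nd_i <- 0
    for (pos in paths[pi, ]) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_cur <- codon_table[[paste(cur, collapse = "")]]
      aa_nxt <- codon_table[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" || aa_cur == "*") blocked[pi] <- TRUE
      if (aa_cur == aa_nxt) sd_i <- sd_i + 1 else nd_i <- nd_i + 1
      cur <- nxt
    }
    path_counts[pi, ] <- c(sd_i, nd_i)
  }
  use <- if (all(blocked)) rep(TRUE, nrow(paths)) else !blocked
  out <- c(Sd = mean(path_counts[use, 1]), Nd = mean(path_counts[use, 2]))
  .ng86_diff_cache[[key]] <- out
  out
}

# all orderings of a position vector (length 1-3)
perms <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  if (n == 2) return(rbind(v, rev(v)))
  out <- matrix(0L, 6, 3)
  r <- 1
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    out[r, ] <- c(v[i], v[j], v[setdiff(1:3, c(i, j))])
    r <- r + 1
  }
  out
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) {
    stop_validation("sequence length not divisible by 3")
  }
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Protein-guided codon alignment of two coding sequences
#'
#' Translates both CDSs (standard code), checks them against the supplied
#' proteins when given, aligns the proteins globally (BLOSUM62, affine gaps)
#' and maps the alignment back onto codons. Codon columns opposite a gap are
#' dropped; terminal stop codons are stripped before alignment; an internal
#' stop is an error naming the offending sequence.
#'
#' @param cds_a,cds_b coding sequences (character strings of A/C/G/T).
#' @param protein_a,protein_b optional amino-acid sequences that must match
#'   the translations.
#' @param pair_id identifier carried into the result.
#' @return a `codon_alignment`: list with `pair_id`, `codons_a`, `codons_b`
#'   (equal-length codon vectors, gap-free) and `n_codons`.
#' @export
backtranslate_align <- function(cds_a, cds_b, protein_a = NULL,
                                protein_b = NULL, pair_id = "pair") {
  prep <- function(cds, protein, label) {
    codons <- split_codons(cds)
    aa <- vapply(codons, function(cd) {
      v <- codon_table[cd]
      if (is.na(v)) stop_validation(sprintf("%s: invalid codon '%s'", label, cd))
      v
    }, "")
    if (length(aa) > 0 && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (any(aa == "*")) {
      stop_validation(sprintf("%s: internal stop codon", label))
    }
    if (!is.null(protein)) {
      protein <- toupper(gsub("\\*$", "", protein))
      if (!identical(paste(aa, collapse = ""), protein)) {
        stop_validation(sprintf("%s: CDS translation does not match protein",
                                label))
      }
    }
    list(codons = codons, aa = paste(aa, collapse = ""))
  }
  a <- prep(cds_a, protein_a, "cds_a")
  b <- prep(cds_b, protein_b, "cds_b")

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$aa), Biostrings::AAString(b$aa),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0
  ib <- 0
  keep_a <- integer(0)
  keep_b <- integer(0)
  for (col in seq_along(pa)) {
    if (pa[col] != "-") ia <- ia + 1
    if (pb[col] != "-") ib <- ib + 1
    if (pa[col] != "-" && pb[col] != "-") {
      keep_a <- c(keep_a, ia)
      keep_b <- c(keep_b, ib)
    }
  }
  structure(list(pair_id = pair_id,
                 codons_a = unname(a$codons[keep_a]),
                 codons_b = unname(b$codons[keep_b]),
                 n_codons = length(keep_a)),
            class = "codon_alignment")
}

#' NG86 Ka/Ks for one codon alignment
#'
#' Site counts are averaged over the two sequences; proportions
#' `pN = Nd/N`, `pS = Sd/S` get the Jukes-Cantor multiple-hit correction
#' `d = -(3/4) log(1 - 4p/3)` (undefined at saturation, `p >= 3/4`).
#' Significance is Fisher's exact test on the 2x2 table of rounded
#' substitution counts against remaining sites. `Ka/Ks` is `NA` when
#' `Ks = 0` (never infinity).
#'
#' @param alignment a `codon_alignment` from [backtranslate_align()] (or any
#'   list with `pair_id`, `codons_a`, `codons_b`).
#' @return one-row data frame: `pair_id`, `Ka`, `Ks`, `ka_ks`, `p_value`,
#'   `S_sites`, `N_sites`, `Sd`, `Nd`, `saturated`.
#' @export
kaks_pair <- function(alignment) {
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  if (length(ca) != length(cb) || length(ca) < 1) {
    stop_validation("kaks_pair: alignment must have >= 1 codon, equal lengths")
  }
  s_sites <- 0
  for (cd in ca) s_sites <- s_sites + ng86_sites(cd)[["S"]]
  s_b <- 0
  for (cd in cb) s_b <- s_b + ng86_sites(cd)[["S"]]
  S <- (s_sites + s_b) / 2
  N <- 3 * length(ca) - S
  sd_tot <- 0
  nd_tot <- 0
  for (i in seq_along(ca)) {
    d <- ng86_differences(ca[i], cb[i])
    sd_tot <- sd_tot + d[["Sd"]]
    nd_tot <- nd_tot + d[["Nd"]]
  }
  ps <- if (S > 0) sd_tot / S else 0
  pn <- if (N > 0) nd_tot / N else 0
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -(3 / 4) * log(1 - 4 * p / 3)
  }
  ka <- jc(pn)
  ks <- jc(ps)
  saturated <- is.na(ka) || is.na(ks)
  ratio <- if (!saturated && ks > 0) ka / ks else NA_real_

  rsd <- round(sd_tot)
  rnd <- round(nd_tot)
  tab <- matrix(c(rsd, max(0, round(S) - rsd),
                  rnd, max(0, round(N) - rnd)), nrow = 2)
  p_value <- if (rsd + rnd == 0) 1 else stats::fisher.test(tab)$p.value

  data.frame(pair_id = alignment$pair_id, Ka = ka, Ks = ks, ka_ks = ratio,
             p_value = p_value, S_sites = S, N_sites = N, Sd = sd_tot,
             Nd = nd_tot, saturated = saturated, stringsAsFactors = FALSE)
}

#' Filter Ka/Ks results on significance
#'
#' Keeps pairs with `p_value <= p_max`; the number removed is reported via
#' `message()`.
#'
#' @param results data frame with a `p_value` column.
#' @param p_max significance threshold (default 0.05).
#' @return the retained rows.
#' @export
filter_pairs <- function(results, p_max = 0.05) {
  keep <- results$p_value <= p_max
  removed <- sum(!keep)
  message(sprintf("filter_pairs: removed %d of %d pairs (p > %g)",
                  removed, nrow(results), p_max))
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Divergence time from synonymous divergence
#'
#' `T = Ks / (2 lambda)`, reported in million years to 2 decimals. The default
#' clock `lambda = 1.5e-8` substitutions/site/year is the Brassicaceae rate.
#'
#' @param ks synonymous substitutions per synonymous site, >= 0.
#' @param lambda_rate substitution rate per site per year, > 0.
#' @param digits decimals in the returned Myr value (default 2; `NA` for
#'   full precision).
#' @return divergence time in million years.
#' @examples
#' divergence_time(0.10331) # 3.44 Myr
#' @export
divergence_time <- function(ks, lambda_rate = 1.5e-8, digits = 2) {
  if (any(!is.finite(ks)) || any(ks < 0)) {
    stop_validation("divergence_time: ks must be >= 0")
  }
  if (!is.finite(lambda_rate) || lambda_rate <= 0) {
    stop_validation("divergence_time: lambda_rate must be > 0")
  }
  t_myr <- ks / (2 * lambda_rate) / 1e6
  if (is.na(digits)) t_myr else round_half_away(t_myr, digits)
}

#' Ka/Ks table for a set of CDS pairs
#'
#' Runs [backtranslate_align()] and [kaks_pair()] over a pair list and adds
#' divergence times.
#'
#' @param pairs data frame `pair_id`, `gene_a`, `gene_b`.
#' @param cds named character vector (or `Biostrings::DNAStringSet`) of coding
#'   sequences.
#' @param lambda_rate clock rate for [divergence_time()].
#' @return data frame, one row per pair, Table-style columns plus `t_myr`.
#' @export
kaks_table <- function(pairs, cds, lambda_rate = 1.5e-8) {
  if (methods::is(cds, "DNAStringSet")) {
    cds <- stats::setNames(as.character(cds), names(cds))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    aln <- backtranslate_align(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]],
                               pair_id = pairs$pair_id[i])
    kaks_pair(aln)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$t_myr <- ifelse(is.na(out$Ks), NA_real_,
                      divergence_time(pmax(out$Ks, 0), lambda_rate))
  out
}

#' Derive Ka/Ks ratio and divergence time from printed rates
#'
#' Companion "derive" mode for published tables: given Ka and Ks values,
#' recomputes the ratio (5 decimals) and `T = Ks / 2 lambda` (2 decimals).
#'
#' @param ka,ks numeric vectors of substitution rates.
#' @param lambda_rate clock rate (default 1.5e-8 subs/site/year).
#' @return data frame `Ka`, `Ks`, `ka_ks`, `t_myr`.
#' @examples
#' kaks_derive(0.05525, 0.10331) # ratio 0.53480, 3.44 Myr
#' @export
kaks_derive <- function(ka, ks, lambda_rate = 1.5e-8) {
  data.frame(
    Ka = ka, Ks = ks,
    ka_ks = ifelse(ks > 0, round_half_away(ka / ks, 5), NA_real_),
    t_myr = divergence_time(ks, lambda_rate)
  )
}
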