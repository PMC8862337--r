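# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes, plus machine-readable ground truth, so the whole
# pipeline is testable without instrument or genome data.
#
# Every generator is a pure function of its arguments: a fixed seed gives
# bit-identical output.

#' Generate a peak table from planted contents
#'
#' Inverts the internal-standard quantification formula: given true contents
#' (micromol/g fresh weight) it computes the peak areas that would produce
#' them, with the internal-standard area fixed at `is_area` so the inversion
#' stays transparent. Optional multiplicative lognormal noise with
#' coefficient of variation `noise_cv` (mean 1) models detector error.
#'
#' @param true_contents data frame `sample_id`, `compound`, `content`.
#' @param sample_mass fresh weight per extraction, g (default 0.2).
#' @param registry a `gsl_registry` supplying correction coefficients.
#' @param cfg a [quant_config()].
#' @param noise_cv lognormal CV of the multiplicative area noise (default 0).
#' @param is_area internal-standard peak area, AU (default 1e6).
#' @param seed RNG seed (used only when `noise_cv > 0`).
#' @return list with `peaks` (quantifiable peak table) and `truth`
#'   (the planted contents).
#' @export
gen_peak_table <- function(true_contents, sample_mass = 0.2,
                           registry = load_registry(), cfg = quant_config(),
                           noise_cv = 0, is_area = 1e6, seed = 1) {
  if (any(true_contents$content < 0)) {
    stop_validation("gen_peak_table: contents must be >= 0")
  }
  k <- registry_k(registry, true_contents$compound)
  unit <- cfg$is_concentration * cfg$is_volume / cfg$is_molar_mass * 1000
  area <- true_contents$content * is_area * sample_mass / (k * unit)
  if (noise_cv > 0) {
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    area <- area * stats::rlnorm(length(area), meanlog = -sdlog^2 / 2,
                                 sdlog = sdlog)
  }
  peaks <- data.frame(
    sample_id = true_contents$sample_id,
    compound = true_contents$compound,
    peak_area = area,
    is_area = is_area,
    sample_mass_g = sample_mass,
    stringsAsFactors = FALSE
  )
  list(peaks = peaks, truth = true_contents)
}

#' Generate diagnostic fragment spectra and decoys
#'
#' For every registry compound, a negative-mode spectrum carrying the m/z 75
#' sulfide-oxime fragment and the 162 Da neutral-loss fragment at the correct
#' precursor and retention time, plus a positive-mode spectrum with the
#' aglycone fragments (144/146/160). Decoys each violate exactly one named
#' rule: `no_oxime` (missing m/z 75), `no_neutral_loss` (no molecular-ion
#' evidence) or `odd_mass` (odd inferred molecular weight); their precursors
#' sit away from every registry compound.
#'
#' @param registry a `gsl_registry`.
#' @param n_decoys number of decoy spectra (cycled over the three types).
#' @param seed RNG seed for fragment intensities.
#' @return list with `spectra` (long-format data frame for
#'   [screen_spectra()]) and `truth` (`spectrum_id`, `kind`, `compound`,
#'   `violated_rule`).
#' @export
gen_spectra <- function(registry = load_registry(), n_decoys = 3, seed = 1) {
  set.seed(seed)
  rows <- list()
  truth <- list()
  add <- function(id, polarity, precursor, rt, frag_mz) {
    rows[[length(rows) + 1]] <<- data.frame(
      spectrum_id = id, polarity = polarity, precursor_mz = precursor,
      rt_min = rt, fragment_mz = frag_mz,
      intensity = round(stats::runif(length(frag_mz), 1e3, 1e5)),
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(registry))) {
    cmp <- registry[i, ]
    rt <- parse_rt(cmp$rt_min)[1]
    id_neg <- sprintf("true_neg_%02d", i)
    add(id_neg, "negative", cmp$desulfo_mz, rt,
        c(75, cmp$desulfo_mz - 162, cmp$desulfo_mz))
    truth[[length(truth) + 1]] <- data.frame(
      spectrum_id = id_neg, kind = "true", compound = cmp$name,
      violated_rule = "", stringsAsFactors = FALSE)
    id_pos <- sprintf("true_pos_%02d", i)
    add(id_pos, "positive", cmp$desulfo_mz + 2, rt, c(144, 146, 160))
    truth[[length(truth) + 1]] <- data.frame(
      spectrum_id = id_pos, kind = "true_positive_mode", compound = cmp$name,
      violated_rule = "", stringsAsFactors = FALSE)
  }
  decoy_types <- c("no_oxime", "no_neutral_loss", "odd_mass")
  for (d in seq_len(n_decoys)) {
    type <- decoy_types[(d - 1) %% 3 + 1]
    # even precursor well away from all registry desulfo masses
    precursor <- 600 + 2 * d
    if (type == "odd_mass") precursor <- precursor + 1
    frag <- switch(type,
      no_oxime = c(precursor - 162, precursor),
      no_neutral_loss = c(75, precursor - 100, precursor),
      odd_mass = c(75, precursor - 162, precursor)
    )
    id <- sprintf("decoy_%02d_%s", d, type)
    add(id, "negative", precursor, 30 + d, frag)
    truth[[length(truth) + 1]] <- data.frame(
      spectrum_id = id, kind = "decoy", compound = "",
      violated_rule = type, stringsAsFactors = FALSE)
  }
  list(spectra = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

# single-nucleotide neighbours of a codon, split by synonymous effect,
# never creating a stop
codon_moves <- function(codon) {
  aa <- codon_table[[codon]]
  chars <- strsplit(codon, "")[[1]]
  syn <- character(0)
  nonsyn <- character(0)
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, chars[pos])) {
      mutant <- chars
      mutant[pos] <- nt
      m <- paste(mutant, collapse = "")
      maa <- codon_table[[m]]
      if (maa == "*") next
      if (maa == aa) syn <- c(syn, m) else nonsyn <- c(nonsyn, m)
    }
  }
  list(syn = syn, nonsyn = nonsyn)
}

#' Generate codon-sequence pairs with controlled divergence
#'
#' Draws a random ancestor of sense codons, then derives a partner sequence
#' by applying synonymous and nonsynonymous single-nucleotide changes at
#' distinct codons (at most one change per codon, so the realized counts are
#' exact) until the realized `pS = Sd/S` and `pN = Nd/N` proportions, computed
#' with the NG86 counters, are as close to the targets as one further change
#' allows. The truth table records the realized proportions and their
#' Jukes-Cantor-corrected rates.
#'
#' @param n_codons codons per sequence.
#' @param target_pn,target_ps target proportions, in `[0, 0.75)`.
#' @param n_pairs number of independent pairs.
#' @param seed RNG seed.
#' @return list with `pairs` (`pair_id`, `gene_a`, `gene_b`), `cds` (named
#'   character vector of coding sequences) and `truth` (realized `pn`, `ps`,
#'   `ka`, `ks`, `ka_ks` per pair).
#' @export
gen_codon_pairs <- function(n_codons, target_pn, target_ps, n_pairs = 1,
                            seed = 1) {
  if (target_pn < 0 || target_pn >= 0.75 || target_ps < 0 || target_ps >= 0.75) {
    stop_validation("gen_codon_pairs: targets must lie in [0, 0.75)")
  }
  set.seed(seed)
  jc <- function(p) -(3 / 4) * log(1 - 4 * p / 3)
  cds <- character(0)
  pairs <- list()
  truth <- list()
  for (pr in seq_len(n_pairs)) {
    anc <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    der <- anc
    s_a <- vapply(anc, function(cd) ng86_sites(cd)[["S"]], 0)
    s_b <- s_a
    sd_tot <- 0
    nd_tot <- 0
    untouched <- sample(seq_len(n_codons)) # randomized visit order
    stat <- function() {
      S <- (sum(s_a) + sum(s_b)) / 2
      N <- 3 * n_codons - S
      c(S = S, N = N, ps = sd_tot / S, pn = nd_tot / N)
    }
    apply_change <- function(kind) {
      for (u in seq_along(untouched)) {
        i <- untouched[u]
        if (i == 0) next
        moves <- codon_moves(der[i])[[kind]]
        if (length(moves) == 0) next
        der[i] <<- moves[sample.int(length(moves), 1)]
        s_b[i] <<- ng86_sites(der[i])[["S"]]
        if (kind == "syn") sd_tot <<- sd_tot + 1 else nd_tot <<- nd_tot + 1
        untouched[u] <<- 0L
        return(TRUE)
      }
      FALSE
    }
    repeat {
      st <- stat()
      need_s <- (target_ps - st[["ps"]]) > 0.5 / st[["S"]]
      need_n <- (target_pn - st[["pn"]]) > 0.5 / st[["N"]]
      if (!need_s && !need_n) break
      progressed <- FALSE
      if (need_s) progressed <- apply_change("syn") || progressed
      if (need_n) progressed <- apply_change("nonsyn") || progressed
      if (!progressed) {
        stop_validation("gen_codon_pairs: target divergence unreachable at this length")
      }
    }
    st <- stat()
    ka <- jc(st[["pn"]])
    ks <- jc(st[["ps"]])
    id <- sprintf("pair_%03d", pr)
    ga <- paste0(id, "_a")
    gb <- paste0(id, "_b")
    cds[[ga]] <- paste(anc, collapse = "")
    cds[[gb]] <- paste(der, collapse = "")
    pairs[[pr]] <- data.frame(pair_id = id, gene_a = ga, gene_b = gb,
                              stringsAsFactors = FALSE)
    truth[[pr]] <- data.frame(pair_id = id, pn = st[["pn"]], ps = st[["ps"]],
                              ka = ka, ks = ks,
                              ka_ks = if (ks > 0) ka / ks else NA_real_,
                              stringsAsFactors = FALSE)
  }
  list(pairs = do.call(rbind, c(pairs, list(make.row.names = FALSE))),
       cds = cds,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate a gene catalogue with planted duplication categories
#'
#' Lays out non-overlapping genes on `n_chromosomes` chromosomes with planted
#' structures: tandem pairs at adjacent ranks, proximal pairs two ranks apart
#' (a singleton filler between), segmental blocks of `block_size` collinear
#' anchors spanning two distinct chromosomes, dispersed pairs on different
#' chromosomes (at most `min_anchors - 1` per chromosome pair so they can
#' never chain into a block), and pair-free singletons. Singletons double as
#' proximal fillers, so `planted["singleton"]` must be at least
#' `planted["proximal"] / 2`.
#'
#' @param planted named integer vector with gene counts per category:
#'   `tandem`, `proximal`, `segmental`, `dispersed`, `singleton`; even where
#'   pairs are implied, and `segmental` divisible by `2 * block_size`.
#' @param n_chromosomes number of chromosomes (default 7).
#' @param block_size anchors per segmental block (default 5).
#' @param min_anchors the block threshold the classifier will use; caps
#'   dispersed density per chromosome pair (default 5).
#' @param seed RNG seed.
#' @return list with `genes` (GFF3-style catalogue: `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`), `pairs` (planted homolog pairs) and `truth`
#'   (`gene_id`, `category`).
#' @export
gen_genome <- function(planted, n_chromosomes = 7, block_size = 5,
                       min_anchors = 5, seed = 1) {
  need <- c("tandem", "proximal", "segmental", "dispersed", "singleton")
  if (!all(need %in% names(planted))) {
    stop_validation(sprintf("gen_genome: planted must name %s",
                            paste(need, collapse = ", ")))
  }
  planted <- planted[need]
  if (any(planted < 0) || planted[["tandem"]] %% 2 != 0 ||
      planted[["proximal"]] %% 2 != 0 || planted[["dispersed"]] %% 2 != 0) {
    stop_validation("gen_genome: paired categories need even gene counts")
  }
  if (planted[["segmental"]] %% (2 * block_size) != 0) {
    stop_validation("gen_genome: segmental count must be a multiple of 2 * block_size")
  }
  n_disp_pairs <- planted[["dispersed"]] / 2
  n_prox_pairs <- planted[["proximal"]] / 2
  n_blocks <- planted[["segmental"]] / (2 * block_size)
  if (planted[["singleton"]] < n_prox_pairs) {
    stop_validation("gen_genome: need one singleton filler per proximal pair")
  }
  chrom_pairs <- utils::combn(n_chromosomes, 2)
  n_cp <- ncol(chrom_pairs)
  if (n_blocks + ceiling(n_disp_pairs / (min_anchors - 1)) > n_cp) {
    stop_validation("gen_genome: not enough chromosome pairs for blocks plus dispersed pairs")
  }
  set.seed(seed)

  mkids <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))
  tandem_ids <- mkids("TAN", planted[["tandem"]])
  prox_ids <- mkids("PRX", planted[["proximal"]])
  seg_ids <- mkids("SEG", planted[["segmental"]])
  disp_ids <- mkids("DSP", planted[["dispersed"]])
  single_ids <- mkids("SGL", planted[["singleton"]])

  seqs <- replicate(n_chromosomes, character(0), simplify = FALSE)
  app <- function(chr, ids) seqs[[chr]] <<- c(seqs[[chr]], ids)
  pairs <- list()
  pair <- function(a, b) {
    pairs[[length(pairs) + 1]] <<- data.frame(gene_a = a, gene_b = b,
                                              stringsAsFactors = FALSE)
  }

  # segmental blocks on dedicated chromosome pairs
  for (b in seq_len(n_blocks)) {
    cp <- chrom_pairs[, b]
    a_ids <- seg_ids[((b - 1) * 2 * block_size + 1):((b - 1) * 2 * block_size + block_size)]
    b_ids <- seg_ids[((b - 1) * 2 * block_size + block_size + 1):(b * 2 * block_size)]
    app(cp[1], a_ids)
    app(cp[2], b_ids)
    for (i in seq_len(block_size)) pair(a_ids[i], b_ids[i])
  }
  # tandem pairs, round robin
  if (planted[["tandem"]] > 0) {
    for (p in seq_len(planted[["tandem"]] / 2)) {
      chr <- (p - 1) %% n_chromosomes + 1
      a <- tandem_ids[2 * p - 1]
      b <- tandem_ids[2 * p]
      app(chr, c(a, b))
      pair(a, b)
    }
  }
  # proximal pairs with a singleton filler between (rank distance 2)
  filler_used <- 0
  if (n_prox_pairs > 0) {
    for (p in seq_len(n_prox_pairs)) {
      chr <- (p - 1) %% n_chromosomes + 1
      a <- prox_ids[2 * p - 1]
      b <- prox_ids[2 * p]
      filler_used <- filler_used + 1
      app(chr, c(a, single_ids[filler_used], b))
      pair(a, b)
    }
  }
  # dispersed pairs: distinct chromosomes, capped per chromosome pair
  if (n_disp_pairs > 0) {
    avail_cp <- setdiff(seq_len(n_cp), seq_len(n_blocks))
    for (p in seq_len(n_disp_pairs)) {
      cp <- chrom_pairs[, avail_cp[(p - 1) %% length(avail_cp) + 1]]
      a <- disp_ids[2 * p - 1]
      b <- disp_ids[2 * p]
      app(cp[1], a)
      app(cp[2], b)
      pair(a, b)
    }
  }
  # remaining singletons
  if (filler_used < planted[["singleton"]]) {
    rest <- single_ids[(filler_used + 1):planted[["singleton"]]]
    for (i in seq_along(rest)) {
      app((i - 1) %% n_chromosomes + 1, rest[i])
    }
  }

  genes <- do.call(rbind, lapply(seq_len(n_chromosomes), function(chr) {
    ids <- seqs[[chr]]
    if (length(ids) == 0) return(NULL)
    pos <- seq_along(ids)
    data.frame(gene_id = ids,
               chromosome = sprintf("Chr%02d", chr),
               start = (pos - 1) * 2000 + 1,
               end = (pos - 1) * 2000 + 1000,
               strand = "+",
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  truth <- data.frame(
    gene_id = c(tandem_ids, prox_ids, seg_ids, disp_ids, single_ids),
    category = rep(c("tandem", "proximal", "wgd_segmental", "dispersed",
                     "singleton"),
                   times = planted[need][c("tandem", "proximal", "segmental",
                                           "dispersed", "singleton")]),
    stringsAsFactors = FALSE
  )
  pair_df <- if (length(pairs) == 0) {
    data.frame(gene_a = character(0), gene_b = character(0))
  } else {
    do.call(rbind, c(pairs, list(make.row.names = FALSE)))
  }
  list(genes = genes, pairs = pair_df, truth = truth)
}

#' Generate a Ct table with planted fold changes
#'
#' The calibrator sample gets target Ct `calibrator_target_ct`; a sample with
#' planted fold `f` gets target Ct `calibrator_target_ct - log2(f)`, with the
#' reference gene constant at `ref_ct`, so the noiseless table round-trips
#' exactly through [delta_delta_ct()]. Gaussian noise of SD `noise_sd` is
#' added per replicate well.
#'
#' @param true_folds named numeric vector: sample id -> fold change (> 0).
#'   The calibrator is added automatically with fold 1.
#' @param calibrator_sample id of the calibrator (default "calibrator").
#' @param target_gene,ref_gene gene names in the emitted table.
#' @param ref_ct reference-gene Ct (default 20).
#' @param calibrator_target_ct calibrator target Ct (default 25).
#' @param noise_sd Gaussian Ct noise SD (default 0).
#' @param n_reps replicate wells (default 3).
#' @param seed RNG seed.
#' @return list with `ct` (long-format Ct table) and `truth` (`sample_id`,
#'   `fold`).
#' @export
gen_ct_table <- function(true_folds, calibrator_sample = "calibrator",
                         target_gene = "target", ref_gene = "ref",
                         ref_ct = 20, calibrator_target_ct = 25,
                         noise_sd = 0, n_reps = 3, seed = 1) {
  if (any(true_folds <= 0)) stop_validation("gen_ct_table: folds must be > 0")
  set.seed(seed)
  folds <- c(stats::setNames(1, calibrator_sample), true_folds)
  rows <- list()
  for (s in names(folds)) {
    t_ct <- calibrator_target_ct - log2(folds[[s]])
    for (r in seq_len(n_reps)) {
      noise <- if (noise_sd > 0) stats::rnorm(2, 0, noise_sd) else c(0, 0)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s,
        gene = c(target_gene, ref_gene),
        ct = c(t_ct + noise[1], ref_ct + noise[2]),
        replicate = r,
        stringsAsFactors = FALSE
      )
    }
  }
  list(ct = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = data.frame(sample_id = names(folds), fold = unname(folds),
                          stringsAsFactors = FALSE))
}
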