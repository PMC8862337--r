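# Single entry point wiring the stages into reproducible runs. Each
# subcommand reads TSV inputs, runs the corresponding module and writes TSV
# outputs plus a resolved copy of the full configuration, so a run directory
# is self-describing. `simulate` emits a full synthetic study; `all` chains
# simulate with every analysis stage.

default_run_config <- function() {
  list(
    quant = list(c_is = 1.0, v_is = 0.040, m_is = 397.5, sample_mass = 0.2),
    screen = list(tol = 0.5, rt_tol = 0.5, mz_tol = 0.5),
    stats = list(alpha = 0.05, test = "anova"),
    expr = list(reference_genes = "ref", calibrator_sample = "calibrator"),
    orthologs = list(k = 2, evalue_max = 1e-20),
    kaks = list(lambda_rate = 1.5e-8, p_max = 0.05, mode = "sequence"),
    dupclass = list(min_anchors = 5, max_rank_gap = 25, tandem_max_gap = 1,
                    proximal_max_gap = 10),
    simulate = list(n_codons = 300, target_pn = 0.1, target_ps = 0.2,
                    n_pairs = 5, n_decoys = 6,
                    planted = list(tandem = 10, proximal = 6, segmental = 20,
                                   dispersed = 12, singleton = 12),
                    folds = list(s1 = 4, s2 = 0.5, s3 = 1))
  )
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  unknown <- setdiff(names(override), names(base))
  if (length(unknown) > 0) {
    stop_format(sprintf("config: unknown key(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

write_resolved_config <- function(cfg, out_dir, seed) {
  cfg$seed <- seed
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (write a synthetic study into `out_dir`),
#' `screen`, `quantify`, `stats`, `expr`, `orthologs`, `kaks` (set
#' `config$kaks$mode = "derive"` with an input of printed `Ka`/`Ks` columns to
#' recompute ratios and divergence times), `dupclass`, and `all` (simulate,
#' then every analysis stage on the simulated outputs). A resolved copy of
#' the configuration is written into `out_dir`.
#'
#' @param subcommand one of the names above.
#' @param inputs named list of input paths (stage-specific; see the methods
#'   vignette). `all` and `simulate` need none.
#' @param out_dir output directory (created if missing).
#' @param config nested list overriding [default_run_config()] entries;
#'   unknown keys are rejected.
#' @param seed integer seed for the stochastic stages.
#' @return (invisibly) a named list of the paths written.
#' @export
run_pipeline <- function(subcommand, inputs = list(), out_dir, config = list(),
                         seed = 1) {
  known <- c("simulate", "screen", "quantify", "stats", "expr", "orthologs",
             "kaks", "dupclass", "all")
  if (!subcommand %in% known) {
    stop_format(sprintf("unknown subcommand '%s' (expected one of %s)",
                        subcommand, paste(known, collapse = ", ")))
  }
  cfg <- merge_config(default_run_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- load_registry()
  qcfg <- quant_config(cfg$quant$c_is, cfg$quant$v_is, cfg$quant$m_is)
  written <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    written[[name]] <<- path
  }

  if (subcommand %in% c("simulate", "all")) {
    set.seed(seed)
    contents <- data.frame(
      sample_id = rep(c("rep1", "rep2", "rep3"), each = 3),
      compound = rep(c("Progoitrin", "Epiprogoitrin", "Indolyl-3-methyl"), 3),
      content = rep(c(2.0, 5.0, 1.2), 3) * rep(c(0.9, 1.0, 1.1), each = 3)
    )
    pk <- gen_peak_table(contents, sample_mass = cfg$quant$sample_mass,
                         registry = registry, cfg = qcfg, seed = seed)
    emit(pk$peaks, "sim_peaks.tsv")
    emit(pk$truth, "sim_peaks_truth.tsv")
    sp <- gen_spectra(registry, n_decoys = cfg$simulate$n_decoys, seed = seed)
    emit(sp$spectra, "sim_spectra.tsv")
    emit(sp$truth, "sim_spectra_truth.tsv")
    cp <- gen_codon_pairs(cfg$simulate$n_codons, cfg$simulate$target_pn,
                          cfg$simulate$target_ps, cfg$simulate$n_pairs,
                          seed = seed)
    emit(cp$pairs, "sim_codon_pairs.tsv")
    emit(cp$truth, "sim_codon_truth.tsv")
    fa <- file.path(out_dir, "sim_cds.fasta")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(cp$cds), fa)
    written[["sim_cds.fasta"]] <- fa
    gn <- gen_genome(unlist(cfg$simulate$planted), seed = seed)
    emit(gn$genes, "sim_genes.tsv")
    emit(gn$pairs, "sim_gene_pairs.tsv")
    emit(gn$truth, "sim_genome_truth.tsv")
    ct <- gen_ct_table(unlist(cfg$simulate$folds),
                       calibrator_sample = cfg$expr$calibrator_sample,
                       ref_gene = cfg$expr$reference_genes[1], seed = seed)
    emit(ct$ct, "sim_ct.tsv")
    emit(ct$truth, "sim_ct_truth.tsv")
  }

  if (subcommand %in% c("screen", "all")) {
    path <- if (subcommand == "all") written[["sim_spectra.tsv"]] else inputs$spectra
    res <- screen_spectra(read_spectra(path), registry,
                          tol = cfg$screen$tol, rt_tol = cfg$screen$rt_tol,
                          mz_tol = cfg$screen$mz_tol)
    emit(res, "screen_results.tsv")
  }

  if (subcommand %in% c("quantify", "all")) {
    path <- if (subcommand == "all") written[["sim_peaks.tsv"]] else inputs$peaks
    contents <- quantify_peaks(path, registry, qcfg)
    emit(contents, "contents.tsv")
    cls <- class_percentages(aggregate_by_class(contents, registry))
    emit(format_class_table(cls), "class_summary.tsv")
  }

  if (subcommand %in% c("stats", "all")) {
    if (subcommand == "all") {
      contents <- utils::read.delim(written[["contents.tsv"]])
      long <- data.frame(group = contents$compound, value = contents$content)
    } else {
      long <- read_tsv_checked(inputs$values, required = c("group", "value"))
    }
    cmp <- if (identical(cfg$stats$test, "kruskal")) {
      kruskal_wallis(long, alpha = cfg$stats$alpha)
    } else {
      one_way_anova(long, alpha = cfg$stats$alpha)
    }
    emit(data.frame(group = cmp$group_labels,
                    mean = cmp$group_means,
                    letters = cmp$letters[cmp$group_labels],
                    statistic = cmp$statistic, p_value = cmp$p_value),
         "group_comparison.tsv")
    emit(as.data.frame(cmp$pairwise_adjusted_p), "pairwise_adjusted_p.tsv")
  }

  if (subcommand %in% c("expr", "all")) {
    path <- if (subcommand == "all") written[["sim_ct.tsv"]] else inputs$ct
    res <- delta_delta_ct(path, cfg$expr$reference_genes,
                          cfg$expr$calibrator_sample)
    emit(res, "expression.tsv")
  }

  if (subcommand == "orthologs") {
    fwd <- parse_blast_tab(inputs$forward)
    rev <- parse_blast_tab(inputs$reverse)
    emit(reciprocal_best_pairs(fwd, rev, k = cfg$orthologs$k,
                               evalue_max = cfg$orthologs$evalue_max),
         "homolog_pairs.tsv")
  }

  if (subcommand %in% c("kaks", "all")) {
    if (identical(cfg$kaks$mode, "derive")) {
      tab <- read_tsv_checked(inputs$rates, required = c("Ka", "Ks"))
      emit(cbind(tab[setdiff(names(tab), c("Ka", "Ks"))],
                 kaks_derive(tab$Ka, tab$Ks, cfg$kaks$lambda_rate)),
           "kaks_derived.tsv")
    } else {
      if (subcommand == "all") {
        pr <- utils::read.delim(written[["sim_codon_pairs.tsv"]])
        fa <- Biostrings::readDNAStringSet(written[["sim_cds.fasta"]])
      } else {
        pr <- read_tsv_checked(inputs$pairs,
                               required = c("pair_id", "gene_a", "gene_b"))
        fa <- Biostrings::readDNAStringSet(inputs$cds)
      }
      res <- kaks_table(pr, fa, lambda_rate = cfg$kaks$lambda_rate)
      emit(res, "kaks_all.tsv")
      emit(filter_pairs(res, p_max = cfg$kaks$p_max), "kaks_significant.tsv")
    }
  }

  if (subcommand %in% c("dupclass", "all")) {
    if (subcommand == "all") {
      genes <- utils::read.delim(written[["sim_genes.tsv"]])
      pairs <- utils::read.delim(written[["sim_gene_pairs.tsv"]])
    } else {
      genes <- if (grepl("\\.gff3?$", inputs$genes)) {
        read_gene_models(inputs$genes)
      } else {
        read_tsv_checked(inputs$genes, required = c("gene_id", "chromosome",
                                                    "start", "end"))
      }
      pairs <- read_tsv_checked(inputs$pairs, required = c("gene_a", "gene_b"))
    }
    ranked <- assign_ranks(genes)
    blocks <- find_collinear_blocks(pairs, ranked,
                                    min_anchors = cfg$dupclass$min_anchors,
                                    max_rank_gap = cfg$dupclass$max_rank_gap,
                                    self_exclude_gap = cfg$dupclass$proximal_max_gap)
    calls <- classify_duplicates(ranked, pairs, blocks,
                                 tandem_max_gap = cfg$dupclass$tandem_max_gap,
                                 proximal_max_gap = cfg$dupclass$proximal_max_gap)
    emit(calls, "duplication_calls.tsv")
    emit(duplication_summary(calls), "duplication_summary.tsv")
  }

  write_resolved_config(cfg, out_dir, seed)
  invisible(written)
}
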