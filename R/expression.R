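# qRT-PCR relative expression by the 2^-ddCt method.
#
# dCt   = mean Ct(target) - reference value, per sample
# ddCt  = dCt(sample) - dCt(calibrator)
# rel   = 2^(-ddCt); the calibrator sample is exactly 1.
#
# The reference value is the mean Ct of the single reference gene or, when
# several reference genes are supplied, the arithmetic mean of their per-gene
# mean Cts. Replicates are averaged on the Ct scale before dCt (mean-Ct-first);
# the per-replicate spread is propagated into a fold-scale SD.

#' Relative expression by 2^-ddCt
#'
#' @param ct_data long-format data frame (or TSV path) with columns
#'   `sample_id`, `gene`, `ct`; one row per replicate well.
#' @param reference_genes character vector of reference gene name(s); every
#'   sample must carry Cts for all of them.
#' @param calibrator_sample sample id whose expression is set to 1.
#' @return data frame `sample_id`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `relative_expression`, `sd` (SD over per-replicate fold values, `NA`
#'   for single replicates), for every non-reference gene.
#' @examples
#' ct <- data.frame(
#'   sample_id = rep(c("cal", "s1"), each = 2),
#'   gene = rep(c("GSL-OH-1", "ref"), 2),
#'   ct = c(25, 20, 23, 20)
#' )
#' delta_delta_ct(ct, reference_genes = "ref", calibrator_sample = "cal")
#' @export
delta_delta_ct <- function(ct_data, reference_genes, calibrator_sample) {
  if (is.character(ct_data)) {
    ct_data <- read_tsv_checked(ct_data, required = c("sample_id", "gene", "ct"))
  }
  if (any(!is.finite(ct_data$ct))) {
    stop_validation("delta_delta_ct: all Ct values must be finite")
  }
  if (!calibrator_sample %in% ct_data$sample_id) {
    stop_validation(sprintf("delta_delta_ct: calibrator sample '%s' absent",
                            calibrator_sample))
  }
  samples <- unique(ct_data$sample_id)
  targets <- setdiff(unique(ct_data$gene), reference_genes)

  ref_value <- function(s) {
    per_gene <- vapply(reference_genes, function(g) {
      cts <- ct_data$ct[ct_data$sample_id == s & ct_data$gene == g]
      if (length(cts) == 0) {
        stop_validation(sprintf(
          "delta_delta_ct: sample '%s' lacks reference gene '%s'", s, g))
      }
      mean(cts)
    }, 0)
    mean(per_gene)
  }
  refs <- vapply(samples, ref_value, 0)
  names(refs) <- samples

  rows <- list()
  for (g in targets) {
    dct <- vapply(samples, function(s) {
      cts <- ct_data$ct[ct_data$sample_id == s & ct_data$gene == g]
      if (length(cts) == 0) return(NA_real_)
      mean(cts) - refs[[s]]
    }, 0)
    if (is.na(dct[[calibrator_sample]])) {
      stop_validation(sprintf(
        "delta_delta_ct: calibrator lacks target gene '%s'", g))
    }
    ddct <- dct - dct[[calibrator_sample]]
    rel <- 2^(-ddct)
    sdv <- vapply(samples, function(s) {
      cts <- ct_data$ct[ct_data$sample_id == s & ct_data$gene == g]
      if (length(cts) < 2) return(NA_real_)
      rep_rel <- 2^(-((cts - refs[[s]]) - dct[[calibrator_sample]]))
      stats::sd(rep_rel)
    }, 0)
    rows[[g]] <- data.frame(sample_id = samples, gene = g, delta_ct = dct,
                            delta_delta_ct = ddct, relative_expression = rel,
                            sd = sdv, stringsAsFactors = FALSE,
                            row.names = NULL)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (any(is.na(out$delta_ct))) {
    warning("delta_delta_ct: some samples lack a target gene; rows flagged NA")
  }
  out
}
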