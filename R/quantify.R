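# Internal-standard HPLC quantification and summaries.
#
# Content of a desulfo-glucosinolate in micromol per gram fresh weight:
#
#   w = (k / m_sample) * (A / A_IS) * (c_IS * V_IS / M_IS) * 1000
#
# with k the compound's UV correction coefficient, m_sample the extracted
# fresh mass (g), A and A_IS the compound and sinigrin peak areas, and
# c_IS (mg/mL), V_IS (mL), M_IS (g/mol) the spiked internal standard.

#' Quantification constants for the sinigrin internal standard
#'
#' @param is_concentration internal-standard concentration, mg/mL (default 1.0).
#' @param is_volume spiked volume, mL (default 0.040).
#' @param is_molar_mass molar mass of sinigrin, g/mol (default 397.5).
#' @return a `quant_config` list.
#' @export
quant_config <- function(is_concentration = 1.0, is_volume = 0.040,
                         is_molar_mass = 397.5) {
  vals <- c(is_concentration, is_volume, is_molar_mass)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_validation("quant_config: all constants must be strictly positive")
  }
  structure(list(is_concentration = is_concentration, is_volume = is_volume,
                 is_molar_mass = is_molar_mass),
            class = "quant_config")
}

#' Content of one compound in one sample from its peak areas
#'
#' @param peak_area compound peak area (AU), >= 0.
#' @param is_area internal-standard peak area (AU), > 0.
#' @param sample_mass extracted fresh weight (g), > 0.
#' @param k correction coefficient from the registry.
#' @param cfg a [quant_config()].
#' @return content in micromol per g fresh weight.
#' @examples
#' content_from_peak(1e6, 1e6, sample_mass = 0.2, k = 1) # 0.50314
#' @export
content_from_peak <- function(peak_area, is_area, sample_mass, k,
                              cfg = quant_config()) {
  if (any(!is.finite(is_area)) || any(is_area <= 0)) {
    stop_validation("content_from_peak: internal-standard area must be > 0")
  }
  if (any(!is.finite(peak_area)) || any(peak_area < 0)) {
    stop_validation("content_from_peak: peak area must be >= 0")
  }
  if (any(!is.finite(sample_mass)) || any(sample_mass <= 0)) {
    stop_validation("content_from_peak: sample mass must be > 0")
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop_validation("content_from_peak: k must be > 0")
  }
  (k / sample_mass) * (peak_area / is_area) *
    (cfg$is_concentration * cfg$is_volume / cfg$is_molar_mass) * 1000
}

#' Quantify a peak table
#'
#' Applies [content_from_peak()] row-wise to a long-format peak table, taking
#' each compound's correction coefficient and class from the registry. The
#' internal standard itself is not quantified.
#'
#' @param peaks data frame with `sample_id`, `compound`, `peak_area`,
#'   `is_area`, `sample_mass_g` (or a path to such a TSV).
#' @param registry a `gsl_registry`.
#' @param cfg a [quant_config()].
#' @return data frame `sample_id`, `compound`, `gsl_class`, `content`
#'   (micromol/g fresh weight, full precision).
#' @export
quantify_peaks <- function(peaks, registry = load_registry(),
                           cfg = quant_config()) {
  if (is.character(peaks)) {
    peaks <- read_tsv_checked(peaks, required = c("sample_id", "compound",
                                                  "peak_area", "is_area",
                                                  "sample_mass_g"))
  }
  keep <- !peaks$compound %in% registry$name[registry$is_internal_standard]
  peaks <- peaks[keep, , drop = FALSE]
  data.frame(
    sample_id = peaks$sample_id,
    compound = peaks$compound,
    gsl_class = registry_class(registry, peaks$compound),
    content = content_from_peak(peaks$peak_area, peaks$is_area,
                                peaks$sample_mass_g,
                                registry_k(registry, peaks$compound), cfg),
    stringsAsFactors = FALSE
  )
}

#' Aggregate contents by glucosinolate class
#'
#' Per-sample sums of aliphatic, aromatic and indole contents plus their
#' total. Classes with no detected compound are 0 and flagged in the
#' corresponding `detected_*` column (reported as "N.D." by
#' [format_class_table()]). Totals are computed on full-precision member
#' contents, never on rounded values.
#'
#' @param contents data frame from [quantify_peaks()] (needs `sample_id`,
#'   `gsl_class`, `content`; `gsl_class` resolved via `registry` when absent).
#' @param registry a `gsl_registry`, used when `contents` lacks `gsl_class`.
#' @return data frame with one row per sample: `sample_id`, `aliphatic`,
#'   `aromatic`, `indole`, `total`, `detected_aliphatic`, `detected_aromatic`,
#'   `detected_indole`.
#' @export
aggregate_by_class <- function(contents, registry = load_registry()) {
  if (is.null(contents$gsl_class)) {
    contents$gsl_class <- registry_class(registry, contents$compound)
  }
  samples <- unique(contents$sample_id)
  rows <- lapply(samples, function(s) {
    sub <- contents[contents$sample_id == s, , drop = FALSE]
    by_class <- vapply(GSL_CLASSES, function(cl) {
      sum(sub$content[sub$gsl_class == cl])
    }, 0)
    detected <- vapply(GSL_CLASSES, function(cl) {
      any(sub$gsl_class == cl & sub$content > 0)
    }, TRUE)
    data.frame(sample_id = s,
               aliphatic = by_class[["aliphatic"]],
               aromatic = by_class[["aromatic"]],
               indole = by_class[["indole"]],
               total = sum(by_class),
               detected_aliphatic = detected[["aliphatic"]],
               detected_aromatic = detected[["aromatic"]],
               detected_indole = detected[["indole"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Class percentages of total glucosinolate content
#'
#' 100 x class / total, rounded half away from zero to one decimal. Samples
#' with zero total get `NA` percentages (nothing detected); classes not
#' detected get `NA` rather than 0.0, mirroring published "N.D." entries.
#'
#' @param class_table output of [aggregate_by_class()].
#' @return `class_table` with added `pct_aliphatic`, `pct_aromatic`,
#'   `pct_indole` columns.
#' @export
class_percentages <- function(class_table) {
  for (cl in GSL_CLASSES) {
    pct <- ifelse(class_table$total > 0,
                  round_half_away(100 * class_table[[cl]] / class_table$total, 1),
                  NA_real_)
    pct[!class_table[[paste0("detected_", cl)]]] <- NA_real_
    class_table[[paste0("pct_", cl)]] <- pct
  }
  class_table
}

#' Format a class table at published precision
#'
#' Contents to three decimals, percentages to one; undetected classes shown
#' as "N.D.". Purely presentational: all arithmetic upstream stays full
#' precision.
#'
#' @param class_table output of [class_percentages()].
#' @return data frame of character columns ready for printing.
#' @export
format_class_table <- function(class_table) {
  fmt <- function(x, detected, digits) {
    ifelse(detected, formatC(round_half_away(x, digits), digits = digits,
                             format = "f"), "N.D.")
  }
  data.frame(
    sample_id = class_table$sample_id,
    total = formatC(round_half_away(class_table$total, 3), digits = 3, format = "f"),
    aliphatic = fmt(class_table$aliphatic, class_table$detected_aliphatic, 3),
    pct_aliphatic = fmt(class_table$pct_aliphatic, class_table$detected_aliphatic, 1),
    aromatic = fmt(class_table$aromatic, class_table$detected_aromatic, 3),
    pct_aromatic = fmt(class_table$pct_aromatic, class_table$detected_aromatic, 1),
    indole = fmt(class_table$indole, class_table$detected_indole, 3),
    pct_indole = fmt(class_table$pct_indole, class_table$detected_indole, 1),
    stringsAsFactors = FALSE
  )
}

#' Elicitor fold changes against controls
#'
#' Treated over control content per timepoint, plus the peak fold and its
#' time. Timepoints with a zero or missing control are flagged undefined
#' rather than dropped.
#'
#' @param treated data frame `timepoint`, `content` for the treated series.
#' @param control data frame `timepoint`, `content` for the control series.
#' @return list with `folds` (data frame `timepoint`, `fold`, `defined`),
#'   `peak_fold` and `peak_time` (both `NA` if nothing is defined).
#' @export
fold_change <- function(treated, control) {
  idx <- match(treated$timepoint, control$timepoint)
  ctrl <- control$content[idx]
  defined <- !is.na(ctrl) & ctrl > 0
  fold <- ifelse(defined, treated$content / ctrl, NA_real_)
  folds <- data.frame(timepoint = treated$timepoint, fold = fold,
                      defined = defined)
  if (any(defined)) {
    peak <- which.max(ifelse(defined, fold, -Inf))
    list(folds = folds, peak_fold = fold[peak],
         peak_time = treated$timepoint[peak])
  } else {
    list(folds = folds, peak_fold = NA_real_, peak_time = NA)
  }
}
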