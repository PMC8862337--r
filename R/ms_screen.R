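# Rule-based LC-MS/MS screening for glucosinolate candidates.
#
# Desulfo-glucosinolates show four diagnostic features on a unit-resolution
# triple quadrupole:
#   R1  sulfide-oxime fragment at m/z 75 (negative mode; mandatory)
#   R2  neutral loss of the thioglucose moiety: 162 Da, or 198 Da when the
#       loss carries a chloride adduct
#   R3  desulfurised glycoside aglycone fragments at m/z 144/146/160
#       (positive mode; two of the three required)
#   R4  even nominal molecular mass (nitrogen rule)
# Candidacy needs R1 plus molecular-ion evidence (R2, or an explicit
# precursor annotation from the instrument software).

DIAGNOSTIC_OXIME_MZ <- 75
NEUTRAL_LOSSES <- c(162, 198)
AGLYCONE_MZ <- c(144, 146, 160)

#' Read a long-format fragment-spectrum table
#'
#' Expects a TSV with columns `spectrum_id`, `polarity` (`negative` or
#' `positive`), `precursor_mz`, `rt_min`, `fragment_mz`, `intensity`, one row
#' per fragment. An optional logical column `precursor_annotated` marks
#' spectra whose precursor was flagged as a desulfo molecular ion by the
#' acquisition software.
#'
#' @param path TSV path.
#' @return list of spectra, each a list with fields `spectrum_id`, `polarity`,
#'   `precursor_mz`, `rt_min`, `fragments` (data frame, sorted by m/z) and
#'   `precursor_annotated`.
#' @export
read_spectra <- function(path) {
  df <- read_tsv_checked(path, required = c("spectrum_id", "polarity",
                                            "precursor_mz", "rt_min",
                                            "fragment_mz", "intensity"))
  spectra_from_table(df)
}

#' Build spectrum objects from a long-format data frame
#'
#' @param df data frame with the columns documented in [read_spectra()].
#' @return list of spectrum objects, ordered by `spectrum_id`.
#' @export
spectra_from_table <- function(df) {
  if (nrow(df) == 0) return(list())
  if (!all(df$polarity %in% c("negative", "positive"))) {
    stop_validation("spectra: polarity must be 'negative' or 'positive'")
  }
  if (any(df$fragment_mz <= 0, na.rm = TRUE)) {
    stop_validation("spectra: fragment m/z must be positive")
  }
  if (is.null(df$precursor_annotated)) df$precursor_annotated <- FALSE
  ids <- sort(unique(df$spectrum_id))
  lapply(ids, function(id) {
    rows <- df[df$spectrum_id == id, , drop = FALSE]
    rows <- rows[order(rows$fragment_mz), , drop = FALSE]
    frag <- rows[stats::complete.cases(rows[c("fragment_mz", "intensity")]),
                 c("fragment_mz", "intensity"), drop = FALSE]
    if (any(frag$intensity < 0)) {
      stop_validation(sprintf("spectrum %s: negative intensity", id))
    }
    list(
      spectrum_id = id,
      polarity = rows$polarity[1],
      precursor_mz = rows$precursor_mz[1],
      rt_min = rows$rt_min[1],
      fragments = frag,
      precursor_annotated = isTRUE(any(rows$precursor_annotated))
    )
  })
}

has_fragment <- function(fragments, mz, tol) {
  any(abs(fragments$fragment_mz - mz) <= tol)
}

# Nominal molecular weight inferred from the precursor on the printed desulfo
# m/z scale: the desulfo ion sits 80 Da below the intact glucosinolate.
infer_mw <- function(precursor_mz) round(precursor_mz) + 80

#' Evaluate the glucosinolate diagnostic rules on one spectrum
#'
#' @param spectrum a spectrum object (see [read_spectra()]).
#' @param tol fragment m/z tolerance in Da (default 0.5, unit resolution).
#' @return one-row data frame: `spectrum_id`, the four rule flags
#'   `R1_sulfide_oxime`, `R2_neutral_loss`, `R3_aglycone`, `R4_even_mass`,
#'   `is_candidate`, `matched_compound` (empty until [match_library()]) and
#'   `inferred_molecular_weight`.
#' @export
evaluate_rules <- function(spectrum, tol = 0.5) {
  if (!is.finite(tol) || tol <= 0) stop_validation("evaluate_rules: tol must be > 0")
  frag <- spectrum$fragments
  neg <- identical(spectrum$polarity, "negative")
  pos <- identical(spectrum$polarity, "positive")
  empty <- is.null(frag) || nrow(frag) == 0

  r1 <- !empty && neg && has_fragment(frag, DIAGNOSTIC_OXIME_MZ, tol)
  r2 <- !empty && any(vapply(
    NEUTRAL_LOSSES,
    function(loss) has_fragment(frag, spectrum$precursor_mz - loss, tol),
    TRUE
  ))
  r3 <- !empty && pos &&
    sum(vapply(AGLYCONE_MZ, function(mz) has_fragment(frag, mz, tol), TRUE)) >= 2
  mw <- infer_mw(spectrum$precursor_mz)
  r4 <- mw > 0 && mw %% 2 == 0
  candidate <- r1 && (r2 || isTRUE(spectrum$precursor_annotated))

  data.frame(
    spectrum_id = spectrum$spectrum_id,
    R1_sulfide_oxime = r1,
    R2_neutral_loss = r2,
    R3_aglycone = r3,
    R4_even_mass = r4,
    is_candidate = candidate,
    matched_compound = "",
    inferred_molecular_weight = mw,
    stringsAsFactors = FALSE
  )
}

#' Assign a candidate spectrum to a registry compound
#'
#' A candidate is assigned to the unique registry compound whose desulfo m/z
#' matches the precursor within `mz_tol` and whose retention time (any of its
#' listed times, for epimer pairs) matches within `rt_tol`. When several
#' compounds match, the nearest retention time wins. Non-candidates and
#' candidates outside every window stay unassigned (putative glucosinolates).
#'
#' @param result one-row data frame from [evaluate_rules()].
#' @param spectrum the corresponding spectrum object.
#' @param registry a `gsl_registry` from [load_registry()].
#' @param rt_tol retention-time tolerance in minutes (default 0.5).
#' @param mz_tol precursor m/z tolerance in Da (default 0.5).
#' @return `result` with `matched_compound` filled in where a match exists.
#' @export
match_library <- function(result, spectrum, registry, rt_tol = 0.5,
                          mz_tol = 0.5) {
  if (rt_tol <= 0 || mz_tol <= 0) {
    stop_validation("match_library: tolerances must be > 0")
  }
  if (!isTRUE(result$is_candidate)) return(result)
  rt_dist <- vapply(registry$rt_min, function(rt) {
    min(abs(parse_rt(rt) - spectrum$rt_min))
  }, 0)
  mz_ok <- abs(registry$desulfo_mz - spectrum$precursor_mz) <= mz_tol
  hit <- which(mz_ok & rt_dist <= rt_tol)
  if (length(hit) >= 1) {
    best <- hit[order(rt_dist[hit], registry$name[hit])][1]
    result$matched_compound <- registry$name[best]
  }
  result
}

#' Screen a set of spectra against the registry
#'
#' Convenience wrapper: runs [evaluate_rules()] and [match_library()] over a
#' spectrum list or long-format table. Output order follows `spectrum_id`, so
#' identical inputs give identical results regardless of row order.
#'
#' @param spectra list of spectrum objects, or a long-format data frame.
#' @param registry a `gsl_registry`.
#' @param tol fragment m/z tolerance (Da).
#' @param rt_tol retention-time tolerance (min).
#' @param mz_tol precursor m/z tolerance (Da).
#' @return data frame of screen results, one row per spectrum.
#' @export
screen_spectra <- function(spectra, registry = load_registry(), tol = 0.5,
                           rt_tol = 0.5, mz_tol = 0.5) {
  if (is.data.frame(spectra)) spectra <- spectra_from_table(spectra)
  rows <- lapply(spectra, function(sp) {
    match_library(evaluate_rules(sp, tol = tol), sp, registry,
                  rt_tol = rt_tol, mz_tol = mz_tol)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
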