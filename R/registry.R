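# Compound registry: the catalogue of desulfo-glucosinolates the screening and
# quantification stages share, plus the nominal-mass arithmetic rules.

GSL_CLASSES <- c("aliphatic", "aromatic", "indole")

# Published catalogue of the 10 identified glucosinolates plus the sinigrin
# internal standard. Retention times are minutes on the 229 nm HPLC program;
# (R,S)-glucoisatisin elutes as two epimers and keeps both times. The
# correction coefficient rescales UV response relative to sinigrin.
default_registry_df <- function() {
  data.frame(
    name = c("Progoitrin", "Epiprogoitrin", "Sinigrin", "Gluconapin",
             "4-hydroxy-3-indolylmethyl GSL", "Glucobrassicanapin",
             "Glucotropaeolin", "Indolyl-3-methyl",
             "4-methoxy-3-indolylmethyl GSL", "(R,S)-Glucoisatisin",
             "1-methoxy-3-indolylmethyl GSL"),
    gsl_class = c("aliphatic", "aliphatic", "aliphatic", "aliphatic",
                  "indole", "aliphatic", "aromatic", "indole", "indole",
                  "aliphatic", "indole"),
    mw = c(389L, 389L, 359L, 373L, 464L, 387L, 409L, 448L, 478L, 562L, 478L),
    desulfo_mz = c(309L, 309L, 279L, 293L, 384L, 307L, 329L, 368L, 398L,
                   482L, 398L),
    rt_min = c("5.3", "5.8", "6.8", "10.2", "11.9", "13.7", "14.7", "16.8",
               "18.8", "20.9;21.1", "23.8"),
    k = c(1.09, 1.09, 1, 1.11, 0.28, 0.25, 0.95, 0.29, 0.25, 1, 0.2),
    is_internal_standard = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                             FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

validate_registry <- function(df) {
  required <- c("name", "gsl_class", "mw", "desulfo_mz", "rt_min", "k",
                "is_internal_standard")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_format(sprintf("registry: missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    out <- df[required]
    class(out) <- c("gsl_registry", "data.frame")
    return(out)
  }
  if (anyDuplicated(df$name)) {
    stop_validation("registry: duplicate compound names")
  }
  if (!all(df$gsl_class %in% GSL_CLASSES)) {
    stop_validation(sprintf("registry: gsl_class must be one of %s",
                            paste(GSL_CLASSES, collapse = "/")))
  }
  if (any(!is.finite(df$k)) || any(df$k <= 0)) {
    stop_validation("registry: correction coefficient k must be > 0")
  }
  rts <- lapply(df$rt_min, parse_rt)
  if (any(vapply(rts, function(r) any(!is.finite(r)) || any(r <= 0), TRUE))) {
    stop_validation("registry: retention times must be strictly positive")
  }
  df$is_internal_standard <- as.logical(df$is_internal_standard)
  out <- df[required]
  class(out) <- c("gsl_registry", "data.frame")
  out
}

# rt_min holds one or more retention times separated by ";" (epimer pairs).
parse_rt <- function(rt) {
  as.numeric(strsplit(as.character(rt), ";", fixed = TRUE)[[1]])
}

#' Load the glucosinolate compound registry
#'
#' Reads a registry TSV (columns `name`, `gsl_class`, `mw`, `desulfo_mz`,
#' `rt_min`, `k`, `is_internal_standard`) or, with `path = NULL`, returns the
#' packaged default: the ten glucosinolates detected in *Isatis indigotica*
#' plus the sinigrin internal standard, with nominal masses, desulfo m/z,
#' retention times and UV correction coefficients.
#'
#' @param path path to a registry TSV, or `NULL` for the packaged default.
#' @return a `gsl_registry` data frame, one row per compound.
#' @examples
#' reg <- load_registry()
#' reg[reg$is_internal_standard, c("name", "desulfo_mz", "k")]
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    return(validate_registry(default_registry_df()))
  }
  df <- read_tsv_checked(path)
  validate_registry(df)
}

#' Nominal desulfo mass of a glucosinolate
#'
#' Sulfatase desulfation removes SO3 (nominal 80 Da) from the intact
#' glucosinolate, so the desulfo analyte observed by HPLC/MS sits 80 Da below
#' the relative molecular weight.
#'
#' @param mw nominal relative molecular weight(s), positive integers > 80.
#' @return nominal desulfo m/z, `mw - 80`.
#' @examples
#' desulfo_mass(389) # progoitrin -> 309
#' @export
desulfo_mass <- function(mw) {
  if (any(!is.finite(mw)) || any(mw <= 80)) {
    stop_validation("desulfo_mass: mw must exceed 80 Da")
  }
  mw - 80L
}

#' Even-mass (nitrogen rule) screen
#'
#' Glucosinolates carry two nitrogens, so an even nominal molecular mass is
#' consistent with the expected elemental composition; the screen used for the
#' putative indole glucosinolates.
#'
#' @param mw nominal molecular weight(s), positive integers.
#' @return logical: `TRUE` iff `mw` is even.
#' @export
passes_even_mass_rule <- function(mw) {
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    stop_validation("passes_even_mass_rule: mw must be positive")
  }
  mw %% 2 == 0
}

#' Suggest triple-quadrupole MS parameters for a glucosinolate
#'
#' Heuristic instrument settings: fragmentor voltage about one third of the
#' molecular weight and collision energy about one fifteenth, both rounded to
#' the nearest integer (halves away from zero).
#'
#' @param mw nominal molecular weight(s), > 0.
#' @return data frame with `fragmentor_v` and `collision_ev`.
#' @examples
#' suggest_ms_params(448) # 149 V, 30 eV
#' @export
suggest_ms_params <- function(mw) {
  if (any(!is.finite(mw)) || any(mw <= 0)) {
    stop_validation("suggest_ms_params: mw must be positive")
  }
  data.frame(
    mw = mw,
    fragmentor_v = round_half_away(mw / 3),
    collision_ev = round_half_away(mw / 15)
  )
}

# Class lookup used by quantification; errors on unknown compounds rather than
# silently dropping them.
registry_class <- function(registry, compound) {
  idx <- match(compound, registry$name)
  if (anyNA(idx)) {
    stop_validation(sprintf("unknown compound(s): %s",
                            paste(unique(compound[is.na(idx)]), collapse = ", ")))
  }
  registry$gsl_class[idx]
}

registry_k <- function(registry, compound) {
  idx <- match(compound, registry$name)
  if (anyNA(idx)) {
    stop_validation(sprintf("unknown compound(s): %s",
                            paste(unique(compound[is.na(idx)]), collapse = ", ")))
  }
  registry$k[idx]
}
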