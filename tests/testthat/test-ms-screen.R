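make_spectrum <- function(id = "s1", polarity = "negative", precursor = 309,
                          rt = 5.8, frags = c(75, 147),
                          annotated = FALSE) {
  list(spectrum_id = id, polarity = polarity, precursor_mz = precursor,
       rt_min = rt,
       fragments = data.frame(fragment_mz = sort(frags),
                              intensity = rep(1000, length(frags))),
       precursor_annotated = annotated)
}

test_that("diagnostic rules fire on the constructed cases", {
  # oxime + thioglucose neutral loss -> candidate
  r <- evaluate_rules(make_spectrum(frags = c(75, 309 - 162)))
  expect_true(r$R1_sulfide_oxime)
  expect_true(r$R2_neutral_loss)
  expect_true(r$is_candidate)

  # missing the mandatory m/z 75 -> never a candidate
  r <- evaluate_rules(make_spectrum(frags = c(97, 147)))
  expect_false(r$R1_sulfide_oxime)
  expect_false(r$is_candidate)

  # positive-mode aglycone pair, even inferred mass
  r <- evaluate_rules(make_spectrum(polarity = "positive", precursor = 400,
                                    frags = c(144, 160)))
  expect_true(r$R3_aglycone)
  expect_true(r$R4_even_mass)
  expect_equal(r$inferred_molecular_weight, 480)

  # chloride-contaminated 198 Da loss is equivalent evidence
  r <- evaluate_rules(make_spectrum(frags = c(75, 309 - 198)))
  expect_true(r$R2_neutral_loss)
  expect_true(r$is_candidate)

  # annotated precursor substitutes for the neutral-loss evidence
  r <- evaluate_rules(make_spectrum(frags = c(75), annotated = TRUE))
  expect_false(r$R2_neutral_loss)
  expect_true(r$is_candidate)

  # empty fragment list: all flags false, no error
  r <- evaluate_rules(make_spectrum(frags = numeric(0)))
  expect_false(any(c(r$R1_sulfide_oxime, r$R2_neutral_loss, r$R3_aglycone,
                     r$is_candidate)))
})

test_that("rule flags are independent: toggling one fragment flips one flag", {
  base <- c(75, 309 - 162)
  flags <- c("R1_sulfide_oxime", "R2_neutral_loss")
  full <- evaluate_rules(make_spectrum(frags = base))
  for (i in seq_along(base)) {
    r <- evaluate_rules(make_spectrum(frags = base[-i]))
    changed <- vapply(flags, function(fl) full[[fl]] != r[[fl]], TRUE)
    expect_equal(sum(changed), 1L)
    expect_true(changed[[flags[i]]])
  }
})

test_that("retention time disambiguates shared desulfo masses", {
  reg <- load_registry()
  r1 <- match_library(evaluate_rules(make_spectrum(precursor = 309, rt = 5.8,
                                                   frags = c(75, 147))),
                      make_spectrum(precursor = 309, rt = 5.8,
                                    frags = c(75, 147)), reg)
  expect_equal(r1$matched_compound, "Epiprogoitrin")
  sp2 <- make_spectrum(precursor = 309, rt = 5.3, frags = c(75, 147))
  r2 <- match_library(evaluate_rules(sp2), sp2, reg)
  expect_equal(r2$matched_compound, "Progoitrin")
  # outside every retention window: candidate stays putative
  sp3 <- make_spectrum(precursor = 482, rt = 30.0, frags = c(75, 482 - 162))
  r3 <- match_library(evaluate_rules(sp3), sp3, reg)
  expect_true(r3$is_candidate)
  expect_equal(r3$matched_compound, "")
  # either epimer retention time matches glucoisatisin
  sp4 <- make_spectrum(precursor = 482, rt = 21.1, frags = c(75, 482 - 162))
  r4 <- match_library(evaluate_rules(sp4), sp4, reg)
  expect_equal(r4$matched_compound, "(R,S)-Glucoisatisin")
})

test_that("screening is deterministic under row reordering", {
  sp <- gen_spectra(n_decoys = 5, seed = 42)
  res1 <- screen_spectra(sp$spectra)
  shuffled <- sp$spectra[sample(nrow(sp$spectra)), ]
  res2 <- screen_spectra(shuffled)
  expect_equal(res1, res2)
})

test_that("noiseless synthetic spectra screen perfectly", {
  sp <- gen_spectra(n_decoys = 9, seed = 7)
  res <- screen_spectra(sp$spectra)
  merged <- merge(res, sp$truth, by = "spectrum_id")
  true_neg <- merged[merged$kind == "true", ]
  expect_true(all(true_neg$is_candidate))
  # every true spectrum assigned to its generating compound
  expect_equal(true_neg$matched_compound, true_neg$compound)
  # decoys lacking m/z 75 are never candidates
  no_oxime <- merged[merged$violated_rule == "no_oxime", ]
  expect_false(any(no_oxime$is_candidate))
  # odd-mass decoys fail exactly the even-mass rule
  odd <- merged[merged$violated_rule == "odd_mass", ]
  expect_false(any(odd$R4_even_mass))
  # decoys are never assigned to a registry compound
  expect_true(all(merged$matched_compound[merged$kind == "decoy"] == ""))
})
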