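test_that("site counts match the enumeration oracle on spot cases", {
  expect_equal(ng86_sites("TTT")[["S"]], 1 / 3)
  expect_equal(ng86_sites("TTA")[["S"]], 2 / 3)
  expect_equal(ng86_sites("ATG")[["S"]], 0)
  expect_error(ng86_sites("TAA"), class = "gsl_validation_error")
  expect_error(ng86_sites("XYZ"), class = "gsl_validation_error")
})

test_that("difference counts handle single and multi-hit codons", {
  expect_equal(unname(ng86_differences("TTT", "TTA")), c(0, 1))
  expect_equal(unname(ng86_differences("TTT", "GTA")), c(0.5, 1.5))
  expect_equal(unname(ng86_differences("AAA", "AAA")), c(0, 0))
})

test_that("site and difference counters agree with exhaustive oracles", {
  # all 61 sense codons
  for (cd in SENSE) {
    expect_equal(ng86_sites(cd)[["S"]], oracle_syn_sites(cd),
                 info = cd)
  }
  # all 61 x 61 codon pairs: pathway averages and conservation of the
  # number of differing positions
  for (ca in SENSE) {
    a <- strsplit(ca, "")[[1]]
    for (cb in SENSE) {
      got <- ng86_differences(ca, cb)
      ref <- oracle_differences(ca, cb)
      if (!isTRUE(all.equal(unname(got), unname(ref), tolerance = 1e-12))) {
        fail(sprintf("mismatch at %s vs %s", ca, cb))
      }
      ndiff <- sum(a != strsplit(cb, "")[[1]])
      if (abs(got[["Sd"]] + got[["Nd"]] - ndiff) > 1e-12) {
        fail(sprintf("Sd+Nd != ndiff at %s vs %s", ca, cb))
      }
    }
  }
  succeed()
})

test_that("protein-guided codon alignment drops indel columns", {
  same <- backtranslate_align("ATGAAATTT", "ATGAAATTT")
  expect_equal(same$n_codons, 3)
  expect_equal(same$codons_a, same$codons_b)

  # one internal codon deleted: that column dropped, remainder aligned
  del <- backtranslate_align("ATGAAATTTGGGCCC", "ATGAAAGGGCCC")
  expect_equal(del$n_codons, 4)
  expect_equal(del$codons_a, c("ATG", "AAA", "GGG", "CCC"))
  expect_equal(del$codons_b, del$codons_a)

  # terminal stops stripped; internal stop and frame errors rejected
  stopped <- backtranslate_align("ATGAAATGA", "ATGAAATGA")
  expect_equal(stopped$n_codons, 2)
  expect_error(backtranslate_align("ATGTAAAAATTT", "ATGAAATTT"),
               regexp = "internal stop")
  expect_error(backtranslate_align("ATGAAATTTC", "ATGAAATTT"),
               class = "gsl_validation_error")
  expect_error(backtranslate_align("ATGAAA", "ATGAAA", protein_a = "MT"),
               class = "gsl_validation_error")
})

test_that("kaks_pair: sites conserve, JC behaves, worked single-codon case", {
  ident <- kaks_pair(list(pair_id = "id", codons_a = c("ATG", "AAA"),
                          codons_b = c("ATG", "AAA")))
  expect_equal(ident$Ka, 0)
  expect_equal(ident$Ks, 0)
  expect_true(is.na(ident$ka_ks))

  one <- kaks_pair(list(pair_id = "x", codons_a = "TTT", codons_b = "TTA"))
  expect_equal(one$Ka, 0.57161, tolerance = 1e-5)
  expect_equal(one$Ks, 0)
  expect_true(is.na(one$ka_ks))
  expect_equal(one$S_sites + one$N_sites, 3)

  set.seed(20)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    ca <- sample(SENSE, n, replace = TRUE)
    cb <- sample(SENSE, n, replace = TRUE)
    res <- kaks_pair(list(pair_id = "r", codons_a = ca, codons_b = cb))
    expect_equal(res$S_sites + res$N_sites, 3 * n, tolerance = 1e-9)
    ndiff <- sum(mapply(function(a, b) {
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, ca, cb))
    expect_equal(res$Sd + res$Nd, ndiff, tolerance = 1e-9)
  }

  # JC correction: d >= p, monotone, saturation flagged
  jc_d <- function(p) -(3 / 4) * log(1 - 4 * p / 3)
  p <- seq(0.01, 0.7, by = 0.01)
  expect_true(all(jc_d(p) >= p))
  expect_true(all(diff(jc_d(p)) > 0))
  sat <- kaks_pair(list(pair_id = "s",
                        codons_a = rep("GCT", 4),
                        codons_b = c("AGA", "AGA", "AGA", "AGA")))
  expect_true(sat$saturated)
})

test_that("significance filter keeps p <= 0.05 and reports removals", {
  res <- data.frame(pair_id = c("a", "b", "c"),
                    p_value = c(0.04, 0.051, 0.05))
  expect_message(kept <- filter_pairs(res), "removed 1 of 3")
  expect_equal(kept$pair_id, c("a", "c"))
  expect_equal(nrow(suppressMessages(filter_pairs(res[0, ]))), 0)
})

test_that("divergence time is Ks / 2 lambda in Myr", {
  expect_equal(divergence_time(0.10331), 3.44)
  expect_equal(divergence_time(0.08470), 2.82)
  expect_equal(divergence_time(0), 0)
  expect_error(divergence_time(-0.1), class = "gsl_validation_error")
  # linear in ks, inverse in lambda
  ks <- c(0.05, 0.1, 0.2)
  t1 <- divergence_time(ks, digits = NA)
  expect_equal(t1[3] / t1[1], 4)
  expect_equal(divergence_time(0.1, lambda_rate = 3e-8, digits = NA),
               t1[2] / 2)
})

test_that("published-rate arithmetic reproduces ratio and dating", {
  tab <- kaks_derive(c(0.05525, 0.05390), c(0.10331, 0.08470))
  expect_equal(tab$ka_ks, c(0.53480, 0.63636))
  expect_equal(tab$t_myr, c(3.44, 2.82))
})

test_that("Ka/Ks recovery on generated pairs is within 10% of truth", {
  gen <- gen_codon_pairs(n_codons = 300, target_pn = 0.08, target_ps = 0.25,
                         n_pairs = 5, seed = 31)
  res <- kaks_table(gen$pairs, gen$cds)
  expect_true(all(abs(res$ka_ks / gen$truth$ka_ks - 1) <= 0.10))
  expect_true(all(abs(res$Ka - gen$truth$ka) <= 0.02))
  expect_true(all(abs(res$Ks - gen$truth$ks) <= 0.02))
})
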