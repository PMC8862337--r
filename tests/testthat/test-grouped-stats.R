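test_that("ANOVA agrees with the reference implementation", {
  set.seed(2)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) rnorm(sample(3:8, 1), mean = j))
    names(g) <- c("a", "b", "c")
    got <- one_way_anova(g)
    df <- data.frame(value = unlist(g), group = rep(names(g), lengths(g)))
    ref <- oneway.test(value ~ group, df, var.equal = TRUE)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    ref_pw <- pairwise.t.test(df$value, df$group, pool.sd = TRUE,
                              p.adjust.method = "bonferroni")
    expect_equal(got$pairwise_adjusted_p["b", "a"],
                 ref_pw$p.value["b", "a"], tolerance = 1e-10)
    expect_equal(got$pairwise_adjusted_p["c", "b"],
                 ref_pw$p.value["c", "b"], tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate and separation cases", {
  eq <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(unname(eq$letters), c("a", "a"))

  set.seed(4)
  sep <- one_way_anova(list(lo = rnorm(3, 0, 1e-3), mid = rnorm(3, 10, 1e-3),
                            hi = rnorm(3, 20, 1e-3)))
  expect_equal(unname(sort(sep$letters)), c("a", "b", "c"))
  # highest mean takes "a"
  expect_equal(unname(sep$letters["hi"]), "a")

  # only the extremes differ -> a / ab / b
  mid <- one_way_anova(list(lo = c(0, 1, 2), mid = c(1.5, 2.5, 3.5),
                            hi = c(3, 4, 5)))
  expect_true(mid$pairwise_adjusted_p["lo", "hi"] < 0.05)
  expect_true(mid$pairwise_adjusted_p["lo", "mid"] >= 0.05)
  expect_equal(unname(mid$letters[c("hi", "mid", "lo")]), c("a", "ab", "b"))
})

test_that("Kruskal-Wallis H matches hand rank arithmetic and base R", {
  kw <- kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(kw$statistic, 7.2)
  kw2 <- kruskal_wallis(list(a = 1:3, b = 4:6))
  expect_equal(kw2$statistic, 3.857143, tolerance = 1e-6)
  flat <- kruskal_wallis(list(a = c(5, 5), b = c(5, 5, 5)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  set.seed(3)
  g <- list(a = rnorm(6), b = rnorm(5, 1), c = rnorm(7, 2))
  got <- kruskal_wallis(g)
  ref <- kruskal.test(list(g$a, g$b, g$c))
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("ANOVA and KW are invariant to group order and location shift", {
  set.seed(5)
  g <- list(a = rnorm(5), b = rnorm(6, 1), c = rnorm(4, 2))
  swapped <- g[c("c", "a", "b")]
  shifted <- lapply(g, function(v) v + 100)
  expect_equal(one_way_anova(g)$statistic, one_way_anova(swapped)$statistic)
  expect_equal(one_way_anova(g)$statistic, one_way_anova(shifted)$statistic)
  expect_equal(kruskal_wallis(g)$statistic, kruskal_wallis(swapped)$statistic)
  expect_equal(kruskal_wallis(g)$statistic, kruskal_wallis(shifted)$statistic)
})

test_that("Bonferroni-adjusted pairwise p values are monotone and capped", {
  set.seed(6)
  g <- list(a = rnorm(4), b = rnorm(4, 0.5), c = rnorm(4, 1), d = rnorm(4, 5))
  for (cmp in list(one_way_anova(g), kruskal_wallis(g))) {
    pw <- cmp$pairwise_adjusted_p
    expect_true(all(pw >= 0 & pw <= 1))
    expect_true(all(pw == t(pw)))
    expect_true(all(diag(pw) == 1))
    # shared letter iff adjusted p >= alpha
    lt <- cmp$letters
    for (i in 1:3) for (j in (i + 1):4) {
      share <- length(intersect(strsplit(lt[i], "")[[1]],
                                strsplit(lt[j], "")[[1]])) > 0
      expect_equal(share, pw[i, j] >= cmp$alpha)
    }
  }
})

test_that("Pearson association matches cor.test and handles extremes", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_association(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_association(x, -x)$r, -1)
  got <- pearson_association(x, c(1, 3, 2, 4))
  expect_equal(got$r, 0.8)
  ref <- cor.test(x, c(1, 3, 2, 4))
  expect_equal(got$p_value, ref$p.value)
  expect_error(pearson_association(x, rep(1, 4)),
               class = "gsl_validation_error")
})

test_that("letter display satisfies its biconditional on random matrices", {
  set.seed(7)
  for (rep in 1:50) {
    k <- 5
    sig <- matrix(FALSE, k, k)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      sig[i, j] <- sig[j, i] <- runif(1) < 0.4
    }
    means <- rnorm(k)
    lt <- compact_letter_display(sig, means = means,
                                 labels = paste0("g", 1:k))
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      share <- length(intersect(strsplit(lt[i], "")[[1]],
                                strsplit(lt[j], "")[[1]])) > 0
      expect_equal(share, !sig[i, j],
                   info = sprintf("rep %d pair (%d,%d)", rep, i, j))
    }
  }
  # canonical small cases
  none <- compact_letter_display(matrix(FALSE, 3, 3), means = 3:1)
  expect_equal(unname(none), c("a", "a", "a"))
  all_sig <- matrix(TRUE, 3, 3); diag(all_sig) <- FALSE
  expect_equal(unname(compact_letter_display(all_sig, means = 3:1)),
               c("a", "b", "c"))
})
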