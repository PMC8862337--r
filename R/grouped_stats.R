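# Multi-group comparison statistics used on content and Ka/Ks data:
# one-way ANOVA with Bonferroni pairwise t tests (pooled variance),
# Kruskal-Wallis H with Bonferroni-adjusted Dunn pairwise comparisons,
# Pearson association, and compact letter displays.

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  lapply(groups, as.numeric)
}

group_comparison <- function(labels, statistic, p_value, pairwise, means,
                             alpha) {
  letters <- compact_letter_display(pairwise < alpha, means = means,
                                    labels = labels)
  structure(list(group_labels = labels, statistic = statistic,
                 p_value = p_value, pairwise_adjusted_p = pairwise,
                 group_means = means, letters = letters, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("statistic = %.4f, p = %.4g (alpha = %g)\n",
              x$statistic, x$p_value, x$alpha))
  print(data.frame(group = x$group_labels, mean = x$group_means,
                   letters = x$letters[x$group_labels]))
  invisible(x)
}

#' One-way ANOVA with Bonferroni pairwise letters
#'
#' Classical one-way fixed-effects ANOVA (equal-variance F test), followed by
#' all pairwise two-sample t tests using the pooled ANOVA error variance, with
#' Bonferroni multiplication by the number of pairs (capped at 1). Groups are
#' labelled with a compact letter display at level `alpha`: two groups share a
#' letter iff their adjusted p >= `alpha`.
#'
#' @param groups named list of numeric vectors (each n >= 2), or a long
#'   data frame with columns `group` and `value`.
#' @param alpha significance level (default 0.05).
#' @return a `group_comparison`: F statistic, p value, symmetric matrix of
#'   Bonferroni-adjusted pairwise p values, group means and letters.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  g <- as_group_list(groups)
  k <- length(g)
  n <- lengths(g)
  if (k < 2 || any(n < 2)) {
    stop_validation("one_way_anova: >= 2 groups with >= 2 observations each")
  }
  if (any(!vapply(g, function(v) all(is.finite(v)), TRUE))) {
    stop_validation("one_way_anova: values must be finite")
  }
  labels <- names(g)
  means <- vapply(g, mean, 0)
  N <- sum(n)
  grand <- sum(vapply(g, sum, 0)) / N
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  df1 <- k - 1
  df2 <- N - k
  mse <- ss_within / df2
  if (mse == 0) {
    # degenerate: no within-group variance; distinct means separate perfectly
    f <- if (ss_between == 0) 0 else Inf
    p <- if (ss_between == 0) 1 else 0
  } else {
    f <- (ss_between / df1) / mse
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  n_pairs <- k * (k - 1) / 2
  pairwise <- matrix(1, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (mse == 0) {
        praw <- if (means[i] == means[j]) 1 else 0
      } else {
        tstat <- (means[i] - means[j]) / sqrt(mse * (1 / n[i] + 1 / n[j]))
        praw <- 2 * stats::pt(abs(tstat), df2, lower.tail = FALSE)
      }
      pairwise[i, j] <- pairwise[j, i] <- min(1, praw * n_pairs)
    }
  }
  group_comparison(labels, f, p, pairwise, means, alpha)
}

#' Kruskal-Wallis H test with Bonferroni-adjusted Dunn comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p value (df = k - 1),
#' wrapping [stats::kruskal.test()]. Pairwise follow-up uses Dunn's z on mean
#' ranks with the tie-corrected variance, two-sided, Bonferroni-multiplied by
#' the number of pairs.
#'
#' @inheritParams one_way_anova
#' @return a `group_comparison` with the H statistic.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  g <- as_group_list(groups)
  k <- length(g)
  n <- lengths(g)
  N <- sum(n)
  if (k < 2 || any(n < 1) || N < 3) {
    stop_validation("kruskal_wallis: >= 2 non-empty groups, total n >= 3")
  }
  labels <- names(g)
  x <- unlist(g, use.names = FALSE)
  grp <- factor(rep(labels, n), levels = labels)
  if (length(unique(x)) == 1) {
    h <- 0
    p <- 1
    pairwise <- matrix(1, k, k, dimnames = list(labels, labels))
    return(group_comparison(labels, h, p, pairwise, vapply(g, mean, 0), alpha))
  }
  kt <- stats::kruskal.test(x, grp)
  h <- unname(kt$statistic)
  p <- kt$p.value

  r <- rank(x)
  mean_rank <- tapply(r, grp, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  n_pairs <- k * (k - 1) / 2
  pairwise <- matrix(1, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(var_base * (1 / n[i] + 1 / n[j]))
      praw <- if (se == 0) 1 else {
        z <- (mean_rank[i] - mean_rank[j]) / se
        2 * stats::pnorm(abs(z), lower.tail = FALSE)
      }
      pairwise[i, j] <- pairwise[j, i] <- min(1, praw * n_pairs)
    }
  }
  group_comparison(labels, h, p, pairwise, vapply(g, mean, 0), alpha)
}

#' Pearson association with a two-sided t-based p value
#'
#' @param x,y equal-length numeric vectors (n >= 3, both with nonzero
#'   variance).
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_association <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_validation("pearson_association: equal-length vectors, n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_validation("pearson_association: zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Compact letter display from a pairwise-significance matrix
#'
#' Insert-and-absorb algorithm: two groups share at least one letter iff they
#' are not significantly different. Letters are assigned in descending order
#' of group mean (ties broken by label), starting at "a", so the display is
#' deterministic.
#'
#' @param significant symmetric logical matrix, `TRUE` where a pair differs
#'   significantly; diagonal `FALSE`.
#' @param means group means used only to order letters (defaults to reverse
#'   row order -> first row gets "a").
#' @param labels group labels (default from the matrix dimnames).
#' @return named character vector of letter strings.
#' @export
compact_letter_display <- function(significant, means = NULL, labels = NULL) {
  significant <- as.matrix(significant)
  k <- nrow(significant)
  if (k != ncol(significant) || !isTRUE(all(significant == t(significant)))) {
    stop_validation("compact_letter_display: matrix must be square and symmetric")
  }
  if (any(diag(significant))) {
    stop_validation("compact_letter_display: diagonal must be FALSE")
  }
  if (is.null(labels)) labels <- rownames(significant)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  if (is.null(means)) means <- rev(seq_len(k))

  # order in which letters are assigned: highest mean first
  ord <- order(-means, labels)

  # columns: sets of groups sharing one letter (logical membership vectors)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!significant[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          new_cols <- c(new_cols, list(a, b))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a == b || !keep[a]) next
          sub_ab <- all(!new_cols[[a]] | new_cols[[b]])
          if (sub_ab && (!all(new_cols[[a]] == new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # letter columns ordered by their highest-ranked member
  first_member <- vapply(cols, function(col) min(match(which(col), ord)), 0)
  cols <- cols[order(first_member)]
  out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(col) col[i], TRUE))],
          collapse = "")
  }, "")
  names(out) <- labels
  out
}
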