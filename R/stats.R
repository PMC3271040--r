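# Statistical layer: group tests on densities and the quantile-quantile
# equalization used to compare counting methods.

#' Welch's unpaired t-test
#'
#' Two-sided unpaired t-test with Welch's correction (Satterthwaite degrees
#' of freedom), as used to compare cone densities between ages.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return List `t`, `df`, `p`, plus `zero_variance` flag for the degenerate
#'   all-constant case (both constant and equal: t = 0, p = 1 by
#'   convention; both constant and different: p = 0).
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0, zero_variance = TRUE))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), zero_variance = FALSE)
}

#' Paired t-test
#'
#' One-sample t-test on the paired differences (df = n - 1), as used for
#' the dorsal-versus-ventral comparison with pairing by retina.
#'
#' @param a,b numeric samples of equal length n >= 2, paired by position.
#' @return List `t`, `df`, `p`, `mean_difference`, and a `zero_variance`
#'   flag (all differences identical: p = 1 if the common difference is 0,
#'   otherwise p reported as 0 with the flag raised).
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b))
    stop("paired samples must have equal length")
  stopifnot(length(a) >= 2)
  d <- a - b
  if (sd(d) == 0) {
    zero <- isTRUE(all.equal(mean(d), 0))
    return(list(t = if (zero) 0 else Inf * sign(mean(d)),
                df = length(d) - 1L,
                p = if (zero) 1 else 0,
                mean_difference = mean(d), zero_variance = TRUE))
  }
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), mean_difference = mean(d),
       zero_variance = FALSE)
}

#' Two-way fixed-effects ANOVA (day x method)
#'
#' Standard two-way decomposition with interaction on a tidy data frame.
#' Balanced designs use the classical sequential table; unbalanced designs
#' use type-II sums of squares. Effects whose sum of squares vanishes are
#' reported with F = 0 and p = 1 (this includes the degenerate all-values-
#' identical input).
#'
#' @param data data frame with the response and two factor columns.
#' @param value,day,method column names (character).
#' @return An object of class `anova_table`: data frame with `term`, `ss`,
#'   `df`, `F`, `p` (terms: day, method, day:method, Residuals).
#' @export
two_way_anova <- function(data, value = "density", day = "day",
                          method = "method") {
  stopifnot(all(c(value, day, method) %in% names(data)))
  df <- data.frame(y = data[[value]],
                   day = factor(data[[day]]),
                   method = factor(data[[method]]))
  stopifnot(nlevels(df$day) >= 2, nlevels(df$method) >= 2)
  cell_n <- table(df$day, df$method)
  if (any(cell_n == 0)) {
    empty <- which(cell_n == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: day '%s', method '%s'",
                 rownames(cell_n)[empty[1]], colnames(cell_n)[empty[2]]))
  }
  fit <- lm(y ~ day * method, data = df)
  balanced <- length(unique(as.vector(cell_n))) == 1
  # F and p are recomputed below from the sums of squares (degenerate
  # zero-variance designs need the F = 0 / p = 1 convention), so the
  # fitters' own F-statistics are discarded
  an <- suppressWarnings(if (balanced) stats::anova(fit)
                         else car::Anova(fit, type = 2))
  ss <- an[["Sum Sq"]]; dfree <- an[["Df"]]
  terms <- rownames(an)
  terms <- sub("^day:method$", "day:method", terms)
  res_i <- which(terms == "Residuals")
  ms_res <- ss[res_i] / max(dfree[res_i], 1)
  tol <- 1e-12 * max(sum(ss), 1)
  Fv <- rep(NA_real_, length(ss)); pv <- rep(NA_real_, length(ss))
  for (i in setdiff(seq_along(ss), res_i)) {
    if (ss[i] <= tol) { Fv[i] <- 0; pv[i] <- 1 }
    else if (ms_res <= tol / max(dfree[res_i], 1)) { Fv[i] <- Inf; pv[i] <- 0 }
    else {
      Fv[i] <- (ss[i] / dfree[i]) / ms_res
      pv[i] <- pf(Fv[i], dfree[i], dfree[res_i], lower.tail = FALSE)
    }
  }
  structure(data.frame(term = terms, ss = ss, df = dfree, F = Fv, p = pv,
                       stringsAsFactors = FALSE),
            class = c("anova_table", "data.frame"),
            balanced = balanced)
}

#' Significance marks as used in the figures
#' @param p numeric p-values.
#' @return Character: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, else "".
#' @export
signif_marks <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Quantile-quantile equalization across counting methods
#'
#' Makes the quantiles of the sets of measures obtained by each technique
#' identical: each dataset is sorted, the rank-r value of every dataset is
#' replaced by the mean across datasets of their rank-r values, and values
#' are returned to their original positions (ties keep their stable
#' original order). After the operation the sorted vectors of all datasets
#' are identical and the grand sum is preserved exactly.
#'
#' @param datasets list of equal-length numeric vectors, one per method.
#' @return List of normalized vectors (same names and lengths).
#' @export
quantile_equalize <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  n <- unique(lengths(datasets))
  if (length(n) != 1)
    stop(paste0("datasets must have equal sizes; resize them first ",
                "(see enumerate_equalizations)"))
  ord <- lapply(datasets, order)
  sorted <- mapply(function(x, o) x[o], datasets, ord, SIMPLIFY = FALSE)
  rank_mean <- Reduce(`+`, sorted) / length(datasets)
  out <- mapply(function(x, o) {
    x[o] <- rank_mean
    x
  }, datasets, ord, SIMPLIFY = FALSE)
  names(out) <- names(datasets)
  out
}

#' Enumerate the equal-size resizings of unequal datasets
#'
#' When the methods yield different numbers of measures per group, they are
#' made comparable by deleting surplus values; every possible deletion
#' choice is enumerated so the downstream normalization + ANOVA can be run
#' on all combinations. Each oversized dataset of size m with surplus s
#' contributes choose(m, s) choices; combinations are the cross product.
#'
#' @param datasets list of numeric vectors.
#' @param target_n target common size (default: the minimum size).
#' @param max_combinations guard against combinatorial explosion (default
#'   1e6).
#' @return List of combinations; each combination is a list of trimmed
#'   vectors (all of length `target_n`), with attribute `dropped` giving
#'   the deleted indices per dataset.
#' @export
enumerate_equalizations <- function(datasets, target_n = min(lengths(datasets)),
                                    max_combinations = 1e6) {
  stopifnot(is.list(datasets), length(datasets) >= 1,
            target_n >= 1, all(lengths(datasets) >= target_n))
  surplus <- lengths(datasets) - target_n
  n_comb <- prod(mapply(choose, lengths(datasets), surplus))
  if (n_comb > max_combinations)
    stop(sprintf(paste0("%.3g combinations exceed the %.3g guard; sample ",
                        "deletion choices instead of enumerating them"),
                 n_comb, max_combinations))
  choices <- mapply(function(x, s) {
    if (s == 0) return(list(integer(0)))
    drop_sets <- combn(length(x), s)
    lapply(seq_len(ncol(drop_sets)), function(j) drop_sets[, j])
  }, datasets, surplus, SIMPLIFY = FALSE)
  idx_grid <- expand.grid(lapply(choices, seq_along))
  lapply(seq_len(nrow(idx_grid)), function(i) {
    dropped <- mapply(function(ch, k) ch[[k]], choices,
                      as.integer(idx_grid[i, ]), SIMPLIFY = FALSE)
    comb <- mapply(function(x, dr) if (length(dr)) x[-dr] else x,
                   datasets, dropped, SIMPLIFY = FALSE)
    attr(comb, "dropped") <- dropped
    comb
  })
}
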