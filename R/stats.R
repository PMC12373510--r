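# Nonparametric statistical layer, written from first principles: exact
# (enumeration) small-sample paths with tie-corrected normal approximations
# otherwise, Benjamini-Hochberg step-up adjustment, Grubbs outlier screening
# and delta-delta-Ct relative quantification.

new_els_test <- function(statistic, p_value, method, n1, n2 = NA_integer_,
                         exact = FALSE, alternative = "two.sided") {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         n1 = n1, n2 = n2, exact = exact, alternative = alternative),
    class = "els_test"
  )
}

#' @export
print.els_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.6g (%s, n1 = %d%s)\n",
              x$method, x$statistic, x$p_value,
              if (x$exact) "exact" else "normal approximation",
              x$n1, if (is.na(x$n2)) "" else sprintf(", n2 = %d", x$n2)))
  invisible(x)
}

#' @method tidy els_test
#' @export
tidy.els_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method,
         n1 = x$n1, n2 = x$n2, exact = x$exact, alternative = x$alternative)
}

two_sided_from_cdf <- function(le, ge) min(1, 2 * min(le, ge))

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midranks for ties.
#' The p-value is exact (full enumeration of the `choose(n1+n2, n1)` group
#' labelings) when `n1 + n2 <= 12` and there are no ties; otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#' Two-sided p-values double the smaller exact tail (capped at 1).
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x` vs `y`).
#' @return An `els_test` with the U statistic of `x`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1 exactly
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty.")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n <= 12) {
    combos <- combn(n, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    le <- mean(us <= u); ge <- mean(us >= u)
    p <- switch(alternative,
      two.sided = two_sided_from_cdf(le, ge),
      less = le,      # small U <=> x shifted down
      greater = ge
    )
    return(new_els_test(u, p, "Mann-Whitney U test", n1, n2, exact = TRUE,
                        alternative = alternative))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  sigma <- sqrt(sigma2)
  p <- if (sigma == 0) {
    1
  } else {
    switch(alternative,
      two.sided = 2 * pnorm(-(max(abs(u - mu) - 0.5, 0)) / sigma),
      less = pnorm((u - mu + 0.5) / sigma),
      greater = pnorm(-(u - mu - 0.5) / sigma)
    )
  }
  new_els_test(u, min(p, 1), "Mann-Whitney U test", n1, n2, exact = FALSE,
               alternative = alternative)
}

#' Wilcoxon signed-rank test
#'
#' Paired-sample rank test. Zero differences are dropped before ranking
#' (Wilcoxon's convention); midranks are used for tied absolute differences.
#' Exact p by enumeration of all `2^n` sign patterns (conditioning on the
#' observed midranks) when the effective `n <= 15`; tie-corrected normal
#' approximation with continuity correction otherwise. All differences zero
#' is degenerate: p = 1 with a warning.
#'
#' @param x,y Paired numeric samples of equal length.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return An `els_test` with statistic W (sum of positive-difference ranks).
#' @examples
#' wilcoxon_signed_rank(2:7, 1:6)$p_value # 2 / 2^6
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) == 0) {
    abort("`x` and `y` must be paired samples of equal positive length.")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; degenerate test (p = 1).")
    return(new_els_test(0, 1, "Wilcoxon signed-rank test", length(x),
                        exact = TRUE, alternative = alternative))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 15) {
    # enumeration conditions on the observed midranks, so it remains exact
    # under tied absolute differences
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    le <- mean(ws <= w); ge <- mean(ws >= w)
    p <- switch(alternative,
      two.sided = two_sided_from_cdf(le, ge),
      less = le,
      greater = ge
    )
    return(new_els_test(w, p, "Wilcoxon signed-rank test", length(x),
                        exact = TRUE, alternative = alternative))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  sigma <- sqrt(sigma2)
  p <- if (sigma == 0) {
    1
  } else {
    switch(alternative,
      two.sided = 2 * pnorm(-(max(abs(w - mu) - 0.5, 0)) / sigma),
      less = pnorm((w - mu + 0.5) / sigma),
      greater = pnorm(-(w - mu - 0.5) / sigma)
    )
  }
  new_els_test(w, min(p, 1), "Wilcoxon signed-rank test", length(x),
               exact = FALSE, alternative = alternative)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj[i] = min_{j: p_(j) >= p_(i)} min(1, m * p_(j) / j)` over the m
#' finite p-values; NAs are passed through and excluded from m.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  o <- order(p[ok])
  ps <- p[ok][o]
  adj <- pmin(1, ps * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out[ok[o]] <- adj
  out
}

#' Spearman correlation matrix with FDR adjustment
#'
#' Spearman r computed as Pearson correlation of midranks over
#' pairwise-complete observations; p-values from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` with n-2 degrees of freedom;
#' Benjamini-Hochberg step-up applied over the strict upper triangle (each
#' variable pair tested once). Constant variables yield `NA` for their pairs
#' and are excluded from the adjustment family.
#'
#' @param data Data frame or matrix of numeric variables (columns).
#' @return An `els_cormat`: list with `variables`, matrices `r`, `p_raw`,
#'   `p_adj`, and `n` (pairwise sample sizes).
#' @examples
#' spearman_matrix(data.frame(a = 1:6, b = c(2, 1, 4, 3, 6, 5)))$r
#' @export
spearman_matrix <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m) || ncol(m) < 2) {
    abort("`data` must have at least two numeric columns.")
  }
  vars <- colnames(m) %||% sprintf("V%d", seq_len(ncol(m)))
  k <- ncol(m)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- r
  nmat <- matrix(NA_integer_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  diag(p) <- NA
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(m[, c(i, j)])
      n <- sum(ok)
      nmat[i, j] <- nmat[j, i] <- n
      if (n < 3) next
      xi <- rank(m[ok, i]); yj <- rank(m[ok, j])
      if (sd(xi) == 0 || sd(yj) == 0) next # constant variable: undefined
      rho <- sum((xi - mean(xi)) * (yj - mean(yj))) /
        sqrt(sum((xi - mean(xi))^2) * sum((yj - mean(yj))^2))
      r[i, j] <- r[j, i] <- rho
      pv <- if (abs(rho) >= 1) {
        0
      } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * pt(-abs(tstat), df = n - 2)
      }
      p[i, j] <- p[j, i] <- pv
    }
  }
  upper <- which(upper.tri(p))
  padj <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  padj[upper] <- bh_adjust(p[upper])
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  structure(
    list(variables = vars, r = r, p_raw = p, p_adj = padj, n = nmat),
    class = "els_cormat"
  )
}

#' @export
print.els_cormat <- function(x, digits = 3, ...) {
  cat(sprintf("<els_cormat> %d variables (Spearman, BH-adjusted)\n",
              length(x$variables)))
  print(round(x$r, digits))
  invisible(x)
}

#' @method tidy els_cormat
#' @export
tidy.els_cormat <- function(x, ...) {
  k <- length(x$variables)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    var1 = x$variables[idx[, 1]],
    var2 = x$variables[idx[, 2]],
    estimate = x$r[idx],
    p.value = x$p_raw[idx],
    p.adjusted = x$p_adj[idx],
    n = x$n[idx]
  )
}

#' Grubbs critical value
#'
#' Closed form `((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2))` with t the upper
#' `alpha/(2n)` quantile of Student's t with n-2 degrees of freedom.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @return The critical value for the two-sided single-outlier test.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (any(n < 3)) abort("Grubbs test needs n >= 3.")
  tq <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Grubbs outlier test
#'
#' Flags the most extreme value when `G = max|x - mean| / sd` exceeds the
#' closed-form critical value; `iterate = TRUE` repeats on the reduced
#' sample until nothing is flagged or only 3 values remain (single-pass is
#' the default).
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Significance level (default 0.05).
#' @param iterate Repeat after each exclusion.
#' @return An `els_grubbs`: list with `outliers` (indices into `values`,
#'   possibly empty), `G`, `critical` (per pass) and `kept` indices.
#' @examples
#' grubbs(c(10, 10.5, 9.5, 10.2, 9.8, 30))$outliers # 6
#' @export
grubbs <- function(values, alpha = 0.05, iterate = FALSE) {
  values <- as.numeric(values)
  if (length(values) < 3) abort("Grubbs test needs at least 3 values.")
  keep <- seq_along(values)
  out <- integer(0)
  gs <- numeric(0); crits <- numeric(0)
  repeat {
    v <- values[keep]
    n <- length(v)
    s <- sd(v)
    if (s == 0) break
    dev <- abs(v - mean(v))
    g <- max(dev) / s
    crit <- grubbs_critical(n, alpha)
    gs <- c(gs, g); crits <- c(crits, crit)
    if (g > crit) {
      i <- keep[which.max(dev)]
      out <- c(out, i)
      keep <- setdiff(keep, i)
      if (!iterate || length(keep) < 3) break
    } else break
  }
  structure(
    list(outliers = out, G = gs, critical = crits, kept = keep,
         alpha = alpha, iterate = iterate),
    class = "els_grubbs"
  )
}

#' @export
print.els_grubbs <- function(x, ...) {
  cat(sprintf("Grubbs test (alpha = %g%s): %s\n", x$alpha,
              if (x$iterate) ", iterated" else "",
              if (length(x$outliers)) {
                paste("outlier indices", paste(x$outliers, collapse = ", "))
              } else "no outliers"))
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change `2^-ddCt` with
#' `ddCt = (Ct_target_sample - Ct_ref_sample) -
#'         (Ct_target_calibrator - Ct_ref_calibrator)`.
#' Each argument may be a vector of duplicate wells, averaged on the Ct
#' scale before differencing.
#'
#' @param ct_target_sample,ct_ref_sample Target / housekeeping Ct in the
#'   sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Same in the calibrator.
#' @return The fold change (numeric scalar) with attribute `ddct`.
#' @examples
#' ddct_fold_change(25, 20, 24, 20) # 0.5
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  vals <- c(ct_target_sample, ct_ref_sample,
            ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(vals))) abort("all Ct values must be finite.")
  ddct <- (mean(ct_target_sample) - mean(ct_ref_sample)) -
    (mean(ct_target_calibrator) - mean(ct_ref_calibrator))
  structure(2^(-ddct), ddct = ddct)
}

#' Significance stars
#'
#' Figure-legend convention: `****` p < 0.0001, `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
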