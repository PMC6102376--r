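ttest_result <- function(t, df, p, kind) {
  structure(list(t = t, df = df, p_two_sided = p, kind = kind),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s t test: t(%.2f) = %.4f, p = %.4g\n", x$kind, x$df, x$t,
              x$p_two_sided))
  invisible(x)
}

two_sided_p <- function(t, df) 2 * pt(-abs(t), df)

#' Two-sample t tests, implemented from the defining formulas
#'
#' `welch_t()` is the unequal-variance test with Welch--Satterthwaite
#' degrees of freedom; `student_t()` the pooled-variance test; `paired_t()`
#' the one-sample test on within-pair differences. All report two-sided p
#' values. A zero difference with zero spread (e.g. identical samples in a
#' paired test) is reported as t = 0, p = 1.
#'
#' @param a,b Numeric samples, each with at least 2 values (equal length for
#'   `paired_t()`).
#' @return An object of class `"ttest_result"`: `t`, `df`, `p_two_sided`,
#'   `kind`.
#' @examples
#' welch_t(rnorm(10), rnorm(12, 1))
#' @export
welch_t <- function(a, b) {
  check_sample(a); check_sample(b)
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  se <- sqrt(va + vb)
  t <- safe_ratio(mean(a) - mean(b), se)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  ttest_result(t, df, if (t == 0 && se == 0) 1 else two_sided_p(t, df),
               "welch")
}

#' @rdname welch_t
#' @export
student_t <- function(a, b) {
  check_sample(a); check_sample(b)
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- safe_ratio(mean(a) - mean(b), se)
  df <- na + nb - 2
  ttest_result(t, df, if (t == 0 && se == 0) 1 else two_sided_p(t, df),
               "student")
}

#' @rdname welch_t
#' @export
paired_t <- function(a, b) {
  check_sample(a); check_sample(b)
  if (length(a) != length(b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  d <- a - b
  n <- length(d)
  se <- sd(d) / sqrt(n)
  t <- safe_ratio(mean(d), se)
  df <- n - 1
  ttest_result(t, df, if (t == 0 && se == 0) 1 else two_sided_p(t, df),
               "paired")
}

check_sample <- function(x) {
  if (!is.numeric(x) || sum(!is.na(x)) < 2L) {
    stop("each sample needs at least 2 non-missing values", call. = FALSE)
  }
}

# 0/0 -> 0 so that degenerate identical samples give t = 0 rather than NaN.
safe_ratio <- function(num, den) {
  if (den == 0) {
    if (num == 0) 0 else sign(num) * Inf
  } else {
    num / den
  }
}

check_rm_table <- function(data) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("the subjects x levels table must be numeric",
                              call. = FALSE)
  if (any(is.na(data))) {
    stop("the subjects x levels table has missing cells; no imputation is ",
         "performed", call. = FALSE)
  }
  if (nrow(data) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (ncol(data) < 2L) stop("need at least 2 levels", call. = FALSE)
  data
}

# Orthonormal contrast matrix (k x (k-1)) spanning the space orthogonal to
# the grand mean; used for the Mauchly and Greenhouse-Geisser computations.
orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' One-way repeated-measures ANOVA with sphericity diagnostics
#'
#' Within-subject one-way F test for a subjects-by-levels table, with the
#' Mauchly test of sphericity (chi-square approximation) and the
#' Greenhouse--Geisser epsilon estimated from the covariance of the
#' orthonormalized level contrasts. With k = 2 levels sphericity holds
#' trivially (W = 1, epsilon = 1) and F equals the square of the paired t
#' statistic.
#'
#' `p_reported` applies the stated correction policy: by default the
#' epsilon-corrected p is used only when the Mauchly test rejects at
#' `alpha`; `"always"` and `"never"` modes are available.
#'
#' @param data Numeric matrix or data.frame, one row per subject, one column
#'   per level; complete (no missing cells), at least 3 subjects.
#' @param correct `"if_violated"` (default), `"always"` or `"never"`.
#' @param alpha Significance level for the sphericity gate. Default 0.05.
#' @return An object of class `"rm_anova_result"`: `F`, `df_num`, `df_den`,
#'   `p_uncorrected`, `mauchly_W`, `mauchly_chisq`, `mauchly_df`,
#'   `mauchly_p`, `gg_epsilon`, `df_num_gg`, `df_den_gg`, `p_gg`,
#'   `p_reported`, `correction_applied`.
#' @examples
#' y <- matrix(rnorm(28), 7, 4)
#' rm_anova_gg(y)
#' @export
rm_anova_gg <- function(data, correct = c("if_violated", "always", "never"),
                        alpha = 0.05) {
  correct <- match.arg(correct)
  y <- check_rm_table(data)
  n <- nrow(y)
  k <- ncol(y)
  d <- k - 1L

  grand <- mean(y)
  col_m <- colMeans(y)
  row_m <- rowMeans(y)
  ss_treat <- n * sum((col_m - grand)^2)
  resid <- y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ss_err <- sum(resid^2)
  df_num <- d
  df_den <- d * (n - 1L)
  ms_treat <- ss_treat / df_num
  ms_err <- ss_err / df_den
  f <- if (ms_err == 0) {
    if (ms_treat == 0) 0 else Inf
  } else {
    ms_treat / ms_err
  }
  p_unc <- pf(f, df_num, df_den, lower.tail = FALSE)
  if (f == 0) p_unc <- 1

  # Sphericity diagnostics on the contrast-space covariance.
  cmat <- orthonormal_contrasts(k)
  s <- stats::cov(y)
  tt <- t(cmat) %*% s %*% cmat
  tr <- sum(diag(tt))
  eps <- tr^2 / (d * sum(tt^2))
  if (k == 2L) {
    w <- 1
    chisq <- 0
    mdf <- NA_real_
    mp <- NA_real_
    eps <- 1
  } else {
    w <- det(tt) / (tr / d)^d
    w <- min(max(w, .Machine$double.xmin), 1)
    # Box's chi-square approximation with the second-order correction term
    nd <- n - 1
    rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nd)
    # second-order coefficient as in stats::mauchly.test (note the 3*k term)
    omega2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * k + 2) /
      (288 * (nd * d * rho)^2)
    chisq <- -nd * rho * log(w)
    mdf <- d * (d + 1) / 2 - 1
    p1 <- pchisq(chisq, mdf, lower.tail = FALSE)
    p2 <- pchisq(chisq, mdf + 4, lower.tail = FALSE)
    mp <- p1 + omega2 * (p2 - p1)
  }

  df_num_gg <- eps * df_num
  df_den_gg <- eps * df_den
  p_gg <- pf(f, df_num_gg, df_den_gg, lower.tail = FALSE)
  if (f == 0) p_gg <- 1

  applied <- switch(correct,
                    if_violated = !is.na(mp) && mp < alpha,
                    always = TRUE,
                    never = FALSE)
  structure(list(F = f, df_num = df_num, df_den = df_den,
                 p_uncorrected = p_unc, mauchly_W = w, mauchly_chisq = chisq,
                 mauchly_df = mdf, mauchly_p = mp, gg_epsilon = eps,
                 df_num_gg = df_num_gg, df_den_gg = df_den_gg, p_gg = p_gg,
                 p_reported = if (applied) p_gg else p_unc,
                 correction_applied = applied),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%g, %g) = %.3f, p = %.4g\n",
              x$df_num, x$df_den, x$F, x$p_uncorrected))
  if (!is.na(x$mauchly_p)) {
    cat(sprintf("  Mauchly W = %.4f, chi2(%g) = %.3f, p = %.4g\n",
                x$mauchly_W, x$mauchly_df, x$mauchly_chisq, x$mauchly_p))
  }
  cat(sprintf("  Greenhouse-Geisser epsilon = %.4f; F(%.2f, %.2f), p = %.4g%s\n",
              x$gg_epsilon, x$df_num_gg, x$df_den_gg, x$p_gg,
              if (x$correction_applied) " [applied]" else ""))
  invisible(x)
}

#' Planned pairwise comparisons across levels
#'
#' Paired t tests for every pair of levels of a subjects-by-levels table,
#' uncorrected (planned contrasts at alpha = .05).
#'
#' @inheritParams rm_anova_gg
#' @return A data.frame with one row per level pair: `level_a`, `level_b`,
#'   `t`, `df`, `p_two_sided`.
#' @export
paired_comparisons <- function(data) {
  y <- check_rm_table(data)
  labs <- colnames(y)
  if (is.null(labs)) labs <- paste0("L", seq_len(ncol(y)))
  pairs <- utils::combn(ncol(y), 2)
  out <- apply(pairs, 2, function(pr) {
    res <- paired_t(y[, pr[1]], y[, pr[2]])
    data.frame(level_a = labs[pr[1]], level_b = labs[pr[2]], t = res$t,
               df = res$df, p_two_sided = res$p_two_sided,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
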