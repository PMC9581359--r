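#' One-way repeated-measures ANOVA
#'
#' Compares a scalar outcome (e.g. total difficulty, or a velocity peak)
#' across k within-subject conditions. Computed from the sums-of-squares
#' decomposition: with subject means removed, the condition mean square is
#' tested against the subject-by-condition residual,
#' \eqn{F = MS_{cond} / MS_{error}} on \eqn{(k - 1,\; (k-1)(n-1))} degrees
#' of freedom. Sphericity is assumed (no correction is applied); normality
#' and sphericity checks are standard library calls left to the caller.
#'
#' @param mat Numeric matrix or data frame, subjects in rows, conditions in
#'   columns, complete (no missing cells; none are imputed).
#' @return An object of class `rm_anova`: list with `F`, `df1`, `df2`, `p`,
#'   the mean squares, and the condition means.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells are not allowed (no imputation)")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 conditions; got ", n, " x ", k)
  grand <- mean(mat)
  col_m <- colMeans(mat)
  row_m <- rowMeans(mat)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  Fval <- if (ms_err > 0) ms_cond / ms_err else if (ms_cond == 0) 0 else Inf
  p <- stats::pf(Fval, df1, df2, lower.tail = FALSE)
  structure(list(F = Fval, df1 = df1, df2 = df2, p = p,
                 MS_condition = ms_cond, MS_error = ms_err,
                 condition_means = col_m, n_subjects = n, n_conditions = k),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("One-way repeated-measures ANOVA: F(%d,%d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Bonferroni-corrected paired comparisons
#'
#' All k(k-1)/2 two-sided paired t-tests between condition columns, with the
#' Bonferroni critical level `alpha / npairs`. A pair whose difference
#' vector has zero variance but non-zero mean has no defined t statistic and
#' is flagged; an identical pair (all differences exactly zero) reports
#' t = 0, p = 1.
#'
#' @param mat Numeric matrix or data frame, subjects x conditions.
#' @param alpha Family-wise level, default 0.05.
#' @return Data frame with columns `cond1`, `cond2`, `t`, `df`, `p`,
#'   `p_critical`, `significant`, `flagged`.
#' @export
bonferroni_pairs <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells are not allowed")
  k <- ncol(mat)
  if (k < 2L) stop("need at least 2 conditions")
  labs <- colnames(mat)
  if (is.null(labs)) labs <- paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2)
  crit <- alpha / ncol(pairs)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    d <- mat[, i1] - mat[, i2]
    if (stats::sd(d) == 0) {
      if (all(d == 0))
        return(data.frame(cond1 = labs[i1], cond2 = labs[i2], t = 0,
                          df = length(d) - 1L, p = 1, p_critical = crit,
                          significant = FALSE, flagged = FALSE))
      return(data.frame(cond1 = labs[i1], cond2 = labs[i2], t = NA_real_,
                        df = length(d) - 1L, p = NA_real_, p_critical = crit,
                        significant = NA, flagged = TRUE))
    }
    tt <- stats::t.test(mat[, i1], mat[, i2], paired = TRUE)
    data.frame(cond1 = labs[i1], cond2 = labs[i2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_critical = crit,
               significant = tt$p.value < crit, flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Compare conditions: ANOVA plus post hocs
#'
#' Convenience wrapper running [rm_anova()] and [bonferroni_pairs()] on the
#' same subjects-by-conditions matrix.
#'
#' @param mat Numeric matrix or data frame, subjects x conditions.
#' @param alpha Family-wise level for the post hocs.
#' @return List of class `condition_comparison` with elements `anova` and
#'   `pairs`.
#' @export
compare_conditions <- function(mat, alpha = 0.05) {
  structure(list(anova = rm_anova(mat), pairs = bonferroni_pairs(mat, alpha)),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  print(x$anova)
  cat(sprintf("Bonferroni-corrected paired t-tests (critical p = %.4g):\n",
              x$pairs$p_critical[1L]))
  print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}
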