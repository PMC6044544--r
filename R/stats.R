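#' One-sample t test on per-subject scores
#'
#' @param values Numeric vector of per-subject values.
#' @param mu0 Null mean (default 0).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `t`, `df`, `p`, `mean`.
#' @export
one_sample_t <- function(values, mu0 = 0, alternative = "two.sided") {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values")
  if (stats::sd(values) == 0)
    stop("zero variance: one-sample t undefined")
  tt <- stats::t.test(values, mu = mu0, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = unname(tt$estimate))
}

# Extract one within-subject effect from a car::Anova summary into the
# package's anova_result shape, applying the Mauchly -> GG rule.
extract_rm_effect <- function(s, effect, k_eff, n) {
  ut <- s$univariate.tests
  row <- ut[effect, , drop = TRUE]
  F_val <- unname(row["F value"])
  df1 <- unname(row["num Df"]); df2 <- unname(row["den Df"])
  # a zero effect sum of squares (e.g. identical factor levels) is a null
  # effect, not a 0/0 indeterminate
  if (!is.finite(F_val) && unname(row["Sum Sq"]) < 1e-12) {
    return(structure(list(F = 0, df1 = df1, df2 = df2, p = 1, epsilon = 1,
                          sphericity_violated = FALSE,
                          mauchly_W = NA_real_, mauchly_p = NA_real_),
                     class = "anova_result"))
  }
  mauchly_W <- NA_real_; mauchly_p <- NA_real_; eps <- 1
  if (k_eff > 2 && !is.null(s$sphericity.tests) &&
      effect %in% rownames(s$sphericity.tests)) {
    mauchly_W <- s$sphericity.tests[effect, "Test statistic"]
    mauchly_p <- s$sphericity.tests[effect, "p-value"]
    eps <- s$pval.adjustments[effect, "GG eps"]
  }
  violated <- is.finite(mauchly_p) && mauchly_p < 0.05
  if (violated) { df1 <- df1 * eps; df2 <- df2 * eps }
  p <- stats::pf(F_val, df1, df2, lower.tail = FALSE)
  structure(list(F = F_val, df1 = df1, df2 = df2, p = p,
                 epsilon = unname(eps), sphericity_violated = violated,
                 mauchly_W = unname(mauchly_W),
                 mauchly_p = unname(mauchly_p)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%.4g, %.4g) = %.3f, p = %.4g%s\n", x$df1, x$df2, x$F, x$p,
              if (x$sphericity_violated)
                sprintf(" [Greenhouse-Geisser, eps = %.3f]", x$epsilon)
              else ""))
  invisible(x)
}

#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Within-subject F test on a complete subject x condition table.
#' Mauchly's test is computed for k > 2 conditions; when it rejects at
#' p < .05 both degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon and the p value recomputed, mirroring the
#' classical SPSS-style output. With k = 2, sphericity holds by
#' construction (epsilon = 1) and F equals the squared paired t.
#'
#' @param table Numeric matrix or data.frame, subjects x conditions,
#'   complete (no missing cells; none are imputed).
#' @return An `anova_result`: `F`, `df1`, `df2`, `p`, `epsilon`,
#'   `sphericity_violated`, `mauchly_W`, `mauchly_p`.
#' @export
rm_anova <- function(table) {
  table <- as.matrix(table)
  if (anyNA(table)) stop("missing cells: repeated-measures ANOVA needs a complete table")
  n <- nrow(table); k <- ncol(table)
  if (k < 2 || n < 3) stop("need k >= 2 conditions and n >= 3 subjects")
  idata <- data.frame(cond = factor(seq_len(k)))
  mlm <- stats::lm(table ~ 1)
  av <- car::Anova(mlm, idata = idata, idesign = ~cond, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  extract_rm_effect(s, "cond", k, n)
}

#' Two-way fully within-subject ANOVA (2-level factor x condition)
#'
#' For the experiment x time-period comparison: the same subjects
#' measured on all conditions in both levels of a two-level factor
#' (e.g. the original session and an 8-month follow-up). Main effects and
#' the interaction each get their own Mauchly/Greenhouse-Geisser handling.
#'
#' @param table1,table2 Subject x condition tables for the two factor
#'   levels, same subjects in the same row order.
#' @return Named list of `anova_result`: `factor1` (2-level factor main
#'   effect), `condition`, `interaction`.
#' @export
two_way_rm_anova <- function(table1, table2) {
  table1 <- as.matrix(table1); table2 <- as.matrix(table2)
  if (!all(dim(table1) == dim(table2)))
    stop("subject mismatch: the two tables must have identical dimensions")
  if (anyNA(table1) || anyNA(table2)) stop("missing cells")
  n <- nrow(table1); k <- ncol(table1)
  Y <- cbind(table1, table2)
  colnames(Y) <- paste0("c", seq_len(2 * k))
  idata <- data.frame(cond = factor(rep(seq_len(k), 2)),
                      expt = factor(rep(1:2, each = k)))
  av <- car::Anova(stats::lm(Y ~ 1), idata = idata,
                   idesign = ~expt * cond, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  list(factor1 = extract_rm_effect(s, "expt", 2, n),
       condition = extract_rm_effect(s, "cond", k, n),
       interaction = extract_rm_effect(s, "expt:cond", k, n))
}

#' Bonferroni-corrected paired t tests
#'
#' @param table Subject x condition table.
#' @param pairs Two-column character matrix (or list of 2-vectors) of
#'   condition names to compare.
#' @param m Family size for the correction (default: number of pairs).
#' @param directions Optional named character vector
#'   (`"greater"`/`"less"`), names formatted `"a-b"`, for planned
#'   one-tailed tests of condition a minus condition b; unnamed pairs stay
#'   two-sided. Names not matching a tested pair are an error.
#' @return Data.frame: `a`, `b`, `t`, `df`, `p_raw`, `p_corrected`,
#'   `alternative`.
#' @export
paired_t_bonferroni <- function(table, pairs, m = NULL, directions = NULL) {
  table <- as.matrix(table)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.character(pairs), ncol = 2)
  if (is.null(m)) m <- nrow(pairs)
  keys <- paste(pairs[, 1], pairs[, 2], sep = "-")
  if (!is.null(directions)) {
    bad <- setdiff(names(directions), keys)
    if (length(bad))
      stop("direction supplied for unplanned pair(s): ",
           paste(bad, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    alt <- if (!is.null(directions) && keys[i] %in% names(directions))
      directions[[keys[i]]] else "two.sided"
    d <- table[, a] - table[, b]
    tt <- if (stats::sd(d) == 0 && all(d == 0)) {
      # identical conditions: no evidence either way
      list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
           p.value = 1)
    } else stats::t.test(table[, a], table[, b], paired = TRUE,
                         alternative = alt)
    data.frame(a = a, b = b, t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               p_corrected = min(1, m * tt$p.value),
               alternative = alt, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Within-subject (Cousineau) normalised SEM
#'
#' Each cell is replaced by `cell - subject mean + grand mean`, removing
#' between-subject offsets; per-condition standard errors are computed on
#' the normalised cells. Condition means are unchanged by construction.
#'
#' @param table Subject x condition table (complete).
#' @return List with `mean` (per-condition means), `sem` (normalised
#'   SEMs), `normalized` (the transformed table).
#' @export
cousineau_sem <- function(table) {
  table <- as.matrix(table)
  norm <- table - rowMeans(table) + mean(table)
  list(mean = colMeans(table),
       sem = apply(norm, 2, stats::sd) / sqrt(nrow(table)),
       normalized = norm)
}

#' Intraclass correlation ICC(2,1)
#'
#' Single-measure, absolute-agreement, two-way random-effects ICC, the
#' interrater reliability index for detail scoring:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' from the two-way ANOVA mean squares (MSR rows/targets, MSC columns/
#' raters, MSE residual).
#'
#' @param ratings Targets x raters numeric matrix (complete, >= 3 targets,
#'   >= 2 raters).
#' @return List with `icc`, `msr`, `msc`, `mse`, `n`, `k`.
#' @export
icc_absolute_single <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need >= 3 targets and >= 2 raters")
  if (anyNA(ratings)) stop("ratings must be complete")
  if (stats::sd(as.vector(ratings)) == 0)
    stop("constant ratings: ICC undefined")
  d <- data.frame(y = as.vector(ratings),
                  target = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  # suppressWarnings: perfect agreement gives an exact fit, which anova()
  # flags even though the mean squares are the quantities needed here
  ms <- suppressWarnings(
    stats::anova(stats::aov(y ~ target + rater, data = d)))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k)
}
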