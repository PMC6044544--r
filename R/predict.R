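#' Shift a score profile forwards by two time points
#'
#' Builds the follow-up prediction from a first-experiment score profile:
#' memories aged 0.5-16 months become 8-24 months old 8 months later, so
#' their predicted scores are the first experiment's values at those ages;
#' the new 28- and 32-month ages (from 20- and 24-month origins) have no
#' first-experiment data and are assumed to match the 24-month value; the
#' 60-month memories (68 months at follow-up) are assumed unchanged.
#'
#' @param exp1_scores Named numeric vector of per-time-point group means;
#'   names are the 8 original ages in months
#'   (`"0.5","4","8","12","16","20","24","60"`).
#' @return Data.frame: `original_tp`, `new_age`, `source_tp`, `original`,
#'   `predicted`.
#' @export
shift_profile <- function(exp1_scores) {
  tps <- c(0.5, 4, 8, 12, 16, 20, 24, 60)
  if (!all(as.character(tps) %in% names(exp1_scores)))
    stop("missing time point(s): need scores named ",
         paste(tps, collapse = ", "))
  v <- exp1_scores[as.character(tps)]
  new_age <- c(8, 12, 16, 20, 24, 28, 32, 68)
  source_tp <- c(8, 12, 16, 20, 24, 24, 24, 60)
  data.frame(original_tp = tps, new_age = new_age, source_tp = source_tp,
             original = unname(v),
             predicted = unname(v[as.character(source_tp)]))
}

#' Directional hypotheses from a shifted profile
#'
#' Classifies each original time point as `increase`, `decrease` or
#' `no_change` by the sign of (predicted - original), with differences
#' smaller than `tol` in magnitude treated as no change. The default
#' tolerance, a quarter of the profile's range, mirrors the qualitative
#' by-eye judgement with which such predictions are read off a profile
#' plot; `tol = 0` gives the strict sign rule.
#'
#' @param exp1_scores Named per-time-point score vector (see
#'   [shift_profile()]).
#' @param tol Absolute difference below which the direction is
#'   `no_change`.
#' @return Data.frame: the [shift_profile()] columns plus `direction`
#'   (factor: increase/decrease/no_change).
#' @export
directional_hypotheses <- function(exp1_scores,
                                   tol = 0.25 * diff(range(exp1_scores))) {
  ps <- shift_profile(exp1_scores)
  d <- ps$predicted - ps$original
  ps$direction <- ifelse(abs(d) <= tol, "no_change",
                         ifelse(d > 0, "increase", "decrease"))
  ps
}

#' Evaluate follow-up predictions with planned paired t tests
#'
#' Per original time point, a paired t test of follow-up minus original
#' per-subject scores, one-tailed in the hypothesised direction where one
#' is declared and two-tailed otherwise. A change hypothesis is supported
#' when p < alpha in the predicted direction; a no-change hypothesis when
#' the two-tailed test fails to reject (or, with `tost_bounds`, when a
#' two-one-sided-tests equivalence procedure rejects both bounds).
#'
#' @param exp1,exp2 Subject x time-point score matrices (same subjects,
#'   same row order; columns named by the original ages in months).
#' @param predictions Data.frame from [directional_hypotheses()].
#' @param alpha Significance level (default 0.05).
#' @param tost_bounds Optional symmetric equivalence bound for no-change
#'   hypotheses; `NULL` (default) uses the non-rejection rule.
#' @return Data.frame: `time_point`, `direction`, `t`, `df`, `p`,
#'   `supported`; attribute `summary` = list(n_supported, n_hypotheses).
#' @export
evaluate_predictions <- function(exp1, exp2, predictions, alpha = 0.05,
                                 tost_bounds = NULL) {
  exp1 <- as.matrix(exp1); exp2 <- as.matrix(exp2)
  if (!all(dim(exp1) == dim(exp2)))
    stop("subject mismatch between experiments")
  rows <- lapply(seq_len(nrow(predictions)), function(i) {
    tp <- as.character(predictions$original_tp[i])
    dir <- predictions$direction[i]
    diff <- exp2[, tp] - exp1[, tp]
    alt <- switch(dir, increase = "greater", decrease = "less",
                  no_change = "two.sided")
    # mirror t.test's near-constancy check: a (numerically) constant
    # difference degenerates the t statistic; p follows the sd -> 0 limit
    stderr <- stats::sd(diff) / sqrt(length(diff))
    degenerate <- stderr == 0 ||
      stderr < 10 * .Machine$double.eps * abs(mean(diff))
    c0 <- mean(diff)
    if (abs(c0) < 10 * .Machine$double.eps * max(abs(diff), 1)) c0 <- 0
    tt <- if (degenerate) {
      p_lim <- if (c0 == 0) 1
               else switch(alt,
                           greater = as.numeric(c0 < 0),
                           less = as.numeric(c0 > 0),
                           two.sided = 0)
      list(statistic = c(t = if (c0 == 0) 0 else sign(c0) * Inf),
           parameter = c(df = length(diff) - 1), p.value = p_lim)
    } else stats::t.test(diff, mu = 0, alternative = alt)
    supported <- if (dir == "no_change") {
      if (is.null(tost_bounds)) tt$p.value >= alpha
      else if (degenerate) abs(c0) < tost_bounds
      else {
        p_lo <- stats::t.test(diff, mu = -tost_bounds,
                              alternative = "greater")$p.value
        p_hi <- stats::t.test(diff, mu = tost_bounds,
                              alternative = "less")$p.value
        max(p_lo, p_hi) < alpha
      }
    } else tt$p.value < alpha
    data.frame(time_point = predictions$original_tp[i], direction = dir,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, supported = supported,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(n_supported = sum(out$supported),
                               n_hypotheses = nrow(out))
  out
}
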