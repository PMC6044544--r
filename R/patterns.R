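#' Pattern matrix constructor
#'
#' A trials x voxels matrix of activity estimates with a `flag` attribute
#' recording whether multivariate noise normalisation has been applied.
#'
#' @param x Numeric matrix (trials x voxels).
#' @param flag `"raw"` or `"whitened"`.
#' @return The matrix with class `pattern_matrix`.
#' @export
as_pattern_matrix <- function(x, flag = c("raw", "whitened")) {
  flag <- match.arg(flag)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("pattern matrix must be finite")
  structure(x, flag = flag, class = c("pattern_matrix", class(x)))
}

pattern_flag <- function(x) attr(x, "flag") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical double-gamma haemodynamic response function
#'
#' The conventional two-gamma shape (peak at 6 s, undershoot at 16 s,
#' undershoot ratio 1/6), normalised to unit peak.
#'
#' @param t Time in seconds (vector).
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(h)
}

# Boxcar (onset, duration) convolved with the canonical HRF, sampled at
# scan times. Convolution on a fine grid (dt seconds) then decimated.
hrf_regressor <- function(onset, duration, n_scans, tr, dt = 0.1) {
  t_fine <- seq(0, n_scans * tr, by = dt)
  box <- as.numeric(t_fine >= onset & t_fine < onset + duration)
  h <- canonical_hrf(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(t_fine)] * dt
  scan_t <- (seq_len(n_scans) - 1) * tr
  stats::approx(t_fine, conv, xout = scan_t, rule = 2)$y
}

#' Session timeseries container
#'
#' @param data Scans x voxels numeric matrix.
#' @param tr Repetition time in seconds.
#' @param onsets Per-trial event onsets in seconds.
#' @param durations Per-trial event durations in seconds (recycled).
#' @param nuisance Optional scans x k matrix of nuisance regressors
#'   (e.g. motion parameters).
#' @return An object of class `session_timeseries`.
#' @export
session_timeseries <- function(data, tr, onsets, durations = 12,
                               nuisance = NULL) {
  data <- as.matrix(data)
  durations <- rep_len(durations, length(onsets))
  span <- nrow(data) * tr
  if (any(onsets < 0 | onsets >= span)) stop("onsets outside the scan span")
  if (any(durations <= 0)) stop("durations must be positive")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == nrow(data))
  }
  structure(list(data = data, tr = tr, onsets = onsets,
                 durations = durations, nuisance = nuisance),
            class = "session_timeseries")
}

#' Estimate trial-wise activity patterns from a session timeseries
#'
#' Each trial's recall window (a boxcar over the 12-s recall period by
#' default) is convolved with the canonical HRF. In `lss` mode
#' (least-squares separate) one GLM is fitted per trial, with the target
#' trial's regressor, a single regressor for all other trials, the
#' nuisance set and an intercept; in `lsa` mode (least-squares all) a
#' single GLM carries one regressor per trial. Residuals are always taken
#' from the `lsa` model, whose fit spans all trials.
#'
#' @param ts A `session_timeseries`.
#' @param mode `"lss"` (default) or `"lsa"`.
#' @return A list with `patterns` (trials x voxels `pattern_matrix`, raw)
#'   and `residuals` (scans x voxels matrix from the lsa fit).
#' @export
estimate_trial_patterns <- function(ts, mode = c("lss", "lsa")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ts, "session_timeseries"))
  n_scans <- nrow(ts$data)
  n_trials <- length(ts$onsets)
  X_trials <- vapply(seq_len(n_trials), function(i)
    hrf_regressor(ts$onsets[i], ts$durations[i], n_scans, ts$tr),
    numeric(n_scans))
  nuis <- cbind(intercept = rep(1, n_scans), ts$nuisance)

  fit_check <- function(X, label) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
      stop("rank-deficient design; collinear columns: ",
           paste(bad, collapse = ", "))
    }
    qx
  }

  X_lsa <- cbind(X_trials, nuis)
  colnames(X_lsa) <- c(paste0("trial", seq_len(n_trials)),
                       colnames(nuis))
  qx <- fit_check(X_lsa, "lsa")
  beta_lsa <- qr.coef(qx, ts$data)
  resid <- ts$data - X_lsa %*% beta_lsa

  if (mode == "lsa") {
    patterns <- beta_lsa[seq_len(n_trials), , drop = FALSE]
  } else {
    patterns <- matrix(NA_real_, n_trials, ncol(ts$data))
    for (i in seq_len(n_trials)) {
      others <- if (n_trials > 1) rowSums(X_trials[, -i, drop = FALSE])
      Xi <- cbind(target = X_trials[, i], others = others, nuis)
      qi <- fit_check(Xi, "lss")
      patterns[i, ] <- qr.coef(qi, ts$data)[1, ]
    }
  }
  dimnames(patterns) <- NULL
  list(patterns = as_pattern_matrix(patterns, "raw"), residuals = resid)
}

#' Estimate the noise covariance from GLM residuals
#'
#' Per-session sample covariances are averaged with equal weights, then
#' shrunk toward their diagonal, `(1 - lambda) S + lambda diag(S)`.
#' `shrink = "auto"` selects lambda with the analytic
#' (Ledoit-Wolf/Schafer-Strimmer style) rule for the diagonal target:
#' the ratio of the summed sampling variances of the off-diagonal entries
#' to their summed squares, clipped to [0, 1].
#'
#' @param residuals A matrix or list of per-session scans x voxels matrices.
#' @param shrink `"auto"` or a fixed lambda in [0, 1].
#' @return An object of class `noise_covariance`: list with `sigma`,
#'   `lambda`, `n_sessions`.
#' @export
estimate_noise_covariance <- function(residuals, shrink = "auto") {
  if (is.matrix(residuals)) residuals <- list(residuals)
  v <- ncol(residuals[[1]])
  stopifnot(all(vapply(residuals, ncol, 0L) == v))
  total_rows <- sum(vapply(residuals, nrow, 0L))
  covs <- lapply(residuals, function(r) {
    s <- stats::cov(r)
    if (any(diag(s) <= 0)) stop("degenerate voxel: zero residual variance")
    s
  })
  S <- Reduce(`+`, covs) / length(covs)

  if (identical(shrink, "auto")) {
    # pooled rows, centred per session, for the sampling-variance estimate
    xc <- do.call(rbind, lapply(residuals, scale, center = TRUE,
                                scale = FALSE))
    n <- nrow(xc)
    w_bar <- crossprod(xc) / n
    # var-hat of off-diagonal sample covariances
    var_sum <- 0; sq_sum <- 0
    for (i in seq_len(v - 1)) {
      wij_bar <- w_bar[i, (i + 1):v]
      wij <- xc[, i] * xc[, (i + 1):v, drop = FALSE]
      var_sum <- var_sum +
        sum(colSums((wij - rep(1, n) %o% wij_bar)^2)) * n / (n - 1)^3
      sq_sum <- sq_sum + sum((S[i, (i + 1):v])^2)
    }
    lambda <- if (sq_sum > 0) min(1, max(0, var_sum / sq_sum)) else 1
    if (total_rows <= v / 10) lambda <- max(lambda, 0.9)
  } else {
    lambda <- as.numeric(shrink)
    stopifnot(lambda >= 0, lambda <= 1)
  }
  sigma <- (1 - lambda) * S + lambda * diag(diag(S), v)
  structure(list(sigma = sigma, lambda = lambda,
                 n_sessions = length(residuals)),
            class = "noise_covariance")
}

# Symmetric inverse square root with an eigenvalue floor.
inv_sqrt_sym <- function(sigma, eps_rel = 1e-10) {
  e <- eigen(sigma, symmetric = TRUE)
  vals <- pmax(e$values, eps_rel * max(e$values))
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

#' Apply multivariate noise normalisation to a pattern matrix
#'
#' Right-multiplies every trial pattern by the symmetric inverse square
#' root of the noise covariance, down-weighting noisier voxels and
#' decorrelating the noise.
#'
#' @param p A raw `pattern_matrix`.
#' @param cov A `noise_covariance` matching the voxel count.
#' @return A `pattern_matrix` flagged `"whitened"`.
#' @export
whiten_patterns <- function(p, cov) {
  stopifnot(inherits(p, "pattern_matrix"), inherits(cov, "noise_covariance"))
  if (pattern_flag(p) == "whitened")
    stop("patterns are already whitened (double-whitening guard)")
  if (ncol(p) != ncol(cov$sigma))
    stop("covariance dimension does not match voxel count")
  as_pattern_matrix(unclass(p) %*% inv_sqrt_sym(cov$sigma), "whitened")
}
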