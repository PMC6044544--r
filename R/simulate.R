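#' Ground-truth consolidation profile for simulation
#'
#' The per-time-point signal amplitude encodes the hypothesised
#' time course of memory-representation strength (arbitrary units);
#' a shared retrieval component common to all trials and a spatially
#' correlated noise process complete the generative model.
#'
#' Defaults: the nonmonotonic amplitude shape used for recovery tests
#' (undetectable at 0.5 months, rising to 12 months, dipping at 16-20
#' months, strong again at 24-60 months), a modest shared retrieval
#' component, and noise with a 2-voxel correlation length.
#'
#' @param amplitude Nonnegative amplitude per time point.
#' @param shared_component_weight Weight of the common retrieval vector
#'   added to every trial regardless of memory identity.
#' @param noise_sd Marginal standard deviation of the voxel noise.
#' @param spatial_corr_length Gaussian correlation length of the noise in
#'   voxel units (0 = independent voxels).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(amplitude = c(0, .6, .7, .9, .3, .1, 1.0, .9),
                         shared_component_weight = 0.2,
                         noise_sd = 0.1,
                         spatial_corr_length = 2) {
  if (!all(is.finite(amplitude)) || any(amplitude < 0))
    stop("amplitudes must be finite and nonnegative")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be positive")
  structure(list(amplitude = amplitude,
                 shared_component_weight = shared_component_weight,
                 noise_sd = noise_sd,
                 spatial_corr_length = spatial_corr_length),
            class = "ground_truth")
}

# Row-normalised Gaussian smoothing operator over voxel geometry.
# Rows have unit L2 norm so smoothed white noise keeps its marginal SD.
smoothing_operator <- function(n_voxels, corr_length, dims = NULL) {
  if (corr_length <= 0) return(NULL)
  if (is.null(dims)) {
    d <- abs(outer(seq_len(n_voxels), seq_len(n_voxels), "-"))
  } else {
    stopifnot(prod(dims) == n_voxels)
    ijk <- arrayInd(seq_len(n_voxels), .dim = dims)
    d <- as.matrix(stats::dist(ijk))
  }
  k <- exp(-d^2 / (2 * corr_length^2))
  k / sqrt(rowSums(k^2))
}

# trials x voxels noise with marginal sd: an equal-power mixture of a
# spatially smooth component and white (thermal) noise, so the covariance
# stays well conditioned and the whitening stage has structure to exploit.
correlated_noise <- function(n_rows, n_voxels, sd, K = NULL) {
  n <- matrix(stats::rnorm(n_rows * n_voxels, sd = sd), n_rows, n_voxels)
  if (is.null(K)) return(n)
  w <- matrix(stats::rnorm(n_rows * n_voxels, sd = sd), n_rows, n_voxels)
  sqrt(0.5) * n %*% t(K) + sqrt(0.5) * w
}

#' Simulate one subject of the longitudinal recall experiment
#'
#' Each trial pattern is
#' `amplitude(time_point) * memory_signature + w * common + noise`:
#' memory signatures are drawn once per memory and unit-normalised, the
#' common retrieval vector is shared by all trials, and the noise is
#' Gaussian with optional spatial correlation. Per-session residual
#' matrices are drawn from the same noise process (for the noise-covariance
#' stage), and per-trial vividness ratings are drawn with high mass on 4-5.
#'
#' @param spec A `design_spec`.
#' @param truth A `ground_truth` whose `amplitude` has one entry per
#'   time point of `spec`.
#' @param n_voxels Number of voxels (>= 8).
#' @param seed Integer seed; output is bit-identical for equal seeds.
#' @param dims Optional 3-element integer vector; when given, voxels are
#'   arranged on a 3-D grid (`prod(dims) == n_voxels`) and the noise is
#'   smoothed in 3-D, for searchlight simulations.
#' @param schedule Optional precomputed schedule (defaults to
#'   `build_schedule(spec, seed)`).
#' @param signal_voxels Optional index vector restricting memory signatures
#'   to a sub-region (signal zero elsewhere); noise still covers all voxels.
#' @param n_resid_scans Residual rows per session
#'   (default `ceiling(n_voxels / 2) + 10`).
#' @return An object of class `synthetic_subject`: list with `schedule`
#'   (including `vividness`), `patterns` (trials x voxels), `residuals`
#'   (list of per-session matrices), `truth`, `signatures`, `common`,
#'   `dims`, `spec`.
#' @export
simulate_subject <- function(spec, truth = ground_truth(), n_voxels = 100,
                             seed = 1, dims = NULL, schedule = NULL,
                             signal_voxels = NULL, n_resid_scans = NULL) {
  stopifnot(inherits(spec, "design_spec"), inherits(truth, "ground_truth"))
  if (n_voxels < 8) stop("n_voxels must be >= 8")
  if (length(truth$amplitude) != length(spec$time_points))
    stop("truth$amplitude must have one entry per time point")
  if (is.null(schedule)) schedule <- build_schedule(spec, seed = seed)
  if (is.null(n_resid_scans)) n_resid_scans <- ceiling(n_voxels / 2) + 10
  set.seed(as.integer(seed))

  mem <- memory_table(spec)
  sig <- matrix(stats::rnorm(nrow(mem) * n_voxels), nrow(mem), n_voxels,
                dimnames = list(mem$memory_id, NULL))
  if (!is.null(signal_voxels)) {
    keep <- logical(n_voxels); keep[signal_voxels] <- TRUE
    sig[, !keep] <- 0
  }
  sig <- sig / sqrt(rowSums(sig^2))
  common <- stats::rnorm(n_voxels)
  common <- common / sqrt(sum(common^2))

  K <- smoothing_operator(n_voxels, truth$spatial_corr_length, dims)
  amp <- truth$amplitude[match(schedule$time_point_months, spec$time_points)]
  patterns <- sig[schedule$memory_id, , drop = FALSE] * amp +
    rep(1, nrow(schedule)) %o% (truth$shared_component_weight * common) +
    correlated_noise(nrow(schedule), n_voxels, truth$noise_sd, K)
  rownames(patterns) <- NULL

  residuals <- lapply(seq_len(spec$n_sessions), function(s)
    correlated_noise(n_resid_scans, n_voxels, truth$noise_sd, K))

  schedule$vividness <- sample(1:5, nrow(schedule), replace = TRUE,
                               prob = c(.01, .03, .06, .35, .55))

  structure(list(schedule = schedule,
                 patterns = as_pattern_matrix(patterns, flag = "raw"),
                 residuals = residuals, truth = truth,
                 signatures = sig, common = common, dims = dims,
                 spec = spec),
            class = "synthetic_subject")
}

#' Simulate the 8-month follow-up acquisition of the same subject
#'
#' Reuses the first experiment's memory signatures and common retrieval
#' vector (the memories are the same, now 8 months older), draws a new
#' schedule, new noise and new vividness ratings, and scales signals by
#' the follow-up amplitude profile `truth2`. The schedule keeps the
#' original time-point labels so scores align across experiments; the
#' current age is recorded in `age_months`.
#'
#' @param subject A `synthetic_subject` from [simulate_subject()].
#' @param truth2 A `ground_truth` with the follow-up amplitudes (one per
#'   original time point).
#' @param seed Integer seed.
#' @return A `synthetic_subject` for the follow-up session set.
#' @export
simulate_followup <- function(subject, truth2, seed) {
  stopifnot(inherits(subject, "synthetic_subject"),
            inherits(truth2, "ground_truth"))
  spec <- subject$spec
  if (length(truth2$amplitude) != length(spec$time_points))
    stop("mismatched memory sets: truth2 amplitude length != number of time points")
  set.seed(as.integer(seed))
  schedule <- build_schedule(spec, seed = seed)
  set.seed(as.integer(seed) + 1L)  # schedule consumed the stream; fresh draw
  n_voxels <- ncol(subject$patterns)
  K <- smoothing_operator(n_voxels, truth2$spatial_corr_length, subject$dims)
  amp <- truth2$amplitude[match(schedule$time_point_months, spec$time_points)]
  patterns <- subject$signatures[schedule$memory_id, , drop = FALSE] * amp +
    rep(1, nrow(schedule)) %o%
      (truth2$shared_component_weight * subject$common) +
    correlated_noise(nrow(schedule), n_voxels, truth2$noise_sd, K)
  rownames(patterns) <- NULL
  n_resid <- nrow(subject$residuals[[1]])
  residuals <- lapply(seq_len(spec$n_sessions), function(s)
    correlated_noise(n_resid, n_voxels, truth2$noise_sd, K))
  schedule$vividness <- sample(1:5, nrow(schedule), replace = TRUE,
                               prob = c(.01, .03, .06, .35, .55))
  schedule$age_months <- schedule$time_point_months + 8
  structure(list(schedule = schedule,
                 patterns = as_pattern_matrix(patterns, flag = "raw"),
                 residuals = residuals, truth = truth2,
                 signatures = subject$signatures, common = subject$common,
                 dims = subject$dims, spec = spec),
            class = "synthetic_subject")
}

#' Simulate behavioural ratings tables and an interrater detail table
#'
#' Produces subject x time-point tables for the five phenomenology scales
#' (vividness, detail, effort, personal significance, emotional valence;
#' all 1-5) and a two-rater detail-count table for interrater reliability
#' testing.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed.
#' @param n_conditions Number of time points (default 8).
#' @param covariance `"compound"` for compound-symmetric condition
#'   covariance (subject random intercept + iid noise, so the sphericity
#'   assumption holds and Greenhouse-Geisser epsilon is ~1) or
#'   `"heterogeneous"` for unequal condition variances.
#' @param rater2 `"noisy"` (default) adds rater disagreement to the second
#'   rater's detail counts; `"identical"` copies rater 1.
#' @return A list with `ratings` (named list of subject x condition
#'   matrices) and `detail_raters` (targets x 2 matrix of counts).
#' @export
simulate_ratings_tables <- function(n_subjects, seed, n_conditions = 8,
                                    covariance = c("compound", "heterogeneous"),
                                    rater2 = c("noisy", "identical")) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  covariance <- match.arg(covariance)
  rater2 <- match.arg(rater2)
  set.seed(as.integer(seed))
  scales <- c("vividness", "detail", "effort", "significance", "valence")
  make_table <- function() {
    subj <- stats::rnorm(n_subjects, sd = 0.4)
    cond <- stats::rnorm(n_conditions, sd = 0.2)
    eps_sd <- if (covariance == "compound") rep(0.3, n_conditions)
              else stats::runif(n_conditions, 0.1, 0.8)
    y <- outer(subj, cond, "+") + 4 +
      matrix(stats::rnorm(n_subjects * n_conditions), n_subjects) *
        rep(eps_sd, each = n_subjects)
    pmin(pmax(y, 1), 5)
  }
  ratings <- stats::setNames(lapply(scales, function(s) make_table()), scales)
  n_targets <- 16
  r1 <- stats::rpois(n_targets, lambda = 25)
  r2 <- if (rater2 == "identical") r1
        else pmax(0, r1 + stats::rpois(n_targets, 2) - 2 +
                    round(stats::rnorm(n_targets, sd = 2)))
  list(ratings = ratings,
       detail_raters = cbind(rater1 = r1, rater2 = r2))
}
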