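#' Write / read a trial table as TSV
#'
#' @param trials Trial table data.frame.
#' @param path Output path.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @return `read_trial_table`: the trial table data.frame.
#' @export
read_trial_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a pattern set as a 4-D NIfTI volume inside an ROI mask
#'
#' Frame t holds trial t's pattern scattered into the mask; voxels outside
#' the mask are zero. In-mask voxel order is ascending linear index
#' (0-based, x-fastest), the package-wide convention.
#'
#' @param p Pattern matrix (trials x in-mask voxels).
#' @param roi_mask 3-D mask array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @export
write_pattern_nifti <- function(p, roi_mask, path) {
  dims <- dim(roi_mask)
  roi_lin <- which(roi_mask != 0)
  stopifnot(ncol(p) == length(roi_lin))
  vol <- array(0, c(dims, nrow(p)))
  frame_len <- prod(dims)
  for (t in seq_len(nrow(p)))
    vol[roi_lin + (t - 1) * frame_len] <- p[t, ]
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' Read a pattern set from a 4-D NIfTI volume
#'
#' @param path NIfTI path.
#' @param roi_mask 3-D mask whose grid must match the volume's first three
#'   dimensions.
#' @param n_trials Optional expected trial count (e.g. from the trial
#'   table); a mismatch is an error naming the dimensions.
#' @return A raw `pattern_matrix` (trials x in-mask voxels, ascending
#'   linear-index order).
#' @export
read_pattern_set <- function(path, roi_mask, n_trials = NULL) {
  vol <- RNifti::readNifti(path)
  vol <- array(as.numeric(vol), dim = dim(vol))
  dims <- dim(vol)
  if (length(dims) == 3) dims <- c(dims, 1L)
  if (!all(dims[1:3] == dim(roi_mask)))
    stop(sprintf("grid mismatch: volume %s vs mask %s",
                 paste(dims[1:3], collapse = "x"),
                 paste(dim(roi_mask), collapse = "x")))
  roi_lin <- which(roi_mask != 0)
  if (!length(roi_lin)) stop("mask has no in-mask voxels")
  if (!is.null(n_trials) && dims[4] != n_trials)
    stop(sprintf("trial-count mismatch: %d frames vs %d trial rows",
                 dims[4], n_trials))
  frame_len <- prod(dims[1:3])
  p <- vapply(seq_len(dims[4]),
              function(t) vol[roi_lin + (t - 1) * frame_len],
              numeric(length(roi_lin)))
  as_pattern_matrix(t(p), "raw")
}

#' Write tidy score tables as TSV
#'
#' One row per subject x time point (x set where present), the exchange
#' format for downstream group statistics.
#'
#' @param scores Subjects x time-points matrix (columns named by age in
#'   months) or a long data.frame.
#' @param path Output path.
#' @param variant Baseline variant label recorded in the file.
#' @export
write_scores_tsv <- function(scores, path, variant = "all-other") {
  if (is.matrix(scores)) {
    long <- data.frame(
      subject = rep(seq_len(nrow(scores)), times = ncol(scores)),
      time_point_months = rep(colnames(scores), each = nrow(scores)),
      variant = variant, score = as.vector(scores))
  } else long <- scores
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tidy score TSV back into a subjects x time-points matrix
#'
#' @param path TSV written by [write_scores_tsv()].
#' @return Matrix with subjects in rows, time points in columns.
#' @export
read_scores_tsv <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  tps <- unique(long$time_point_months)
  subs <- sort(unique(long$subject))
  m <- matrix(NA_real_, length(subs), length(tps),
              dimnames = list(subs, tps))
  m[cbind(match(long$subject, subs),
          match(long$time_point_months, tps))] <- long$score
  m
}

#' Score one subject end to end
#'
#' Vividness filtering, optional multivariate noise normalisation from the
#' subject's session residuals, then per-time-point neural representation
#' scores.
#'
#' @param subject A `synthetic_subject` (or any list with `schedule`,
#'   `patterns`, `residuals`).
#' @param variant Baseline variant.
#' @param vividness_min Vividness threshold (default 3).
#' @param whiten Apply noise normalisation (default TRUE).
#' @param shrink Shrinkage for the noise covariance (default `"auto"`).
#' @return The [timepoint_scores()] data.frame.
#' @export
score_subject <- function(subject, variant = "all-other",
                          vividness_min = 3, whiten = TRUE,
                          shrink = "auto") {
  trials <- filter_vivid_trials(subject$schedule, vividness_min)
  p <- subject$patterns
  if (whiten) {
    cov <- estimate_noise_covariance(subject$residuals, shrink)
    p <- whiten_patterns(p, cov)
  }
  p <- p[trials$trial, , drop = FALSE]
  timepoint_scores(as_pattern_matrix(p, if (whiten) "whitened" else "raw"),
                   trials, variant)
}

#' Score a cohort of subjects
#'
#' @param subjects List of `synthetic_subject`s.
#' @param ... Passed to [score_subject()].
#' @return List with `scores` (subjects x time-points matrix), `per_set`
#'   (list of per-set matrices), `tables` (per-subject data.frames).
#' @export
cohort_scores <- function(subjects, ...) {
  tabs <- lapply(subjects, score_subject, ...)
  tps <- tabs[[1]]$time_point_months
  scores <- do.call(rbind, lapply(tabs, `[[`, "score"))
  colnames(scores) <- tps
  set_cols <- grep("^score_", names(tabs[[1]]), value = TRUE)
  per_set <- lapply(stats::setNames(set_cols, set_cols), function(cn) {
    m <- do.call(rbind, lapply(tabs, `[[`, cn)); colnames(m) <- tps; m
  })
  list(scores = scores, per_set = per_set, tables = tabs)
}

#' Run the full experiment pipeline on a configuration
#'
#' Composes the stages — simulate (or accept supplied subjects), filter,
#' whiten, score, group statistics, and, when a follow-up experiment is
#' present, the two-way ANOVA and the prediction-shift evaluation. All
#' randomness derives from `config$seed`, so output is deterministic.
#'
#' @param config List with `n_subjects`, `seed`, and optionally `truth`,
#'   `truth2` (enables the follow-up arm, simulated for
#'   `n_followup` subjects, default all), `n_voxels`, `variant`,
#'   `vividness_min`, `whiten`, `out_dir` (write TSV outputs there).
#' @return List with `scores1` (+ `scores2` when a follow-up is run),
#'   `detectability` (per-time-point one-sample t), `anova`, and, for
#'   two-experiment runs, `two_way`, `predictions`.
#' @export
run_experiment_pipeline <- function(config) {
  # [[-access throughout: $ would partially match (e.g. config$truth
  # finding truth2 when truth is absent)
  stopifnot(is.numeric(config[["seed"]]), !is.null(config[["n_subjects"]]))
  spec <- config[["spec"]] %||% design_spec()
  truth <- config[["truth"]] %||% ground_truth()
  n_vox <- config[["n_voxels"]] %||% 100
  variant <- config[["variant"]] %||% "all-other"
  viv_min <- config[["vividness_min"]] %||% 3
  whiten <- config[["whiten"]] %||% TRUE
  base_seed <- as.integer(config[["seed"]])

  subjects <- config[["subjects"]] %||% lapply(seq_len(config[["n_subjects"]]),
    function(i) simulate_subject(spec, truth, n_vox,
                                 seed = base_seed + i))
  cs1 <- cohort_scores(subjects, variant = variant,
                       vividness_min = viv_min, whiten = whiten)
  detect <- lapply(seq_len(ncol(cs1$scores)), function(j)
    one_sample_t(cs1$scores[, j]))
  names(detect) <- colnames(cs1$scores)
  res <- list(scores1 = cs1$scores,
              detectability = detect,
              anova = rm_anova(cs1$scores))

  if (!is.null(config[["truth2"]])) {
    n_fu <- config[["n_followup"]] %||% length(subjects)
    fu <- lapply(seq_len(n_fu), function(i)
      simulate_followup(subjects[[i]], config[["truth2"]],
                        seed = base_seed + 10000L + i))
    cs2 <- cohort_scores(fu, variant = variant,
                         vividness_min = viv_min, whiten = whiten)
    e1 <- cs1$scores[seq_len(n_fu), , drop = FALSE]
    preds <- directional_hypotheses(colMeans(e1))
    res$scores2 <- cs2$scores
    res$two_way <- two_way_rm_anova(e1, cs2$scores)
    res$predictions <- evaluate_predictions(e1, cs2$scores, preds)
  }

  if (!is.null(config[["out_dir"]])) {
    dir.create(config[["out_dir"]], showWarnings = FALSE, recursive = TRUE)
    write_scores_tsv(res$scores1,
                     file.path(config[["out_dir"]], "scores_exp1.tsv"), variant)
    if (!is.null(res$scores2))
      write_scores_tsv(res$scores2,
                       file.path(config[["out_dir"]], "scores_exp2.tsv"),
                       variant)
  }
  res
}
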