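#' Exclude the least vivid trials
#'
#' Removes trials rated below `threshold` on the 1-5 in-scanner vividness
#' scale. A memory stays scorable only if it retains at least 2 trials in
#' at least 2 distinct sessions (cross-session similarity needs a
#' cross-session pair); memories failing this are flagged, never silently
#' dropped.
#'
#' @param trials Trial table with `memory_id`, `session`, `vividness`.
#' @param threshold Minimum vividness retained (default 3, i.e. ratings
#'   1-2 excluded).
#' @return The filtered trial table, with attribute `unscorable`: character
#'   vector of memory ids that can no longer be scored.
#' @export
filter_vivid_trials <- function(trials, threshold = 3) {
  stopifnot(all(trials$vividness %in% 1:5))
  kept <- trials[trials$vividness >= threshold, , drop = FALSE]
  mems <- unique(trials$memory_id)
  unscorable <- vapply(mems, function(m) {
    rows <- kept[kept$memory_id == m, , drop = FALSE]
    nrow(rows) < 2 || length(unique(rows$session)) < 2
  }, logical(1))
  attr(kept, "unscorable") <- mems[unscorable]
  # the design-level memory list survives filtering, so downstream
  # per-time-point summaries can flag memories lost entirely
  attr(kept, "memory_info") <-
    unique(trials[, intersect(c("memory_id", "set", "time_point_months"),
                              names(trials)), drop = FALSE])
  kept
}

scorable_memories <- function(trials) {
  setdiff(unique(trials$memory_id), attr(trials, "unscorable"))
}

# Trial x trial Pearson correlations; errors on zero-variance trials.
trial_correlations <- function(p) {
  if (any(apply(p, 1, stats::sd) == 0))
    stop("zero-variance trial pattern: correlation undefined")
  stats::cor(t(unclass(p)))
}

# Mean correlation over eligible (cross-session) trial pairs for a memory
# pair, from a precomputed trial correlation matrix.
pair_similarity <- function(C, trials, mem_a, mem_b) {
  ia <- which(trials$memory_id == mem_a)
  ib <- which(trials$memory_id == mem_b)
  if (mem_a == mem_b) {
    pr <- t(utils::combn(ia, 2))
  } else {
    pr <- as.matrix(expand.grid(ia, ib))
  }
  ok <- trials$session[pr[, 1]] != trials$session[pr[, 2]]
  if (!any(ok))
    stop(sprintf("no cross-session trial pairs between %s and %s",
                 mem_a, mem_b))
  mean(C[pr[ok, , drop = FALSE]])
}

#' Mean cross-session pattern similarity between two memories
#'
#' The Pearson correlation of every eligible trial pair (one trial from
#' each memory, sessions differing) averaged without Fisher transform.
#' With `mem_a == mem_b` this is the within-memory similarity over
#' unordered distinct trial pairs.
#'
#' @param p Pattern matrix (rows matching `trials`).
#' @param trials Trial table.
#' @param mem_a,mem_b Memory ids.
#' @return Mean correlation (scalar).
#' @export
cross_session_similarity <- function(p, trials, mem_a, mem_b) {
  stopifnot(nrow(p) == nrow(trials))
  pair_similarity(trial_correlations(p), trials, mem_a, mem_b)
}

#' Memory-by-memory representational similarity matrix
#'
#' Symmetric matrix of mean cross-session similarities; the diagonal holds
#' within-memory values (not forced to 1).
#'
#' @param p Pattern matrix.
#' @param trials Trial table (filtered; unscorable memories are skipped
#'   and returned as NA rows/columns).
#' @param memories Memory ids to include (default: all scorable).
#' @return A `memory_rsm`: square matrix with `labels` attribute
#'   (data.frame memory_id, set, time_point_months).
#' @export
memory_rsm <- function(p, trials, memories = NULL) {
  if (is.null(memories)) memories <- scorable_memories(trials)
  C <- trial_correlations(p)
  n <- length(memories)
  out <- matrix(NA_real_, n, n, dimnames = list(memories, memories))
  for (i in seq_len(n)) for (j in i:n) {
    out[i, j] <- out[j, i] <-
      pair_similarity(C, trials, memories[i], memories[j])
  }
  lab <- unique(trials[trials$memory_id %in% memories,
                       c("memory_id", "set", "time_point_months")])
  lab <- lab[match(memories, lab$memory_id), ]
  structure(out, labels = lab, class = c("memory_rsm", "matrix"))
}

#' Neural representation score of one memory
#'
#' Within-memory cross-session similarity minus a between-memory baseline.
#' With the `all-other` variant the baseline is the mean similarity to the
#' other memories of the same set (the two 8-memory sets are analysed
#' separately); with `matched-age` it is the similarity to the single
#' identically aged memory of the other set.
#'
#' @param p Pattern matrix.
#' @param trials Filtered trial table.
#' @param memory Memory id.
#' @param variant `"all-other"` (default) or `"matched-age"`.
#' @return Score (scalar, correlation difference).
#' @export
neural_representation_score <- function(p, trials, memory,
                                        variant = c("all-other",
                                                    "matched-age")) {
  variant <- match.arg(variant)
  scor <- scorable_memories(trials)
  if (!memory %in% scor) stop("memory ", memory, " is not scorable")
  C <- trial_correlations(p)
  score_from_C(C, trials, memory, variant, scor)
}

score_from_C <- function(C, trials, memory, variant, scor) {
  info <- trials[trials$memory_id == memory, ][1, ]
  within <- pair_similarity(C, trials, memory, memory)
  if (variant == "all-other") {
    others <- scor[scor != memory &
                   trials$set[match(scor, trials$memory_id)] == info$set]
    if (length(others) == 0) stop("no same-set baseline memories for ", memory)
    between <- mean(vapply(others, function(m)
      pair_similarity(C, trials, memory, m), numeric(1)))
  } else {
    mate <- unique(trials$memory_id[
      trials$time_point_months == info$time_point_months &
      trials$set != info$set])
    mate <- intersect(mate, scor)
    if (length(mate) != 1)
      stop("no scorable identically aged counterpart for ", memory)
    between <- pair_similarity(C, trials, memory, mate)
  }
  within - between
}

#' Per-time-point neural representation scores for one subject
#'
#' Scores every scorable memory and averages the (up to
#' `memories_per_timepoint`) scores at each time point; per-set sub-scores
#' are retained for set-wise replication plots.
#'
#' @param p Pattern matrix.
#' @param trials Filtered trial table.
#' @param variant Baseline variant, see [neural_representation_score()].
#' @return A data.frame (one row per time point): `time_point_months`,
#'   `score`, per-set columns (`score_A`, `score_B`, ...), `n_memories`,
#'   `flag` (TRUE when a time point lost one or all memories).
#' @export
timepoint_scores <- function(p, trials, variant = c("all-other",
                                                    "matched-age")) {
  variant <- match.arg(variant)
  scor <- scorable_memories(trials)
  if (length(scor) == 0) stop("no scorable memories")
  C <- trial_correlations(p)
  mem_info <- attr(trials, "memory_info") %||%
    unique(trials[, c("memory_id", "set", "time_point_months")])
  tps <- sort(unique(mem_info$time_point_months))
  sets <- sort(unique(mem_info$set))
  per_mem <- stats::setNames(rep(NA_real_, nrow(mem_info)),
                             mem_info$memory_id)
  # a memory whose baseline set is empty after filtering is itself
  # unscorable here, not an error: the time point keeps its other memory
  for (m in scor)
    per_mem[m] <- tryCatch(score_from_C(C, trials, m, variant, scor),
                           error = function(e) NA_real_)
  out <- data.frame(time_point_months = tps)
  set_cols <- matrix(NA_real_, length(tps), length(sets),
                     dimnames = list(NULL, paste0("score_", sets)))
  out$score <- NA_real_; out$n_memories <- 0L; out$flag <- FALSE
  for (i in seq_along(tps)) {
    ids <- mem_info$memory_id[mem_info$time_point_months == tps[i]]
    vals <- per_mem[ids]
    for (s in seq_along(sets)) {
      id_s <- ids[mem_info$set[match(ids, mem_info$memory_id)] == sets[s]]
      if (length(id_s)) set_cols[i, s] <- per_mem[id_s]
    }
    out$n_memories[i] <- sum(!is.na(vals))
    out$flag[i] <- out$n_memories[i] < length(ids)
    out$score[i] <- if (out$n_memories[i] > 0) mean(vals, na.rm = TRUE)
                    else NA_real_
  }
  cbind(out, set_cols)
}

#' Group-average RSM, optionally rank-transformed for display
#'
#' Element-wise mean of identically labelled subject RSMs; for display the
#' values are replaced by their ranks (ties averaged) rescaled linearly to
#' [0, 1].
#'
#' @param rsms List of `memory_rsm` with identical labelling.
#' @param display Rank-transform and rescale for plotting.
#' @return A `memory_rsm`.
#' @export
group_rsm <- function(rsms, display = FALSE) {
  lab0 <- rownames(rsms[[1]])
  for (r in rsms) if (!identical(rownames(r), lab0))
    stop("label mismatch across subject RSMs")
  m <- Reduce(`+`, lapply(rsms, unclass)) / length(rsms)
  if (display) {
    v <- m[lower.tri(m, diag = TRUE)]
    rk <- rank(v, ties.method = "average")
    if (max(rk) > min(rk)) rk <- (rk - min(rk)) / (max(rk) - min(rk))
    else rk <- rep(0, length(rk))
    m[lower.tri(m, diag = TRUE)] <- rk
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
  }
  structure(m, labels = attr(rsms[[1]], "labels"),
            class = c("memory_rsm", "matrix"))
}

#' Per-time-point mean between-memory similarity
#'
#' For each subject and time point, the mean of that time point's
#' memories' same-set between-memory baselines (off-diagonal RSM entries),
#' the quantity whose stability across time points shows the score profile
#' is driven by within- rather than between-memory similarity.
#'
#' @param rsms List of subject `memory_rsm`s (identical labelling).
#' @return A subjects x time-points matrix of mean between-memory r.
#' @export
between_memory_profile <- function(rsms) {
  lab <- attr(rsms[[1]], "labels")
  tps <- sort(unique(lab$time_point_months))
  out <- matrix(NA_real_, length(rsms), length(tps),
                dimnames = list(NULL, tps))
  for (s in seq_along(rsms)) {
    r <- unclass(rsms[[s]])
    if (!identical(rownames(r), rownames(rsms[[1]])))
      stop("label mismatch across subject RSMs")
    for (i in seq_along(tps)) {
      ids <- lab$memory_id[lab$time_point_months == tps[i]]
      vals <- vapply(ids, function(m) {
        same_set <- lab$memory_id[lab$set == lab$set[lab$memory_id == m] &
                                  lab$memory_id != m]
        mean(r[m, same_set])
      }, numeric(1))
      out[s, i] <- mean(vals)
    }
  }
  out
}
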