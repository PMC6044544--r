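#' Experimental design specification
#'
#' Describes the longitudinal recall design: memories of several ages
#' (in months), a fixed number of memories per age, and a session/trial
#' grid over which each memory is recalled repeatedly.
#'
#' The default reproduces the study design this package emulates:
#' 16 memories = 2 sets x 8 time points (0.5, 4, 8, 12, 16, 20, 24, 60
#' months), each recalled 6 times across 12 scanning sessions of 8 trials.
#'
#' @param time_points Ordered numeric vector of memory ages in months.
#' @param memories_per_timepoint Number of memories sampled at each age.
#' @param repetitions Number of recall trials per memory.
#' @param n_sessions Number of scanning sessions.
#' @param trials_per_session Number of trials in each session.
#' @return An object of class `design_spec`.
#' @examples
#' spec <- design_spec()
#' spec$n_sessions * spec$trials_per_session  # 96 trials
#' @export
design_spec <- function(time_points = c(0.5, 4, 8, 12, 16, 20, 24, 60),
                        memories_per_timepoint = 2L,
                        repetitions = 6L,
                        n_sessions = 12L,
                        trials_per_session = 8L) {
  stopifnot(length(time_points) >= 1, !is.unsorted(time_points),
            memories_per_timepoint >= 1)
  n_mem <- memories_per_timepoint * length(time_points)
  if (repetitions * n_mem != n_sessions * trials_per_session) {
    stop(sprintf(
      "infeasible design: repetitions x memories (%d x %d = %d) must equal n_sessions x trials_per_session (%d x %d = %d)",
      repetitions, n_mem, repetitions * n_mem,
      n_sessions, trials_per_session, n_sessions * trials_per_session))
  }
  structure(list(time_points = time_points,
                 memories_per_timepoint = as.integer(memories_per_timepoint),
                 repetitions = as.integer(repetitions),
                 n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session)),
            class = "design_spec")
}

#' Memory labels for a design
#'
#' One row per memory: id, set label (A, B, ...) and age in months.
#' Memories at the same age are assigned to different sets, so the
#' set-restricted RSA baselines are well defined.
#'
#' @param spec A `design_spec`.
#' @return A data.frame with columns `memory_id`, `set`, `time_point_months`.
#' @export
memory_table <- function(spec) {
  sets <- LETTERS[seq_len(spec$memories_per_timepoint)]
  data.frame(
    memory_id = paste0(rep(sets, each = length(spec$time_points)),
                       rep(seq_along(spec$time_points), times = length(sets))),
    set = rep(sets, each = length(spec$time_points)),
    time_point_months = rep(spec$time_points, times = length(sets)),
    stringsAsFactors = FALSE)
}

#' Build a session schedule
#'
#' Allocates recall trials to sessions under the design constraints:
#' each memory occurs exactly `repetitions` times, never twice in one
#' session, and the memories sharing a time point never occur in the same
#' session. Sessions are single-set (set A sessions alternate with set B
#' sessions and so on), the simplest layout satisfying both co-occurrence
#' constraints; each session then contains each of its set's memories once,
#' which requires `trials_per_session == length(time_points)` and
#' `n_sessions == memories_per_timepoint * repetitions`.
#' Within-session trial order is a seeded random permutation.
#'
#' @param spec A `design_spec`.
#' @param seed Integer seed; schedules are bit-identical for equal seeds.
#' @return A data.frame of class `session_schedule` with columns
#'   `trial`, `session`, `memory_id`, `time_point_months`, `set`, `order`.
#' @examples
#' sch <- build_schedule(design_spec(), seed = 1)
#' nrow(sch)                    # 96
#' table(sch$memory_id)         # each memory 6 times
#' @export
build_schedule <- function(spec, seed) {
  stopifnot(inherits(spec, "design_spec"))
  k <- length(spec$time_points)
  if (spec$trials_per_session != k) {
    stop(sprintf(
      "infeasible schedule layout: trials_per_session (%d) must equal the number of time points (%d) for single-set sessions",
      spec$trials_per_session, k))
  }
  if (spec$n_sessions != spec$memories_per_timepoint * spec$repetitions) {
    stop(sprintf(
      "infeasible schedule layout: n_sessions (%d) must equal memories_per_timepoint x repetitions (%d x %d = %d)",
      spec$n_sessions, spec$memories_per_timepoint, spec$repetitions,
      spec$memories_per_timepoint * spec$repetitions))
  }
  mem <- memory_table(spec)
  sets <- unique(mem$set)
  set.seed(as.integer(seed))
  rows <- vector("list", spec$n_sessions)
  for (s in seq_len(spec$n_sessions)) {
    ses_set <- sets[((s - 1L) %% length(sets)) + 1L]
    ses_mem <- mem[mem$set == ses_set, , drop = FALSE]
    ord <- sample.int(nrow(ses_mem))
    rows[[s]] <- data.frame(
      session = s,
      memory_id = ses_mem$memory_id[ord],
      time_point_months = ses_mem$time_point_months[ord],
      set = ses_mem$set[ord],
      order = seq_len(nrow(ses_mem)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- cbind(trial = seq_len(nrow(out)), out)
  class(out) <- c("session_schedule", "data.frame")
  out
}

#' Validate schedule constraints
#'
#' Checks the invariants a schedule must satisfy: repetition counts,
#' no within-session memory repeats, no same-time-point co-occurrence,
#' and the session size. Used by tests and defensive callers.
#'
#' @param schedule A schedule data.frame.
#' @param spec The `design_spec` it should satisfy.
#' @return `TRUE` invisibly, or an error naming the violated constraint.
#' @export
validate_schedule <- function(schedule, spec) {
  reps <- table(schedule$memory_id)
  if (any(reps != spec$repetitions))
    stop("schedule invariant violated: unequal memory repetition counts")
  per_ses <- table(schedule$session)
  if (any(per_ses != spec$trials_per_session))
    stop("schedule invariant violated: session size != trials_per_session")
  for (s in unique(schedule$session)) {
    rows <- schedule[schedule$session == s, ]
    if (anyDuplicated(rows$memory_id))
      stop("schedule invariant violated: memory repeated within a session")
    if (anyDuplicated(rows$time_point_months))
      stop("schedule invariant violated: same-time-point memories co-occur in a session")
  }
  invisible(TRUE)
}
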