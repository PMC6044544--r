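test_that("vividness filtering retains the right trials and flags unscorable memories", {
  tr <- toy_trials(rep("A1", 6), session = 1:6,
                   vividness = c(5, 5, 5, 4, 4, 2))
  expect_equal(nrow(filter_vivid_trials(tr, 1)), 6)     # no-op bound
  f3 <- filter_vivid_trials(tr, 3)
  expect_equal(nrow(f3), 5)
  expect_length(attr(f3, "unscorable"), 0)
  f6 <- filter_vivid_trials(tr, 6)
  expect_equal(attr(f6, "unscorable"), "A1")            # flagged, not dropped
  # two trials in one session only: cross-session pairs impossible
  tr2 <- toy_trials(rep("A1", 3), session = c(1, 1, 2),
                    vividness = c(5, 5, 1))
  expect_equal(attr(filter_vivid_trials(tr2, 3), "unscorable"), "A1")
})

test_that("cross-session similarity matches hand-computed pair averages", {
  tr <- toy_trials(c("A1", "A1"), session = c(1, 2))
  p <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(cross_session_similarity(p, tr, "A1", "A1"), -1)
  # identical vectors across sessions: perfect reproducibility
  p_same <- rbind(c(1, 5, 2), c(1, 5, 2))
  expect_equal(cross_session_similarity(p_same, tr, "A1", "A1"), 1)
  # 3 vs 2 trials, brute-force mean of eligible pairwise r
  tr2 <- toy_trials(c("A1", "A1", "A1", "A2", "A2"),
                    session = c(1, 2, 3, 1, 2))
  set.seed(1)
  p2 <- matrix(sample(1:9, 20, replace = TRUE), 5, 4)
  expect_equal(cross_session_similarity(p2, tr2, "A1", "A2"),
               oracle_pair_similarity(p2, tr2, "A1", "A2"),
               tolerance = 1e-12)
  # same-session-only pairs are an error naming the memories
  tr3 <- toy_trials(c("A1", "A2"), session = c(1, 1))
  expect_error(cross_session_similarity(p_same, tr3, "A1", "A2"),
               "A1.*A2")
  expect_error(cross_session_similarity(rbind(c(1, 1, 1), c(1, 2, 3)),
                                        tr, "A1", "A1"), "zero-variance")
})

test_that("neural representation scores match constructions and the brute-force oracle", {
  sets <- rep(c("A", "B"), each = 8)
  mems <- paste0(sets, rep(1:8, 2))
  tr <- toy_trials(rep(mems, each = 2), session = rep(1:2, 16),
                   set = rep(sets, each = 2),
                   tp = rep(rep(1:8, 2), each = 2))
  # all memories share one identical pattern: no distinctiveness
  p_same <- matrix(rep(c(2, 7, 1, 5), 32), 32, 4, byrow = TRUE)
  expect_equal(neural_representation_score(p_same, tr, "A3"), 0)
  expect_equal(neural_representation_score(p_same, tr, "A3",
                                           variant = "matched-age"), 0)
  # random small patterns vs independent pairwise-enumeration oracle
  set.seed(42)
  p <- matrix(rnorm(32 * 3), 32, 3)
  for (m in c("A1", "A5", "B2")) {
    expect_equal(neural_representation_score(p, tr, m),
                 oracle_score(p, tr, m), tolerance = 1e-12)
    expect_equal(neural_representation_score(p, tr, m, "matched-age"),
                 oracle_score(p, tr, m, "matched-age"), tolerance = 1e-12)
  }
})

test_that("a perfectly reproducible orthogonal memory scores 1", {
  # A1 has a fixed signature, other memories mutually uncorrelated patterns
  sets <- rep("A", 4)
  tr <- toy_trials(rep(paste0("A", 1:4), each = 2), session = rep(1:2, 4),
                   set = rep(sets, each = 2), tp = rep(1:4, each = 2))
  v <- diag(8)
  p <- rbind(v[1, ], v[1, ],       # A1: identical -> within = 1
             v[2, ], v[3, ], v[4, ], v[5, ], v[6, ], v[7, ])
  score <- neural_representation_score(p, tr, "A1")
  within <- 1
  between <- mean(sapply(3:8, function(i) cor(v[1, ], v[i, ])))
  expect_equal(score, within - between, tolerance = 1e-12)
})

test_that("scores are invariant to global affine rescaling of the patterns", {
  sub <- simulate_subject(design_spec(), ground_truth(), 20, seed = 11)
  tr <- filter_vivid_trials(sub$schedule, 3)
  p <- unclass(sub$patterns)[tr$trial, ]
  s1 <- timepoint_scores(p, tr)
  s2 <- timepoint_scores(3.7 * p + 2, tr)
  expect_equal(s1$score, s2$score, tolerance = 1e-10)
})

test_that("random small instances match the enumeration oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n_mem <- sample(2:4, 1)
    n_rep <- sample(2:3, 1)
    mems <- paste0("A", seq_len(n_mem))
    tr <- toy_trials(rep(mems, each = n_rep),
                     session = rep(seq_len(n_rep), n_mem),
                     set = rep("A", n_mem * n_rep),
                     tp = rep(seq_len(n_mem), each = n_rep))
    p <- matrix(rnorm(nrow(tr) * 5), nrow(tr), 5)
    for (m in mems)
      expect_equal(neural_representation_score(p, tr, m),
                   oracle_score(p, tr, m), tolerance = 1e-12)
  }
})

test_that("timepoint averaging handles pairs and unscorable memories", {
  # construct a two-memory time point with known memory scores
  tr <- toy_trials(rep(c("A1", "A2", "B1", "B2"), each = 2),
                   session = rep(1:2, 4),
                   set = rep(c("A", "A", "B", "B"), each = 2),
                   tp = rep(c(1, 2, 1, 2), each = 2))
  set.seed(3)
  p <- matrix(rnorm(8 * 6), 8, 6)
  st <- timepoint_scores(p, tr)
  s_a1 <- neural_representation_score(p, tr, "A1")
  s_b1 <- neural_representation_score(p, tr, "B1")
  expect_equal(st$score[st$time_point_months == 1], mean(c(s_a1, s_b1)))
  expect_equal(st$score_A[1], s_a1)
  expect_false(any(st$flag))
  # knock out B1 via vividness: time point keeps A1's score, flagged
  tr2 <- tr
  tr2$vividness[tr2$memory_id == "B1"] <- 1
  f <- filter_vivid_trials(tr2, 3)
  p_f <- p[f$trial, ]
  st2 <- timepoint_scores(p_f, f)
  expect_true(st2$flag[st2$time_point_months == 1])
  expect_equal(st2$n_memories[st2$time_point_months == 1], 1L)
})

test_that("group RSM averaging and rank-display transform", {
  lab <- data.frame(memory_id = c("A1", "A2"), set = "A",
                    time_point_months = c(1, 2))
  mk <- function(vals) structure(matrix(vals, 2, 2,
                                        dimnames = list(c("A1", "A2"),
                                                        c("A1", "A2"))),
                                 labels = lab,
                                 class = c("memory_rsm", "matrix"))
  r1 <- mk(c(.1, .3, .3, .9))
  expect_equal(unclass(group_rsm(list(r1), display = FALSE)),
               unclass(r1), ignore_attr = TRUE)
  disp <- group_rsm(list(r1), display = TRUE)
  expect_equal(as.vector(unclass(disp)), c(0, .5, .5, 1))
  r2 <- mk(c(.2, .4, .4, .8))
  avg <- group_rsm(list(r1, r2))
  expect_equal(as.vector(unclass(avg)), c(.15, .35, .35, .85))
  bad <- mk(c(1, 0, 0, 1)); rownames(bad) <- c("X1", "X2")
  expect_error(group_rsm(list(r1, bad)), "label mismatch")
  # display range is [0, 1] whenever two distinct values exist
  set.seed(4)
  r3 <- mk(c(.1, .2, .2, .15))
  d3 <- unclass(group_rsm(list(r3), display = TRUE))
  expect_equal(min(d3), 0); expect_equal(max(d3), 1)
})

test_that("between-memory profile equals hand-averaged off-diagonal entries", {
  lab <- data.frame(memory_id = c("A1", "A2", "B1", "B2"),
                    set = c("A", "A", "B", "B"),
                    time_point_months = c(1, 2, 1, 2))
  m <- matrix(c(1, .2, .3, .4,
                .2, 1, .5, .6,
                .3, .5, 1, .7,
                .4, .6, .7, 1), 4, 4,
              dimnames = list(lab$memory_id, lab$memory_id))
  rsm <- structure(m, labels = lab, class = c("memory_rsm", "matrix"))
  prof <- between_memory_profile(list(rsm))
  # tp 1: A1's same-set baseline = r(A1,A2) = .2; B1's = r(B1,B2) = .7
  expect_equal(unname(prof[1, ]), c(mean(c(.2, .7)), mean(c(.2, .7))))
})

test_that("a shared retrieval component raises the baseline but not the score", {
  spec <- design_spec()
  base <- ground_truth(amplitude = rep(0, 8), shared_component_weight = 0,
                       noise_sd = 0.1)
  with_common <- ground_truth(amplitude = rep(0, 8),
                              shared_component_weight = 0.5, noise_sd = 0.1)
  stat <- function(truth) {
    sc <- c(); btw <- c()
    for (i in 1:10) {
      s <- simulate_subject(spec, truth, 24, seed = 500 + i)
      tr <- filter_vivid_trials(s$schedule, 1)
      r <- memory_rsm(s$patterns, tr)
      sc <- c(sc, timepoint_scores(s$patterns, tr)$score)
      btw <- c(btw, between_memory_profile(list(r)))
    }
    c(score = mean(sc), between = mean(btw))
  }
  s0 <- stat(base); s1 <- stat(with_common)
  expect_gt(s1["between"] - s0["between"], 0.1)   # baseline elevated
  expect_lt(abs(s1["score"]), 0.03)               # distinctiveness unchanged
  expect_lt(abs(s0["score"]), 0.03)
})
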