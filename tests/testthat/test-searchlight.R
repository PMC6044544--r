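# 2-set, 2-reps-per-memory trial table over a supplied pattern matrix
sl_trials <- function(n_tp = 8) {
  sets <- rep(c("A", "B"), each = n_tp)
  mems <- paste0(sets, rep(seq_len(n_tp), 2))
  toy_trials(rep(mems, each = 2), session = rep(1:2, 2 * n_tp),
             set = rep(sets, each = 2),
             tp = rep(rep(seq_len(n_tp), 2), each = 2))
}

test_that("region growth hits the target size with deterministic tie-breaking", {
  mask <- array(TRUE, c(20, 20, 20))
  reg <- grow_region(mask, c(10, 10, 10), target = 160)
  expect_length(reg$members, 160)
  expect_false(reg$saturated)
  expect_true(reg$center %in% reg$members)
  # determinism
  expect_identical(reg, grow_region(mask, c(10, 10, 10), target = 160))
  # small ROI saturates to the whole ROI, flagged
  small <- array(FALSE, c(5, 5, 5)); small[1:10] <- TRUE
  sreg <- grow_region(small, which(small)[1], target = 160)
  expect_length(sreg$members, 10)
  expect_true(sreg$saturated)
  expect_error(grow_region(small, c(5, 5, 5), 10), "outside the ROI")
})

test_that("corner-centred growth matches the exhaustive distance-sort oracle", {
  mask <- array(TRUE, c(5, 5, 5))
  reg <- grow_region(mask, c(1, 1, 1), target = 27)
  expect_equal(sort(reg$members),
               sort(oracle_grow(mask, c(1, 1, 1), 27)))
  # irregular ROI
  set.seed(36)
  mask2 <- array(runif(125) > 0.3, c(5, 5, 5))
  center <- which(mask2)[10]
  cijk <- arrayInd(center, dim(mask2))
  reg2 <- grow_region(mask2, center, target = 15)
  expect_equal(reg2$members, oracle_grow(mask2, as.vector(cijk), 15))
})

test_that("region model-RSM agreement matches the rank-based oracle", {
  tr <- sl_trials(3)          # 3 memories per set
  set.seed(37)
  p <- matrix(rnorm(12 * 6), 12, 6)
  rho <- region_rsm_score(p, tr, rsm_mode = "full")
  r_all <- memory_rsm(p, tr)
  expect_equal(rho, oracle_model_spearman(unclass(r_all)),
               tolerance = 1e-10)
  # per-set mode averages the two per-set rank correlations
  rho_ps <- region_rsm_score(p, tr, rsm_mode = "per_set")
  r_a <- memory_rsm(p, tr, memories = c("A1", "A2", "A3"))
  r_b <- memory_rsm(p, tr, memories = c("B1", "B2", "B3"))
  expect_equal(rho_ps, mean(c(oracle_model_spearman(unclass(r_a)),
                              oracle_model_spearman(unclass(r_b)))),
               tolerance = 1e-10)
})

test_that("within above between yields the tie-structure maximum; flat RSMs are missing", {
  tr <- sl_trials(3)
  # identical pattern within each memory, orthogonal across memories:
  # within = 1 everywhere, between < 1 -> two-group rank structure
  v <- diag(8)
  p <- v[rep(1:6, each = 2), ]
  # add a fixed voxel profile with generic (power-spaced) entries so the
  # 15 between-memory correlations are pairwise distinct
  p <- p + matrix(rep(2^(1:8) / 300, each = 12), 12, 8)
  rho <- region_rsm_score(p, tr, rsm_mode = "full")
  r <- unclass(memory_rsm(p, tr))
  # oracle on the realised tie structure
  expect_equal(rho, oracle_model_spearman(r), tolerance = 1e-10)
  # within entries separate cleanly from between entries, and rho is close
  # to the ideal two-group value (6 entries tied at the top rank, 15
  # distinct below); floating point makes some within correlations 1-eps,
  # jittering the tie ranks, hence the loose tolerance
  vv <- r[lower.tri(r, diag = TRUE)]
  model <- diag(6)[lower.tri(r, diag = TRUE)]
  expect_gt(min(vv[model == 1]), max(vv[model == 0]))
  rho_groups <- cor(c(rep(18.5, 6), 1:15), c(rep(1, 6), rep(0, 15)))
  expect_equal(rho, rho_groups, tolerance = 0.01)
  # all similarities equal -> degenerate, missing not zero
  p_same <- matrix(rep(c(1, 3, 2, 5, 4, 6, 8, 7), 12), 12, 8, byrow = TRUE)
  expect_true(is.na(region_rsm_score(p_same, tr, rsm_mode = "full")))
})

test_that("searchlight map is total on the ROI and constant when the ROI equals one region", {
  dims <- c(3, 3, 3)
  mask <- array(TRUE, dims)
  tr <- sl_trials(4)
  set.seed(38)
  p <- matrix(rnorm(16 * 27), 16, 27)
  m <- searchlight_map(p, tr, mask, target = 27)
  expect_length(m$values, 27)
  expect_true(all(m$n_regions >= 1))
  # every region is the whole ROI: every voxel belongs to all 27 regions
  expect_true(all(m$n_regions == 27))
  expect_equal(diff(range(m$values)), 0)
  expect_error(searchlight_map(p, tr, array(FALSE, dims), 5), "empty ROI")
})

test_that("signal confined to a block attracts the map maximum", {
  dims <- c(6, 6, 6)
  mask <- array(TRUE, dims)
  block <- array(FALSE, dims); block[1:3, 1:3, 1:3] <- TRUE
  block_lin <- which(block)
  spec <- design_spec()
  hits <- 0
  for (i in 1:10) {
    sub <- simulate_subject(spec, ground_truth(amplitude = rep(1, 8),
                                               noise_sd = 0.05),
                            n_voxels = 216, seed = 600 + i, dims = dims,
                            signal_voxels = block_lin)
    tr <- filter_vivid_trials(sub$schedule, 1)
    m <- searchlight_map(unclass(sub$patterns)[tr$trial, ], tr, mask,
                         target = 27)
    if (which(mask)[which.max(m$values)] %in% block_lin) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("sign-flip cluster p values match exhaustive enumeration on a tiny case", {
  # 6 subjects, 2-voxel ROI: 2^6 = 64 equally likely sign patterns
  dims <- c(2, 1, 1)
  mask <- array(TRUE, dims)
  X <- rbind(c(2.0, 1.8), c(2.2, 2.1), c(1.9, 2.3),
             c(2.1, 2.0), c(1.7, 2.2), c(2.3, 1.9))
  res <- signflip_cluster_test(X, mask, n_perm = 8000, t_thresh = 3,
                               seed = 5)
  # exhaustive oracle over all sign assignments
  t_of <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  null_max <- apply(signs, 1, function(s) {
    tv <- c(t_of(s * X[, 1]), t_of(s * X[, 2]))
    sum(tv >= 3) # two adjacent voxels form one cluster when both pass
  })
  null_max <- ifelse(null_max == 2, 2, null_max)
  obs_size <- res$clusters$n_voxels[1]
  p_exact <- mean(null_max >= obs_size)
  expect_equal(res$clusters$p_fwe[1], p_exact, tolerance = 0.03)
  # p can never undercut the permutation-count granularity
  expect_gte(res$clusters$p_fwe[1], 1 / res$n_perm)
})

test_that("a strong common signal is recovered as a significant cluster", {
  dims <- c(4, 4, 4)
  mask <- array(TRUE, dims)
  set.seed(40)
  base <- numeric(64); base[1:8] <- 1.5    # signal block
  X <- t(replicate(16, base + rnorm(64, sd = 0.3)))
  res <- signflip_cluster_test(X, mask, n_perm = 1000, t_thresh = 3,
                               seed = 6)
  expect_true(any(res$clusters$significant))
  top <- res$clusters[which.max(res$clusters$n_voxels), ]
  expect_gte(top$p_fwe, 1 / 1000)
  labs <- res$cluster_label
  expect_true(all(which(labs == top$cluster_id) %in% 1:8))
  # corrected p monotone nonincreasing in observed cluster size
  if (nrow(res$clusters) > 1) {
    ord <- order(res$clusters$n_voxels)
    expect_true(all(diff(res$clusters$p_fwe[ord]) <= 0))
  }
  # infinite threshold -> no clusters on any input
  res_inf <- signflip_cluster_test(X, mask, n_perm = 200, t_thresh = Inf,
                                   seed = 7)
  expect_equal(nrow(res_inf$clusters), 0)
  expect_warning(signflip_cluster_test(X, mask, n_perm = 50, seed = 8),
                 "permutations")
  # all-negative maps: valid empty result
  res_neg <- signflip_cluster_test(-abs(X), mask, n_perm = 200,
                                   t_thresh = 3, seed = 9)
  expect_equal(nrow(res_neg$clusters), 0)
})

test_that("26-connectivity labelling groups diagonal neighbours", {
  dims <- c(3, 3, 3)
  # two voxels touching only at a corner are 26-connected
  lin <- c(1, 1 + 1 + 3 + 9)  # (1,1,1) and (2,2,2)
  labs <- memrep:::label_components(lin, dims)
  expect_equal(labs[1], labs[2])
  # far-apart voxels are separate components
  lin2 <- c(1, 27)
  labs2 <- memrep:::label_components(lin2, dims)
  expect_equal(length(unique(labs2)), 2)
  expect_equal(memrep:::max_cluster_size(integer(0), dims), 0L)
})
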