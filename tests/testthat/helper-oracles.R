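# Independent brute-force oracles, kept free of the package's internals:
# everything here recomputes quantities from first principles with explicit
# loops and textbook formulas.

# Mean cross-session Pearson r between two memories, by explicit pair loops.
oracle_pair_similarity <- function(p, trials, mem_a, mem_b) {
  ia <- which(trials$memory_id == mem_a)
  ib <- which(trials$memory_id == mem_b)
  vals <- c()
  for (i in ia) for (j in ib) {
    if (mem_a == mem_b && j <= i) next
    if (trials$session[i] == trials$session[j]) next
    vals <- c(vals, cor(p[i, ], p[j, ]))
  }
  mean(vals)
}

oracle_score <- function(p, trials, memory, variant = "all-other") {
  info <- trials[trials$memory_id == memory, ][1, ]
  within <- oracle_pair_similarity(p, trials, memory, memory)
  mems <- unique(trials[, c("memory_id", "set", "time_point_months")])
  if (variant == "all-other") {
    others <- mems$memory_id[mems$set == info$set &
                             mems$memory_id != memory]
    between <- mean(sapply(others, function(m)
      oracle_pair_similarity(p, trials, memory, m)))
  } else {
    mate <- mems$memory_id[mems$set != info$set &
                           mems$time_point_months == info$time_point_months]
    between <- oracle_pair_similarity(p, trials, memory, mate)
  }
  within - between
}

# Classical one-way repeated-measures sums-of-squares decomposition,
# Greenhouse-Geisser epsilon from the double-centred covariance, and
# Mauchly's W on orthonormal contrasts.
oracle_rm_anova <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  grand <- mean(tab)
  ss_cond <- n * sum((colMeans(tab) - grand)^2)
  ss_subj <- k * sum((rowMeans(tab) - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F_val <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  S <- cov(tab)
  Sdc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps <- sum(diag(Sdc))^2 / ((k - 1) * sum(Sdc^2))
  M <- contr.helmert(k)
  M <- qr.Q(qr(M))  # orthonormal contrasts
  Sc <- t(M) %*% S %*% M
  W <- det(Sc) / (sum(diag(Sc)) / (k - 1))^(k - 1)
  # Mauchly (1940) chi-square approximation with the standard
  # second-order correction term (Anderson 2003, sec. 10.7)
  pdim <- k - 1; ne <- n - 1
  rho <- 1 - (2 * pdim^2 + pdim + 2) / (6 * pdim * ne)
  w2 <- (pdim + 2) * (pdim - 1) * (pdim - 2) *
    (2 * pdim^3 + 6 * pdim^2 + 3 * pdim + 2) /
    (288 * pdim^2 * ne^2 * rho^2)
  df_w <- pdim * (pdim + 1) / 2 - 1
  chi2 <- -ne * rho * log(W)
  p_w <- pchisq(chi2, df_w, lower.tail = FALSE) +
    w2 * (pchisq(chi2, df_w + 4, lower.tail = FALSE) -
          pchisq(chi2, df_w, lower.tail = FALSE))
  list(F = F_val, df1 = k - 1, df2 = (k - 1) * (n - 1),
       epsilon = eps, mauchly_W = W,
       mauchly_p = p_w,
       ss_cond = ss_cond, ss_err = ss_err)
}

# Fully within-subject two-factor decomposition (factor a: 2 levels,
# factor b: k levels), textbook SS with subject interactions as errors.
oracle_two_way_rm <- function(tab1, tab2) {
  n <- nrow(tab1); k <- ncol(tab1)
  y <- array(0, c(n, 2, k))
  y[, 1, ] <- tab1; y[, 2, ] <- tab2
  grand <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- n * k * sum((m_a - grand)^2)
  ss_b <- n * 2 * sum((m_b - grand)^2)
  ss_sa <- k * sum((m_sa - outer(m_s, m_a, "+") + grand)^2)
  ss_sb <- 2 * sum((m_sb - outer(m_s, m_b, "+") + grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, "+") + grand)^2)
  resid <- y
  for (i in 1:n) for (a in 1:2) for (b in 1:k)
    resid[i, a, b] <- y[i, a, b] - m_sa[i, a] - m_sb[i, b] - m_ab[a, b] +
      m_s[i] + m_a[a] + m_b[b] - grand
  ss_sab <- sum(resid^2)
  list(F_a = (ss_a / 1) / (ss_sa / (n - 1)),
       F_b = (ss_b / (k - 1)) / (ss_sb / ((k - 1) * (n - 1))),
       F_ab = (ss_ab / (k - 1)) / (ss_sab / ((k - 1) * (n - 1))))
}

oracle_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  sse <- sum((x - grand)^2) - msr * (n - 1) - msc * (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

oracle_cousineau_sem <- function(tab) {
  norm <- tab
  for (i in seq_len(nrow(tab)))
    norm[i, ] <- tab[i, ] - mean(tab[i, ]) + mean(tab)
  apply(norm, 2, sd) / sqrt(nrow(tab))
}

# Spearman rho of RSM lower triangle (diag included) against the
# identity-model vector, via explicit rank formula.
oracle_model_spearman <- function(rsm) {
  v <- rsm[lower.tri(rsm, diag = TRUE)]
  model <- diag(nrow(rsm))[lower.tri(rsm, diag = TRUE)]
  rv <- rank(v); rm_ <- rank(model)
  sum((rv - mean(rv)) * (rm_ - mean(rm_))) /
    sqrt(sum((rv - mean(rv))^2) * sum((rm_ - mean(rm_))^2))
}

# Nearest-`target` ROI voxels by (squared distance, linear index).
oracle_grow <- function(mask, center_ijk, target) {
  dims <- dim(mask)
  lin <- which(mask != 0)
  ijk <- arrayInd(lin, dims)
  d2 <- colSums((t(ijk) - center_ijk)^2)
  lin[order(d2, lin)][seq_len(min(target, length(lin)))]
}

# A tiny deterministic subject: per-memory patterns with chosen vectors.
toy_trials <- function(memory_id, session, set = NULL, tp = NULL,
                       vividness = 5) {
  n <- length(memory_id)
  data.frame(trial = seq_len(n), session = session, memory_id = memory_id,
             time_point_months = tp %||% as.numeric(factor(memory_id)),
             set = set %||% rep("A", n), order = seq_len(n),
             vividness = rep_len(vividness, n), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
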