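# Shared fixtures and independent oracles for the test suite.

grid_chr <- as.character(freq_grid())

# A complete audiogram with the given thresholds (scalar recycled to 10).
mk_aud <- function(id = "a1", pid = "p1", age = 30, thr = 50,
                   gene = NA_character_, region = NA_character_) {
  audiogram(pid, id, age, stats::setNames(rep_len(thr, 10), grid_chr),
            region = region, gene = gene)
}

# Two well-separated flat gene classes: A at 20 dB, B at 80 dB, noise sd 2.
# One single-audiogram patient per row, n per class.
mk_separable_records <- function(n_per_class = 50, seed = 1,
                                 levels_db = c(A = 20, B = 80),
                                 noise_sd = 2) {
  set.seed(seed)
  recs <- list()
  i <- 0
  for (g in names(levels_db)) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1
      pid <- sprintf("%s%03d", g, r)
      thr <- pmin(pmax(levels_db[[g]] + rnorm(10, 0, noise_sd), -10), 130)
      a <- audiogram(pid, paste0(pid, "-1"), runif(1, 10, 70),
                     stats::setNames(thr, grid_chr), gene = g)
      recs[[i]] <- patient_record(pid, list(a), gene = g)
    }
  }
  recs
}

# --- independent oracles -------------------------------------------------

# Negative log-likelihood criterion whose constrained minimizer is the
# pairwise-coupling fixed point (Hastie-Tibshirani). Independent of the
# package's iterative implementation.
coupling_objective <- function(p, R) {
  K <- length(p)
  val <- 0
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    mu <- p[i] / (p[i] + p[j])
    mu <- min(max(mu, 1e-12), 1 - 1e-12)
    val <- val + R[i, j] * log(R[i, j] / mu) +
      R[j, i] * log(R[j, i] / (1 - mu))
  }
  val
}

# Coarse-to-fine dense grid search over the probability simplex.
simplex_grid_search <- function(R, levels = 4) {
  K <- nrow(R)
  lo <- rep(0, K - 1); hi <- rep(1, K - 1)
  step <- if (K == 3) 0.02 else 0.05
  best <- rep(1 / K, K)
  for (lev in seq_len(levels)) {
    axes <- lapply(seq_len(K - 1), function(d) {
      seq(max(lo[d], 0), min(hi[d], 1), by = step)
    })
    cand <- as.matrix(expand.grid(axes))
    last <- 1 - rowSums(cand)
    keep <- last >= -1e-12
    cand <- cbind(cand, pmax(last, 0))[keep, , drop = FALSE]
    cand <- cand[rowSums(cand > 1e-9) == K, , drop = FALSE]  # interior
    vals <- apply(cand, 1, coupling_objective, R = R)
    best <- cand[which.min(vals), ]
    lo <- best[seq_len(K - 1)] - step
    hi <- best[seq_len(K - 1)] + step
    step <- step / 8
  }
  as.numeric(best)
}

# Random pairwise-probability table with a consistent generating vector.
random_pairwise_table <- function(K, seed) {
  set.seed(seed)
  q <- runif(K, 0.05, 1); q <- q / sum(q)
  R <- matrix(NA_real_, K, K, dimnames = list(LETTERS[1:K], LETTERS[1:K]))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    r <- q[i] / (q[i] + q[j]) + runif(1, -0.05, 0.05)
    r <- min(max(r, 0.02), 0.98)
    R[i, j] <- r; R[j, i] <- 1 - r
  }
  R
}

# Exhaustive minimal-inertia bipartition of a small point set.
best_two_partition <- function(x) {
  n <- nrow(x)
  best <- NULL; best_val <- Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    ss <- function(m) {
      if (!nrow(m)) return(0)
      sum(sweep(m, 2, colMeans(m))^2)
    }
    val <- ss(x[grp, , drop = FALSE]) + ss(x[!grp, , drop = FALSE])
    if (val < best_val) {
      best_val <- val
      best <- grp
    }
  }
  list(partition = best, inertia = best_val)
}

# Trustworthiness of a low-dimensional map Y of data X at neighbourhood k:
# penalizes points that enter the embedded k-neighbourhood without being
# close in the original space.
trustworthiness <- function(X, Y, k = 10) {
  n <- nrow(X)
  dx <- as.matrix(dist(X)); dy <- as.matrix(dist(Y))
  diag(dx) <- Inf; diag(dy) <- Inf
  penalty <- 0
  for (i in seq_len(n)) {
    rank_x <- rank(dx[i, ], ties.method = "first")
    nn_x <- which(rank_x <= k)
    nn_y <- order(dy[i, ])[seq_len(k)]
    intruders <- setdiff(nn_y, nn_x)
    penalty <- penalty + sum(rank_x[intruders] - k)
  }
  1 - 2 * penalty / (n * k * (2 * n - 3 * k - 1))
}

# Three separated Gaussian blobs in d dimensions (separation 10 x SD).
mk_blobs <- function(n_per = 20, d = 11, seed = 5) {
  set.seed(seed)
  centers <- matrix(rnorm(3 * d), 3, d)
  centers <- centers / sqrt(rowSums(centers^2)) * 10
  x <- do.call(rbind, lapply(1:3, function(b) {
    sweep(matrix(rnorm(n_per * d, sd = 1), n_per, d), 2, centers[b, ], "+")
  }))
  rownames(x) <- sprintf("pt%02d", seq_len(nrow(x)))
  x
}
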