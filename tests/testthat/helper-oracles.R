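# Independent brute-force oracles used to verify the package's numerics.
# These deliberately avoid the implementation's code paths.

# dense diffusion-map oracle: build the transition operator explicitly and
# eigendecompose it as a plain (non-symmetric) matrix
oracle_diffusion <- function(W, alpha, k) {
  d <- rowSums(W)
  W1 <- W / outer(d^alpha, d^alpha)
  d1 <- rowSums(W1)
  P <- W1 / d1
  e <- eigen(P)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  list(values = vals[2:(k + 1)],
       vectors = vecs[, 2:(k + 1), drop = FALSE])
}

# exhaustive Benjamini-Hochberg step-up: find the largest i with
# p_(i) <= q * i / m and reject everything at or below it
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= q * seq_len(m) / m)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

oracle_bonferroni <- function(p, alpha) pmin(p * length(p), 1) <= alpha

# double-loop normalized-angle cosine affinity
oracle_affinity <- function(block) {
  n <- nrow(block)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- sum(block[i, ] * block[j, ])
      den <- sqrt(sum(block[i, ]^2)) * sqrt(sum(block[j, ]^2))
      rho <- max(min(num / den, 1), -1)
      out[i, j] <- 1 - acos(rho) / pi
    }
  }
  diag(out) <- 1
  out
}

# per-row sort-based sparsification with lowest-index tie-break
oracle_sparsify <- function(block, density) {
  n <- ncol(block)
  keep <- ceiling(density * n)
  out <- matrix(0, nrow(block), n)
  for (i in seq_len(nrow(block))) {
    ord <- order(-block[i, ], seq_len(n))
    out[i, ord[seq_len(keep)]] <- block[i, ord[seq_len(keep)]]
  }
  out
}

# permutation null for the two-sample Hotelling statistic
oracle_perm_p <- function(Xa, Xb, B, seed) {
  set.seed(seed)
  X <- rbind(Xa, Xb)
  n1 <- nrow(Xa)
  n <- nrow(X)
  t2_of <- function(ia) {
    A <- X[ia, , drop = FALSE]
    Bm <- X[-ia, , drop = FALSE]
    d <- colMeans(A) - colMeans(Bm)
    S <- ((nrow(A) - 1) * stats::cov(A) + (nrow(Bm) - 1) * stats::cov(Bm)) /
      (n - 2)
    as.numeric(nrow(A) * nrow(Bm) / n * crossprod(d, solve(S, d)))
  }
  obs <- t2_of(seq_len(n1))
  hits <- 0L
  for (b in seq_len(B)) {
    if (t2_of(sample(n, n1)) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

# OLS residual via the explicit hat matrix
oracle_residualize <- function(Y, C) {
  X <- cbind(1, as.matrix(C))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  R <- Y - H %*% Y
  beta0 <- (solve(crossprod(X)) %*% t(X) %*% Y)[1, ]
  R + matrix(beta0, nrow(Y), ncol(Y), byrow = TRUE)
}

# brute-force weighted decoding score
oracle_term_score <- function(term_z, stat_map, n_bins) {
  n <- length(stat_map)
  ord <- order(stat_map, seq_len(n))
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  assignment <- integer(n)
  assignment[ord] <- rep(seq_len(n_bins), times = sizes)
  score <- 0
  for (b in seq_len(n_bins)) {
    idx <- which(assignment == b)
    loading <- mean(stat_map[idx])
    pos <- term_z[idx][term_z[idx] > 0]
    if (length(pos)) score <- score + mean(pos) * loading
  }
  score
}

# random symmetric, connected, non-negative affinity with unit diagonal
random_affinity <- function(n, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n, 0, 1), n, n)
  A <- (A + t(A)) / 2 + 0.1
  diag(A) <- 1
  A
}

# a small valid parcellation table for io tests
tiny_parcellation_df <- function(n_per_hemi = 6) {
  ids <- seq_len(n_per_hemi) - 1L
  nets <- rep_len(NETWORK_LABELS, n_per_hemi)
  data.frame(
    parcel_id = c(ids, ids + n_per_hemi),
    parcel_name = c(paste0("L", ids), paste0("R", ids)),
    hemisphere = rep(c("left", "right"), each = n_per_hemi),
    homolog_id = c(ids + n_per_hemi, ids),
    network = rep(nets, 2),
    stringsAsFactors = FALSE)
}

tiny_phenotype_df <- function() {
  data.frame(
    subject_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    group = c("autism", "NAI", "autism", "NAI", "autism", "NAI"),
    age = c(8, 15, 25, 41, 30, 12),
    site = c("A", "A", "B", "B", "A", "B"),
    fiq = c(100, 110, 65, 105, 95, 120),
    mean_fd = c(0.1, 0.2, 0.15, 0.1, 0.31, 0.05),
    ados_total = c(12, NA, 15, NA, 9, NA),
    stringsAsFactors = FALSE)
}
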