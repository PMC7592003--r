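# Independent brute-force oracles: explicit loops and defining formulas,
# deliberately sharing no code with the package internals.

mk_mat <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  cq_matrix(m)
}

sd_manual <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  sqrt(sum((v - mu)^2) / (n - 1))
}

oracle_pairwise_sd <- function(mat, j, k) {
  d <- numeric(0)
  for (s in colnames(mat)) {
    a <- mat[j, s]; b <- mat[k, s]
    if (!is.na(a) && !is.na(b)) d <- c(d, a - b)
  }
  sd_manual(d)
}

oracle_m_values <- function(mat, panel = rownames(mat)) {
  out <- numeric(length(panel)); names(out) <- panel
  for (j in panel) {
    acc <- numeric(0)
    for (k in panel) if (k != j) acc <- c(acc, oracle_pairwise_sd(mat, j, k))
    out[j] <- mean(acc)
  }
  out
}

oracle_v_series <- function(mat, ranked) {
  K <- length(ranked)
  v <- numeric(K - 2)
  for (n in 2:(K - 1)) {
    diffs <- numeric(0)
    for (s in colnames(mat)) {
      top_n <- mat[ranked[1:n], s]
      top_n1 <- mat[ranked[1:(n + 1)], s]
      if (!any(is.na(top_n1)))
        diffs <- c(diffs, mean(top_n) - mean(top_n1))
    }
    v[n - 1] <- sd_manual(diffs)
  }
  names(v) <- paste0("V", 2:(K - 1))
  v
}

# NormFinder estimator pieces, straight from the defining formulas:
# per-group two-way residual variance with bias correction, and the
# gene-by-group interaction of (equally weighted) group means.
oracle_normfinder_parts <- function(mat, groups) {
  genes <- rownames(mat)
  lv <- unique(as.character(groups))
  I <- length(genes)
  sigma2 <- d <- matrix(NA_real_, I, length(lv), dimnames = list(genes, lv))
  ggm <- matrix(NA_real_, I, length(lv), dimnames = list(genes, lv))
  for (g in lv) {
    idx <- which(as.character(groups) == g)
    x <- mat[, idx, drop = FALSE]
    n <- ncol(x)
    grand <- mean(x)
    s2 <- numeric(I)
    for (i in seq_len(I)) {
      acc <- 0
      for (s in seq_len(n)) {
        r <- x[i, s] - mean(x[i, ]) - mean(x[, s]) + grand
        acc <- acc + r^2
      }
      s2[i] <- acc / (n - 1)
      ggm[i, g] <- mean(x[i, ])
    }
    for (i in seq_len(I))
      sigma2[i, g] <- max(0, (s2[i] - sum(s2) / (I * (I - 1))) * I / (I - 2))
  }
  for (i in seq_len(I)) for (g in lv)
    d[i, g] <- ggm[i, g] - mean(ggm[i, ]) - mean(ggm[, g]) + mean(ggm)
  list(sigma2 = sigma2, d = d)
}

oracle_deltacq_samplemean <- function(mat) {
  genes <- rownames(mat)
  out <- numeric(length(genes)); names(out) <- genes
  centered <- mat
  for (s in colnames(mat)) centered[, s] <- mat[, s] - mean(mat[, s])
  for (g in genes) out[g] <- sd_manual(centered[g, ])
  out
}

oracle_rel_expr <- function(tq, rq) {
  out <- numeric(length(tq))
  for (i in seq_along(tq)) out[i] <- 2^(-(tq[i] - rq[i]))
  out
}

# small random Cq matrix for property batteries
random_cq <- function(genes, samples, seed, lo = 20, hi = 35, noise = 1.5) {
  set.seed(seed)
  base <- runif(genes, lo, hi)
  m <- base + matrix(rnorm(genes * samples, 0, noise), genes, samples)
  mk_mat(pmin(pmax(m, 0), 45))
}
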