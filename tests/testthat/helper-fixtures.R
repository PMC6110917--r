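# Shared fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive re-derivations (enumeration, direct
# formulas, stats:: reference fits) kept separate from the package's own
# computational paths.

# random symmetric zero-diagonal distance matrix with labels
random_distance <- function(n, seed, labels = paste0("s", seq_len(n))) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 1)
  m <- m + t(m)
  dimnames(m) <- list(labels, labels)
  m
}

# small community matrix with per-phylum OTU blocks
small_community <- function(n_samples = 12, n_otus = 30, seed = 1,
                            lambda = 40) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
                   dimnames = list(paste0("s", seq_len(n_samples)),
                                   paste0("otu", seq_len(n_otus))))
  taxonomy <- setNames(rep(c("PhylumA", "PhylumB", "PhylumC"),
                           length.out = n_otus),
                       colnames(counts))
  community_matrix(counts, taxonomy)
}

# exhaustive-permutation Mantel oracle: naive Spearman on permuted raw
# matrices, enumerating every relabeling (identity included)
oracle_mantel_exact <- function(A, B, tail = "greater") {
  n <- nrow(A)
  up <- upper.tri(A)
  r_obs <- cor(A[up], B[up], method = "spearman")
  perms <- combinat_perms(n)
  stats_all <- vapply(perms, function(p) {
    Bp <- B[p, p]
    cor(A[up], Bp[up], method = "spearman")
  }, numeric(1))
  if (tail == "greater") mean(stats_all >= r_obs - 1e-12)
  else mean(abs(stats_all) >= abs(r_obs) - 1e-12)
}

# exhaustive partial-Mantel oracle via residual-based partial correlation of
# rank vectors (a different algebraic route than the package's formula)
oracle_partial_mantel_exact <- function(A, B, C) {
  up <- upper.tri(A)
  ra <- rank(A[up]); rc <- rank(C[up])
  pcor <- function(rb) {
    cor(resid(lm(ra ~ rc)), resid(lm(rb ~ rc)))
  }
  r_obs <- pcor(rank(B[up]))
  stats_all <- vapply(combinat_perms(nrow(A)), function(p) {
    Bp <- B[p, p]
    pcor(rank(Bp[up]))
  }, numeric(1))
  mean(stats_all >= r_obs - 1e-12)
}

# exhaustive ANOSIM oracle over distinct relabelings of the group multiset
oracle_anosim_exact <- function(D, groups) {
  n <- nrow(D)
  rk <- matrix(0, n, n)
  rk[upper.tri(rk)] <- rank(D[upper.tri(D)])
  rk <- rk + t(rk)
  stat <- function(g) {
    same <- outer(g, g, "==")
    (mean(rk[upper.tri(rk) & !same]) - mean(rk[upper.tri(rk) & same])) /
      (n * (n - 1) / 4)
  }
  r_obs <- stat(groups)
  seen <- character(0)
  stats_all <- numeric(0)
  for (p in combinat_perms(n)) {
    g <- groups[p]
    key <- paste(g, collapse = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      stats_all <- c(stats_all, stat(g))
    }
  }
  list(p = mean(stats_all >= r_obs - 1e-12), n_distinct = length(stats_all))
}

# plain recursive permutation enumerator (independent of the package's)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (k in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = k)
  }
  out
}

# brute-force LMG oracle: average sequential R^2 gains over all orderings,
# each R^2 from a fresh stats::lm fit
oracle_lmg <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  shares <- setNames(numeric(p), colnames(X))
  orders <- combinat_perms(p)
  for (ord in orders) {
    prev_r2 <- 0
    for (k in seq_len(p)) {
      idx <- ord[seq_len(k)]
      r2 <- summary(lm(y ~ X[, idx, drop = FALSE]))$r.squared
      shares[ord[k]] <- shares[ord[k]] + (r2 - prev_r2)
      prev_r2 <- r2
    }
  }
  shares / length(orders)
}
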