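# Permutation inference on distance matrices. All tests share conventions:
# the statistic uses Spearman ranks (mid-ranks on ties), the null is built by
# simultaneously permuting rows and columns of one matrix, and p-values obey
# the add-one rule p = (1 + #{stat_perm >= stat_obs}) / (1 + n_perm), so the
# minimum attainable p is 1/(n_perm + 1). Passing `exhaustive = TRUE`
# replaces Monte-Carlo permutations by complete enumeration (n <= 8), with
# p the exact fraction of relabelings (identity included) at least as
# extreme as the observed one.

# symmetric matrix holding the mid-ranks of the upper off-diagonal entries
rank_matrix <- function(m) {
  r <- matrix(0, nrow(m), ncol(m))
  r[upper.tri(r)] <- rank(m[upper.tri(m)])
  r + t(r)
}

perm_pvalue <- function(stat_perm, stat_obs, tail, eps = 1e-12) {
  hits <- switch(tail,
    greater = sum(stat_perm >= stat_obs - eps),
    two_sided = sum(abs(stat_perm) >= abs(stat_obs) - eps)
  )
  (1 + hits) / (1 + length(stat_perm))
}

exact_pvalue <- function(stat_all, stat_obs, tail, eps = 1e-12) {
  hits <- switch(tail,
    greater = sum(stat_all >= stat_obs - eps),
    two_sided = sum(abs(stat_all) >= abs(stat_obs) - eps)
  )
  hits / length(stat_all)
}

#' Mantel test (Spearman)
#'
#' Correlates the upper off-diagonal entries of two distance matrices using
#' Spearman ranks; significance by simultaneously permuting rows and columns
#' of `B`.
#'
#' @param A,B Square labelled distance matrices with identical labels/order.
#' @param n_perm Number of permutations (ignored when `exhaustive`); 0 skips
#'   the permutation test and returns `p = NA`.
#' @param seed Integer seed.
#' @param tail `"greater"` (default, tests positive matrix association) or
#'   `"two_sided"`.
#' @param exhaustive Enumerate all `n!` relabelings instead of sampling
#'   (requires n <= 8); `p` is then the exact enumeration fraction.
#' @return A `mantel_outcome`: list with `r`, `p`, `n_perm`, `seed`, `tail`.
#' @export
mantel_test <- function(A, B, n_perm = 999, seed = 1L,
                        tail = c("greater", "two_sided"),
                        exhaustive = FALSE) {
  tail <- match.arg(tail)
  A <- as_square_distance(A, "A"); B <- as_square_distance(B, "B")
  check_same_labels(A, B)
  n <- nrow(A)
  if (n < 4) stop("Mantel test needs at least 4 samples")
  if (!exhaustive && n_perm < 0) stop("n_perm must be >= 0")
  ra <- rank(upper_entries(A))
  rB <- rank_matrix(B)
  r_obs <- stats::cor(ra, upper_entries(rB))
  if (exhaustive) {
    perms <- all_permutations(n)
    stats_all <- vapply(perms, function(p) {
      stats::cor(ra, upper_entries(rB[p, p]))
    }, numeric(1))
    p <- exact_pvalue(stats_all, r_obs, tail)
    n_used <- length(perms)
  } else if (n_perm == 0) {
    p <- NA_real_; n_used <- 0L
  } else {
    stats_perm <- with_substream(seed, "mantel", {
      vapply(seq_len(n_perm), function(i) {
        pp <- sample.int(n)
        stats::cor(ra, upper_entries(rB[pp, pp]))
      }, numeric(1))
    })
    p <- perm_pvalue(stats_perm, r_obs, tail)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = n_used, seed = as.integer(seed),
                 tail = tail, exhaustive = exhaustive),
            class = "mantel_outcome")
}

# first-order partial correlation from three pairwise correlations
partial_cor <- function(rab, rac, rbc) {
  (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
}

#' Partial Mantel test (Spearman)
#'
#' Rank-transforms the off-diagonal entries of each matrix, then computes the
#' first-order partial correlation of `A` and `B` given the control matrix
#' `C`. The null permutes rows and columns of `B` and recomputes the partial
#' statistic with `C` held fixed.
#'
#' @inheritParams mantel_test
#' @param C Control distance matrix (typically spatial distance).
#' @return A `mantel_outcome`.
#' @export
partial_mantel_test <- function(A, B, C, n_perm = 999, seed = 1L,
                                tail = c("greater", "two_sided"),
                                exhaustive = FALSE) {
  tail <- match.arg(tail)
  A <- as_square_distance(A, "A"); B <- as_square_distance(B, "B")
  C <- as_square_distance(C, "C")
  check_same_labels(A, B, C)
  n <- nrow(A)
  if (n < 5) stop("partial Mantel test needs at least 5 samples")
  ra <- rank(upper_entries(A)); rc <- rank(upper_entries(C))
  rB <- rank_matrix(B)
  rb <- upper_entries(rB)
  rac <- stats::cor(ra, rc)
  rbc <- stats::cor(rb, rc)
  if (abs(rac) >= 1 - 1e-12 || abs(rbc) >= 1 - 1e-12) {
    stop("degenerate control: C is perfectly correlated with A or B")
  }
  r_obs <- partial_cor(stats::cor(ra, rb), rac, rbc)
  stat_for <- function(p) {
    rbp <- upper_entries(rB[p, p])
    partial_cor(stats::cor(ra, rbp), rac, stats::cor(rbp, rc))
  }
  if (exhaustive) {
    stats_all <- vapply(all_permutations(n), stat_for, numeric(1))
    p <- exact_pvalue(stats_all, r_obs, tail)
    n_used <- length(stats_all)
  } else if (n_perm == 0) {
    p <- NA_real_; n_used <- 0L
  } else {
    stats_perm <- with_substream(seed, "partial_mantel", {
      vapply(seq_len(n_perm), function(i) stat_for(sample.int(n)), numeric(1))
    })
    p <- perm_pvalue(stats_perm, r_obs, tail)
    n_used <- n_perm
  }
  structure(list(r = r_obs, p = p, n_perm = n_used, seed = as.integer(seed),
                 tail = tail, exhaustive = exhaustive),
            class = "mantel_outcome")
}

anosim_stat <- function(rD, groups) {
  same <- outer(groups, groups, "==")
  within <- rD[upper.tri(rD) & same]
  between <- rD[upper.tri(rD) & !same]
  n <- length(groups)
  (mean(between) - mean(within)) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all pairwise dissimilarities (mid-ranks on ties) and contrasts mean
#' between-group against mean within-group rank, scaled by `n(n-1)/4` so that
#' R lies in [-1, 1]. Significance by permuting group labels; `exhaustive`
#' enumerates the distinct relabelings of the label multiset.
#'
#' @param D Distance matrix.
#' @param groups Group label per sample (>= 2 groups, each of size >= 2).
#' @inheritParams mantel_test
#' @return An `anosim_outcome`: list with `R`, `p`, `n_perm`, `seed`.
#' @export
anosim_test <- function(D, groups, n_perm = 999, seed = 1L,
                        exhaustive = FALSE) {
  D <- as_square_distance(D)
  groups <- as.character(groups)
  if (length(groups) != nrow(D)) stop("groups must match the matrix dimension")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("ANOSIM needs at least two groups")
  if (any(sizes < 2)) {
    stop("every group needs >= 2 samples; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  n <- nrow(D)
  rD <- rank_matrix(D)
  R_obs <- anosim_stat(rD, groups)
  if (exhaustive) {
    perms <- all_permutations(n)
    keys <- new.env(hash = TRUE)
    stats_all <- numeric(0)
    for (p in perms) {
      g <- groups[p]
      key <- paste(g, collapse = "\r")
      if (is.null(keys[[key]])) {
        keys[[key]] <- TRUE
        stats_all <- c(stats_all, anosim_stat(rD, g))
      }
    }
    p_val <- exact_pvalue(stats_all, R_obs, "greater")
    n_used <- length(stats_all)
  } else if (n_perm == 0) {
    p_val <- NA_real_; n_used <- 0L
  } else {
    stats_perm <- with_substream(seed, "anosim", {
      vapply(seq_len(n_perm), function(i) {
        anosim_stat(rD, groups[sample.int(n)])
      }, numeric(1))
    })
    p_val <- perm_pvalue(stats_perm, R_obs, "greater")
    n_used <- n_perm
  }
  structure(list(R = R_obs, p = p_val, n_perm = n_used,
                 seed = as.integer(seed)),
            class = "anosim_outcome")
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Gower-centres `-D^2/2` and partitions the total sum of squares
#' sequentially (Type I, order of entry) across the model terms by projecting
#' onto nested design-matrix column spaces, exactly as a distance-based
#' `adonis`-style analysis. Per-term R2 values plus the residual sum to 1.
#' Significance per term by permuting the sample identities of `D`.
#'
#' @param D Distance matrix.
#' @param data Data frame of per-sample covariates/factors, rows aligned to
#'   `D`'s labels.
#' @param terms Character vector of column names of `data`, in entry order.
#' @inheritParams mantel_test
#' @return A `permanova_outcome` with a per-term table (`Df`, `SS`, `R2`,
#'   `F`, `p`), `residual_r2`, `n_perm`, `seed`, and any dropped collinear
#'   columns in `dropped`.
#' @export
permanova <- function(D, data, terms, n_perm = 999, seed = 1L) {
  D <- as_square_distance(D)
  n <- nrow(D)
  if (nrow(data) != n) stop("data must have one row per sample")
  if (!all(terms %in% names(data))) {
    stop("terms not found in data: ",
         paste(setdiff(terms, names(data)), collapse = ", "))
  }
  G <- gower_center(D)
  ss_total <- sum(diag(G))

  if (length(terms) == 0) {    # intercept-only model: everything is residual
    return(structure(list(
      table = data.frame(term = character(0), Df = integer(0),
                         SS = numeric(0), R2 = numeric(0), F = numeric(0),
                         p = numeric(0)),
      residual_ss = ss_total, residual_r2 = 1, residual_df = n - 1L,
      total_ss = ss_total, n_perm = n_perm, seed = as.integer(seed),
      dropped = character(0)), class = "permanova_outcome"))
  }

  # nested QR bases: Q_j spans intercept + terms 1..j
  qs <- vector("list", length(terms) + 1L)
  X <- matrix(1, n, 1)
  qr0 <- qr(X)
  qs[[1]] <- qr.Q(qr0)[, seq_len(qr0$rank), drop = FALSE]
  dropped <- character(0)
  dfs <- integer(length(terms))
  for (j in seq_along(terms)) {
    mm <- stats::model.matrix(stats::reformulate(terms[seq_len(j)]), data)
    qrj <- qr(mm)
    if (qrj$rank < ncol(mm)) {
      bad <- colnames(mm)[qrj$pivot[-seq_len(qrj$rank)]]
      newbad <- setdiff(bad, dropped)
      if (length(newbad)) {
        warning("dropping collinear design columns: ",
                paste(newbad, collapse = ", "))
        dropped <- c(dropped, newbad)
      }
    }
    qs[[j + 1L]] <- qr.Q(qrj)[, seq_len(qrj$rank), drop = FALSE]
    dfs[j] <- qrj$rank - ncol(qs[[j]])
  }
  # terms fully aliased by earlier ones contribute 0 df; they stay in the
  # table with zero SS and an undefined F
  live <- dfs > 0
  rank_full <- ncol(qs[[length(qs)]])
  df_res <- n - rank_full
  if (df_res <= 0) stop("model saturates the samples (no residual df)")

  term_ss <- function(Gm) {
    tr <- vapply(qs, function(Q) sum(crossprod(Q, Gm) * t(Q)), numeric(1))
    diff(tr)
  }
  ss <- term_ss(G)
  # the intercept projection of a Gower-centred G is zero, so the residual
  # is total minus the term sums
  ss_res <- ss_total - sum(ss)
  f_obs <- ifelse(live, (ss / pmax(dfs, 1)) / (ss_res / df_res), NA_real_)

  if (n_perm > 0) {
    exceed <- integer(length(terms))
    with_substream(seed, "permanova", {
      for (i in seq_len(n_perm)) {
        pp <- sample.int(n)
        Gp <- G[pp, pp]
        ssp <- term_ss(Gp)
        fp <- (ssp / pmax(dfs, 1)) / ((ss_total - sum(ssp)) / df_res)
        exceed <- exceed + ifelse(live, fp >= f_obs - 1e-12, 0L)
      }
    })
    p <- ifelse(live, (1 + exceed) / (1 + n_perm), NA_real_)
  } else {
    p <- rep(NA_real_, length(terms))
  }
  tab <- data.frame(term = terms, Df = dfs, SS = ss, R2 = ss / ss_total,
                    F = f_obs, p = p, stringsAsFactors = FALSE)
  structure(list(table = tab, residual_ss = ss_res,
                 residual_r2 = ss_res / ss_total, residual_df = df_res,
                 total_ss = ss_total, n_perm = n_perm,
                 seed = as.integer(seed), dropped = dropped),
            class = "permanova_outcome")
}

gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Multivariate Mantel correlogram
#'
#' Cuts the spatial distances into equal-frequency classes and, for each
#' class, runs a Mantel test of the community distances against the binary
#' within-class membership matrix. The statistic is reported sign-flipped so
#' that positive values mean spatial autocorrelation (samples in the same
#' distance class are compositionally more similar than average). P-values
#' receive a progressive Holm correction; classes whose lower bound exceeds
#' the median spatial distance are flagged unreliable.
#'
#' @param community_D,space_D Distance matrices with matching labels.
#' @param n_classes Number of equal-frequency distance classes (>= 2).
#' @inheritParams mantel_test
#' @return A `correlogram_outcome`: data frame `classes` with bounds,
#'   pair counts, `r`, raw and corrected p, and a `reliable` flag.
#' @export
mantel_correlogram <- function(community_D, space_D, n_classes = 6,
                               n_perm = 999, seed = 1L) {
  if (n_classes < 2) stop("need at least 2 distance classes")
  community_D <- as_square_distance(community_D, "community_D")
  space_D <- as_square_distance(space_D, "space_D")
  check_same_labels(community_D, space_D)
  n <- nrow(space_D)
  sd_up <- upper_entries(space_D)
  breaks <- unique(stats::quantile(sd_up, probs = seq(0, 1, length.out = n_classes + 1)))
  if (length(breaks) < 3) stop("spatial distances too discrete for the requested classes")
  cls <- cut(sd_up, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  k <- length(breaks) - 1L
  rc <- rank(upper_entries(community_D))
  med <- stats::median(sd_up)

  r <- p_raw <- numeric(k)
  n_pairs <- integer(k)
  ut <- upper.tri(space_D)
  for (j in seq_len(k)) {
    ind_up <- as.numeric(cls == j)
    n_pairs[j] <- sum(ind_up)
    # indicator as a full symmetric matrix so the permutation acts on samples
    M <- matrix(0, n, n)
    M[ut] <- ind_up
    M <- M + t(M)
    r_obs <- -stats::cor(rc, ind_up)
    r[j] <- r_obs
    stats_perm <- with_substream(seed, paste0("correlogram_class", j), {
      vapply(seq_len(n_perm), function(i) {
        pp <- sample.int(n)
        -stats::cor(rc, upper_entries(M[pp, pp]))
      }, numeric(1))
    })
    p_raw[j] <- perm_pvalue(stats_perm, r_obs, "two_sided")
  }
  p_corr <- vapply(seq_len(k), function(j) {
    stats::p.adjust(p_raw[seq_len(j)], method = "holm")[j]
  }, numeric(1))
  classes <- data.frame(
    class = seq_len(k), lower = breaks[-length(breaks)], upper = breaks[-1],
    n_pairs = n_pairs, r = r, p = p_raw, p_corrected = p_corr,
    reliable = breaks[-length(breaks)] <= med
  )
  structure(list(classes = classes, n_perm = n_perm, seed = as.integer(seed)),
            class = "correlogram_outcome")
}
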