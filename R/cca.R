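#' Canonical correspondence analysis
#'
#' Constrained ordination of a count table on environmental covariates under
#' the chi-square metric. The counts are normalized to a grand total of 1;
#' the chi-square standardized residual matrix
#' `Qbar = diag(r)^(-1/2) (P - r c') diag(c)^(-1/2)` is projected, with row
#' weights `r`, onto the span of the (weighted-centred, standardized)
#' constraint columns; the SVD of the projection yields the constrained
#' axes. Total inertia is `sum(Qbar^2)` — identically the Pearson chi-square
#' statistic of the table divided by its grand total — and splits exactly
#' into constrained plus unconstrained inertia.
#'
#' @param community A `rarefied_community`, `community_matrix`, or counts
#'   matrix (samples x OTUs). All-zero rows/columns are dropped with a
#'   message.
#' @param constraints Data frame of per-sample covariates (factors allowed),
#'   rows aligned with the community samples.
#' @return A `cca_model`: inertias, `constrained_proportion`, per-axis
#'   `eigenvalues`, `site_scores`, `species_scores`, `biplot_scores`, and
#'   bookkeeping (`dropped_rows`, `dropped_cols`, `q` constrained df).
#' @export
cca_fit <- function(community, constraints) {
  Y <- count_input(community)
  if (!is.data.frame(constraints)) constraints <- as.data.frame(constraints)
  if (nrow(constraints) != nrow(Y)) {
    stop("constraints must have one row per community sample")
  }
  keep_r <- rowSums(Y) > 0
  keep_c <- colSums(Y) > 0
  dropped_rows <- rownames(Y)[!keep_r]
  dropped_cols <- colnames(Y)[!keep_c]
  if (length(dropped_rows) || length(dropped_cols)) {
    message("cca_fit: dropping ", length(dropped_rows), " all-zero rows and ",
            length(dropped_cols), " all-zero columns")
  }
  Y <- Y[keep_r, keep_c, drop = FALSE]
  constraints <- constraints[keep_r, , drop = FALSE]
  n <- nrow(Y)

  P <- Y / sum(Y)
  r <- rowSums(P); cc <- colSums(P)
  Qbar <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  total <- sum(Qbar^2)

  # design matrix: weighted-centred and standardized covariate columns
  X <- stats::model.matrix(~., data = constraints)[, -1, drop = FALSE]
  X <- sweep(X, 2, colSums(X * r))          # weighted centring
  wsd <- sqrt(colSums(X^2 * r))
  ok <- wsd > 1e-10
  if (!all(ok)) {
    warning("dropping constant constraint columns: ",
            paste(colnames(X)[!ok], collapse = ", "))
  }
  X <- sweep(X[, ok, drop = FALSE], 2, wsd[ok], "/")
  Xw <- X * sqrt(r)
  qrx <- qr(Xw)
  if (qrx$rank < ncol(Xw)) {
    bad <- colnames(Xw)[qrx$pivot[-seq_len(qrx$rank)]]
    warning("dropping collinear constraint columns: ",
            paste(bad, collapse = ", "))
  }
  Qx <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  q <- qrx$rank

  fitted <- Qx %*% crossprod(Qx, Qbar)
  constrained <- sum(fitted^2)
  sv <- svd(fitted)
  pos <- sv$d^2 > max(1e-12, 1e-10 * max(sv$d^2))
  eig <- sv$d[pos]^2
  naxes <- sum(pos)

  if (naxes > 0) {
    # weighted site scores (linear-combination scores) and species scores,
    # vegan-like scaling: species scaled by singular values
    site <- sweep(sv$u[, pos, drop = FALSE], 1, sqrt(r), "/")
    species <- sweep(sweep(sv$v[, pos, drop = FALSE], 1, sqrt(cc), "/"),
                     2, sv$d[pos], "*")
    dimnames(site) <- list(rownames(Y), paste0("CCA", seq_len(naxes)))
    dimnames(species) <- list(colnames(Y), paste0("CCA", seq_len(naxes)))
    # biplot scores: weighted correlations of constraints with site scores
    bip <- crossprod(X * r, site)
    bipn <- sqrt(colSums(X^2 * r)) %o% sqrt(colSums(site^2 * r))
    biplot_scores <- bip / bipn
  } else {
    site <- matrix(numeric(0), n, 0, dimnames = list(rownames(Y), NULL))
    species <- matrix(numeric(0), ncol(Y), 0,
                      dimnames = list(colnames(Y), NULL))
    biplot_scores <- matrix(numeric(0), ncol(X), 0,
                            dimnames = list(colnames(X), NULL))
  }

  structure(list(
    total_inertia = total, constrained_inertia = constrained,
    unconstrained_inertia = total - constrained,
    constrained_proportion = constrained / total,
    eigenvalues = eig, q = q, n = n,
    site_scores = site, species_scores = species,
    biplot_scores = biplot_scores,
    dropped_rows = dropped_rows, dropped_cols = dropped_cols,
    model_chi2 = NA_real_, model_f = NA_real_, model_p = NA_real_,
    n_perm = 0L, seed = NA_integer_
  ), class = "cca_model")
}

#' Permutation test of CCA model significance
#'
#' Pseudo-F is `(constrained/q) / (unconstrained/(n - q - 1))` with `q` the
#' constrained degrees of freedom. The null distribution permutes the rows
#' of the constraint table against the community; the p-value follows the
#' add-one rule.
#'
#' @param model A fitted `cca_model`.
#' @param community,constraints The inputs that produced `model`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return The model updated with `model_chi2` (the constrained inertia),
#'   `model_f`, `model_p`, `n_perm`, `seed`.
#' @export
cca_permutation_test <- function(model, community, constraints,
                                 n_perm = 999, seed = 1L) {
  stopifnot(inherits(model, "cca_model"))
  if (model$unconstrained_inertia <= 1e-12) {
    stop("saturated model: unconstrained inertia is zero, pseudo-F undefined")
  }
  n <- model$n; q <- model$q
  if (n - q - 1 <= 0) stop("no residual degrees of freedom")
  f_of <- function(fit) {
    (fit$constrained_inertia / q) /
      (fit$unconstrained_inertia / (n - q - 1))
  }
  f_obs <- f_of(model)
  if (!is.data.frame(constraints)) constraints <- as.data.frame(constraints)
  Y <- count_input(community)
  keep_r <- rowSums(Y) > 0
  constraints <- constraints[keep_r, , drop = FALSE]
  Y <- Y[keep_r, colSums(Y) > 0, drop = FALSE]
  exceed <- 0L
  with_substream(seed, "cca_perm", {
    for (i in seq_len(n_perm)) {
      cp <- constraints[sample.int(nrow(constraints)), , drop = FALSE]
      fit <- suppressWarnings(suppressMessages(cca_fit(Y, cp)))
      if (f_of(fit) >= f_obs - 1e-12) exceed <- exceed + 1L
    }
  })
  model$model_chi2 <- model$constrained_inertia
  model$model_f <- f_obs
  model$model_p <- (1 + exceed) / (1 + n_perm)
  model$n_perm <- as.integer(n_perm)
  model$seed <- as.integer(seed)
  model
}
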