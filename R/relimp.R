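# LMG relative importance: attribute a regression's R^2 to its predictors by
# averaging each predictor's sequential R^2 gain over every ordering in
# which it can enter the model. Computed from all-subsets R^2 with the
# standard combinatorial weights k!(p-1-k)!/p!, which is algebraically the
# all-orderings average but needs 2^p fits instead of p! * p.

# R^2 of y on the columns of X listed in `idx`, tolerant of rank deficiency
subset_r2 <- function(y, X, idx) {
  ssy <- sum((y - mean(y))^2)
  if (ssy == 0) return(0)
  if (length(idx) == 0) return(0)
  Xs <- cbind(1, X[, idx, drop = FALSE])
  res <- qr.resid(qr(Xs), y)
  max(0, 1 - sum(res^2) / ssy)
}

#' LMG decomposition of regression R-squared
#'
#' For each predictor, the LMG share is the average over all `p!` predictor
#' orderings of the increase in R^2 when that predictor enters the model.
#' Shares are non-negative and sum exactly to the full-model R^2. Orderings
#' are enumerated exactly (via the all-subsets identity); `p <= 8` is
#' enforced. Rank-deficient predictor sets are handled by least-squares
#' projection, so duplicated predictors split their shared contribution
#' evenly rather than erroring.
#'
#' @param y Numeric response.
#' @param X Numeric matrix or data frame of predictors (columns named).
#' @return An `lmg_decomposition`: list with `predictors`, `lmg_share`,
#'   `model_r2`, `n_obs`, and a `degenerate` flag (zero-variance response or
#'   predictor: all shares 0 by convention).
#' @export
lmg_decompose <- function(y, X) {
  X <- as.matrix(as.data.frame(X))
  p <- ncol(X)
  n <- length(y)
  if (p > 8) stop("LMG enumeration limited to 8 predictors")
  if (nrow(X) != n) stop("y and X must have matching rows")
  if (n <= p + 1) stop("need n_obs > n_predictors + 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))

  degenerate <- stats::sd(y) == 0 || any(apply(X, 2, stats::sd) == 0)
  if (degenerate) {
    return(structure(list(predictors = colnames(X),
                          lmg_share = stats::setNames(numeric(p), colnames(X)),
                          model_r2 = 0, n_obs = n, degenerate = TRUE),
                     class = "lmg_decomposition"))
  }

  # R^2 for every subset, indexed by bitmask
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
    r2[mask + 1L] <- subset_r2(y, X, idx)
  }
  wts <- factorial(0:(p - 1)) * factorial((p - 1):0) / factorial(p)
  shares <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(2^p - 1)) {
      if (bitwAnd(mask, bit) == 0L) {
        k <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
        shares[j] <- shares[j] +
          wts[k + 1L] * (r2[bitwOr(mask, bit) + 1L] - r2[mask + 1L])
      }
    }
  }
  shares <- pmax(shares, 0)
  structure(list(predictors = colnames(X),
                 lmg_share = stats::setNames(shares, colnames(X)),
                 model_r2 = r2[2^p], n_obs = n, degenerate = FALSE),
            class = "lmg_decomposition")
}

#' Sliding windows of LMG decompositions along an edaphic gradient
#'
#' Orders the samples by pH or EC (ties broken by the other edaphic
#' variable, then by sample id, so the ordering is total and input row order
#' is irrelevant), slides a fixed-size window one step at a time, and fits
#' `observed_species ~ ph + ec` with an LMG decomposition inside each
#' window. Windows where the response or a predictor has zero variance are
#' flagged and contribute zero shares.
#'
#' @param samples Data frame with columns `sample_id`, `ph`, `ec` and the
#'   response column (default `observed_species`).
#' @param ordering_variable `"ph"` or `"ec"`.
#' @param window_size,step Window membership count and slide increment.
#' @param response Name of the response column.
#' @return A `window_profile`: list with `ordering_variable`, `window_size`,
#'   `step`, and `windows` — a list of records carrying `index`,
#'   `sample_ids`, `span` (lo/hi of the ordering variable), and the
#'   `lmg_decomposition`.
#' @export
sliding_windows <- function(samples, ordering_variable = c("ph", "ec"),
                            window_size = 10, step = 1,
                            response = "observed_species") {
  ordering_variable <- match.arg(ordering_variable)
  need <- c("sample_id", "ph", "ec", response)
  if (!all(need %in% names(samples))) {
    stop("samples must contain columns: ", paste(need, collapse = ", "))
  }
  samples <- samples[stats::complete.cases(samples[, need]), , drop = FALSE]
  n <- nrow(samples)
  if (n < window_size) stop("fewer complete samples (", n,
                            ") than window_size (", window_size, ")")
  other <- if (ordering_variable == "ph") "ec" else "ph"
  ord <- order(samples[[ordering_variable]], samples[[other]],
               samples$sample_id)
  samples <- samples[ord, , drop = FALSE]

  starts <- seq(1L, n - window_size + 1L, by = step)
  windows <- lapply(seq_along(starts), function(w) {
    rows <- samples[starts[w]:(starts[w] + window_size - 1L), , drop = FALSE]
    dec <- lmg_decompose(rows[[response]], rows[, c("ph", "ec")])
    g <- rows[[ordering_variable]]
    list(index = w, sample_ids = rows$sample_id,
         span = c(lo = min(g), hi = max(g)), lmg = dec,
         flagged = dec$degenerate)
  })
  structure(list(ordering_variable = ordering_variable,
                 window_size = as.integer(window_size),
                 step = as.integer(step), windows = windows),
            class = "window_profile")
}

#' Normalize a window profile onto fixed-width gradient bins
#'
#' Partitions the gradient axis into contiguous bins of `bin_width` native
#' units (defaults in this pipeline: 5 uS/cm for EC, 0.05 for pH) and
#' averages, within each bin, the per-predictor LMG shares of every window
#' whose span overlaps the bin. Bins no window touches are reported with
#' `n_windows = 0` and `NA` means.
#'
#' @param profile A `window_profile`.
#' @param bin_width Bin width in the ordering variable's native units.
#' @return An `importance_profile` data frame: `bin_lo`, `bin_hi`,
#'   `mean_share_ph`, `mean_share_ec`, `mean_r2`, `n_windows`, with the
#'   gradient name in attribute `gradient`.
#' @export
normalize_profile <- function(profile, bin_width) {
  stopifnot(inherits(profile, "window_profile"), bin_width > 0)
  spans <- t(vapply(profile$windows, function(w) w$span, numeric(2)))
  share_ph <- vapply(profile$windows, function(w) w$lmg$lmg_share[["ph"]], numeric(1))
  share_ec <- vapply(profile$windows, function(w) w$lmg$lmg_share[["ec"]], numeric(1))
  r2 <- vapply(profile$windows, function(w) w$lmg$model_r2, numeric(1))

  lo <- floor(min(spans[, 1]) / bin_width) * bin_width
  hi <- ceiling(max(spans[, 2]) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  nb <- length(edges) - 1L
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    mean_share_ph = NA_real_, mean_share_ec = NA_real_,
                    mean_r2 = NA_real_, n_windows = 0L)
  for (b in seq_len(nb)) {
    olap <- spans[, 2] >= out$bin_lo[b] & spans[, 1] < out$bin_hi[b]
    # point spans sitting exactly on the upper edge of the last bin
    if (b == nb) olap <- olap | (spans[, 1] == out$bin_hi[b])
    if (any(olap)) {
      out$mean_share_ph[b] <- mean(share_ph[olap])
      out$mean_share_ec[b] <- mean(share_ec[olap])
      out$mean_r2[b] <- mean(r2[olap])
      out$n_windows[b] <- sum(olap)
    }
  }
  attr(out, "gradient") <- profile$ordering_variable
  attr(out, "bin_width") <- bin_width
  class(out) <- c("importance_profile", class(out))
  out
}

# changepoint along the bin sequence: the boundary that best separates
# pH-dominant bins (below) from EC-dominant bins (above)
profile_crossover <- function(profile) {
  occ <- profile[profile$n_windows > 0, , drop = FALSE]
  if (!nrow(occ)) return(NA_real_)
  ec_dom <- occ$mean_share_ec > occ$mean_share_ph
  nb <- nrow(occ)
  bounds <- c(occ$bin_lo[1], occ$bin_hi)
  score <- vapply(seq_len(nb + 1L), function(cut) {
    below <- seq_len(nb) < cut
    sum(!ec_dom[below]) + sum(ec_dom[!below])
  }, numeric(1))
  bounds[which.max(score)]
}

#' Dominance intervals and crossover of edaphic importance profiles
#'
#' Reports, for each normalized profile, the contiguous runs of occupied
#' bins where one predictor's mean LMG share exceeds the other's, in native
#' gradient units, plus a changepoint estimate of where dominance switches
#' from pH to EC (the bin boundary minimizing misclassified bins).
#'
#' @param ph_profile,ec_profile `importance_profile`s along the pH and EC
#'   gradients.
#' @return A `dominance_summary` list: per-gradient interval tables
#'   (`gradient`, `lo`, `hi`, `dominant`) and `crossover` estimates.
#' @export
dominance_summary <- function(ph_profile, ec_profile) {
  one <- function(profile, gradient) {
    occ <- profile[profile$n_windows > 0, , drop = FALSE]
    if (!nrow(occ)) {
      return(data.frame(gradient = character(0), lo = numeric(0),
                        hi = numeric(0), dominant = character(0)))
    }
    dom <- ifelse(occ$mean_share_ec > occ$mean_share_ph, "ec",
                  ifelse(occ$mean_share_ph > occ$mean_share_ec, "ph", "tie"))
    # runs break on dominance change or a gap in occupied bins
    newrun <- c(TRUE, dom[-1] != dom[-length(dom)] |
                  occ$bin_lo[-1] != occ$bin_hi[-nrow(occ)])
    run_id <- cumsum(newrun)
    do.call(rbind, lapply(split(seq_len(nrow(occ)), run_id), function(ix) {
      data.frame(gradient = gradient, lo = occ$bin_lo[ix[1]],
                 hi = occ$bin_hi[ix[length(ix)]], dominant = dom[ix[1]],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    intervals = rbind(one(ph_profile, "ph"), one(ec_profile, "ec")),
    crossover = c(ph = profile_crossover(ph_profile),
                  ec = profile_crossover(ec_profile))
  ), class = "dominance_summary")
}
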