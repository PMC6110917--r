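test_that("LMG shares honour orthogonality and symmetry anchors", {
  # orthogonal, centred predictors: share = marginal R-squared
  x1 <- rep(c(-1, 1), 10)
  x2 <- rep(c(-1, -1, 1, 1), 5)
  set.seed(3)
  y <- 0.8 * x1 + 0.3 * x2 + rnorm(20, 0, 0.5)
  dec <- lmg_decompose(y, cbind(x1 = x1, x2 = x2))
  expect_equal(unname(dec$lmg_share["x1"]),
               summary(lm(y ~ x1))$r.squared, tolerance = 1e-9)
  expect_equal(unname(dec$lmg_share["x2"]),
               summary(lm(y ~ x2))$r.squared, tolerance = 1e-9)
  # duplicated predictor: the joint contribution splits evenly
  dup <- lmg_decompose(y, cbind(a = x1, b = x1))
  r2 <- summary(lm(y ~ x1))$r.squared
  expect_equal(unname(dup$lmg_share), c(r2 / 2, r2 / 2), tolerance = 1e-9)
})

test_that("LMG equals the all-orderings brute force for p in 2:4", {
  for (p in 2:4) {
    set.seed(p * 10)
    n <- 40
    X <- matrix(rnorm(n * p), n,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    X[, p] <- X[, 1] * 0.6 + X[, p] * 0.8   # induce correlation
    y <- X %*% rnorm(p) + rnorm(n)
    dec <- lmg_decompose(y, X)
    oracle <- oracle_lmg(y, X)
    expect_equal(dec$lmg_share, oracle, tolerance = 1e-9)
    expect_equal(sum(dec$lmg_share), dec$model_r2, tolerance = 1e-9)
    expect_true(all(dec$lmg_share >= 0))
  }
  expect_error(lmg_decompose(rnorm(50), matrix(rnorm(50 * 9), 50)),
               "8 predictors")
  expect_error(lmg_decompose(rnorm(3), matrix(rnorm(6), 3)), "n_obs")
})

make_window_data <- function(n, seed = 1, rich = NULL) {
  set.seed(seed)
  d <- data.frame(sample_id = sprintf("s%03d", 1:n),
                  ph = runif(n, 8, 10.5), ec = runif(n, 50, 2000))
  d$observed_species <- if (is.null(rich)) {
    150 - 0.03 * d$ec + rnorm(n, 0, 5)
  } else rich(d)
  d
}

test_that("sliding windows have the promised shape and membership", {
  d <- make_window_data(30, seed = 2)
  prof <- sliding_windows(d, "ec", window_size = 10, step = 1)
  expect_length(prof$windows, 21)
  expect_true(all(vapply(prof$windows,
                         function(w) length(w$sample_ids), numeric(1)) == 10))
  # consecutive windows share window_size - step members
  shared <- length(intersect(prof$windows[[1]]$sample_ids,
                             prof$windows[[2]]$sample_ids))
  expect_equal(shared, 9)
  # each sample appears in min(i, ws, N - i + 1, N - ws + 1) windows
  ord <- order(d$ec, d$ph, d$sample_id)
  counts <- table(unlist(lapply(prof$windows, `[[`, "sample_ids")))
  for (i in c(1, 5, 15, 30)) {
    expect_equal(unname(counts[d$sample_id[ord[i]]]),
                 min(i, 10, 30 - i + 1, 21))
  }
  # input row order is irrelevant: sorting is internal and total
  prof2 <- sliding_windows(d[sample(30), ], "ec")
  expect_equal(lapply(prof2$windows, `[[`, "sample_ids"),
               lapply(prof$windows, `[[`, "sample_ids"))
  expect_error(sliding_windows(d[1:5, ], "ec"), "window_size")
})

test_that("noiseless single-driver and constant responses are recognized", {
  d <- make_window_data(25, seed = 3, rich = function(d) 200 - 0.05 * d$ec)
  prof <- sliding_windows(d, "ec")
  for (w in prof$windows) {
    expect_equal(unname(w$lmg$lmg_share["ec"] + w$lmg$lmg_share["ph"]),
                 w$lmg$model_r2, tolerance = 1e-9)
    expect_equal(w$lmg$model_r2, 1, tolerance = 1e-9)
    expect_lt(unname(w$lmg$lmg_share["ph"]), 0.35)
    expect_gt(unname(w$lmg$lmg_share["ec"]), 0.65)
  }
  dflat <- make_window_data(15, seed = 4, rich = function(d) rep(100, nrow(d)))
  proff <- sliding_windows(dflat, "ph")
  expect_true(all(vapply(proff$windows, `[[`, logical(1), "flagged")))
  expect_true(all(vapply(proff$windows,
                         function(w) w$lmg$model_r2, numeric(1)) == 0))
})

test_that("bin normalization averages overlapping windows", {
  d <- make_window_data(12, seed = 5)
  prof <- sliding_windows(d, "ec", window_size = 10)
  # 3 windows; force all spans into one wide bin
  np <- normalize_profile(prof, bin_width = 5000)
  occ <- np[np$n_windows > 0, ]
  expect_equal(nrow(occ), 1)
  shares <- vapply(prof$windows, function(w) w$lmg$lmg_share[["ec"]],
                   numeric(1))
  expect_equal(occ$mean_share_ec, mean(shares), tolerance = 1e-12)
  # with step > window_size the spans are disjoint and the gradient gap
  # between them yields empty bins
  d2 <- make_window_data(20, seed = 7)
  prof2 <- sliding_windows(d2, "ec", window_size = 5, step = 12)
  np2 <- normalize_profile(prof2, bin_width = 5)
  expect_true(any(np2$n_windows == 0))
  expect_true(all(abs(np2$bin_hi - np2$bin_lo - 5) < 1e-9))
  expect_true(all(is.na(np2$mean_share_ec[np2$n_windows == 0])))
})

test_that("dominance intervals and crossover track the configured regime", {
  # all-EC-dominant profile: one interval
  prof <- data.frame(bin_lo = seq(0, 40, 10), bin_hi = seq(10, 50, 10),
                     mean_share_ph = 0.1, mean_share_ec = 0.5,
                     mean_r2 = 0.6, n_windows = 2L)
  attr(prof, "gradient") <- "ec"
  class(prof) <- c("importance_profile", class(prof))
  ds <- dominance_summary(prof, prof)
  expect_equal(nrow(ds$intervals[ds$intervals$gradient == "ec", ]), 1)
  expect_equal(ds$intervals$dominant[1], "ec")
  # alternating dominance: one interval per bin
  alt <- prof
  alt$mean_share_ph <- c(0.5, 0.1, 0.5, 0.1, 0.5)
  alt$mean_share_ec <- c(0.1, 0.5, 0.1, 0.5, 0.1)
  ds2 <- dominance_summary(alt, alt)
  expect_equal(nrow(ds2$intervals[ds2$intervals$gradient == "ph", ]), 5)
  # dual-regime fixture: crossover lands near the breakpoint
  d <- simulate_dual_regime(n = 200, breakpoint = 500, seed = 6)
  wp <- sliding_windows(d, "ec")
  np <- normalize_profile(wp, bin_width = 25)
  ds3 <- dominance_summary(np, np)
  expect_lt(abs(ds3$crossover[["ec"]] - 500), 2 * 25)
})
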