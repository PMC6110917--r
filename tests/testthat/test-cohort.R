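test_that("Kruskal-Wallis matches the rank formula and handles ties", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                        rep(c("a", "b", "c"), each = 3))
  expect_equal(res$chi2, 7.2)  # hand-ranked: 12/(9*10) * 3*(9+0+9)
  expect_equal(res$df, 2)
  # fully tied data carry no signal
  flat <- kruskal_wallis(rep(5, 12), rep(c("a", "b", "c"), 4))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  expect_true(all(flat$letters == "a"))
  # rank basis: strictly monotone transforms leave H unchanged
  x <- c(3, 9, 1, 7, 4, 12, 8, 2, 11, 5)
  g <- rep(c("u", "v"), 5)
  expect_equal(kruskal_wallis(x, g)$chi2, kruskal_wallis(exp(x), g)$chi2)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("letter display separates exactly the significant pairs", {
  pw <- data.frame(group1 = c("b", "c", "c"), group2 = c("a", "a", "b"),
                   p = c(0.20, 0.01, 0.03))
  lt <- compact_letters(c("a", "b", "c"), pw, alpha = 0.05)
  # a and b share a letter; c shares with neither
  expect_true(grepl(lt[["a"]], lt[["b"]]) ||
                any(strsplit(lt[["a"]], "")[[1]] %in%
                      strsplit(lt[["b"]], "")[[1]]))
  expect_false(any(strsplit(lt[["c"]], "")[[1]] %in%
                     strsplit(lt[["a"]], "")[[1]]))
  expect_false(any(strsplit(lt[["c"]], "")[[1]] %in%
                     strsplit(lt[["b"]], "")[[1]]))
  # chain case: a < c significant, b bridges both
  pw2 <- data.frame(group1 = c("b", "c", "c"), group2 = c("a", "a", "b"),
                    p = c(0.5, 0.01, 0.5))
  lt2 <- compact_letters(c("a", "b", "c"), pw2, alpha = 0.05)
  expect_true(any(strsplit(lt2[["b"]], "")[[1]] %in%
                    strsplit(lt2[["a"]], "")[[1]]))
  expect_true(any(strsplit(lt2[["b"]], "")[[1]] %in%
                    strsplit(lt2[["c"]], "")[[1]]))
  expect_false(any(strsplit(lt2[["a"]], "")[[1]] %in%
                     strsplit(lt2[["c"]], "")[[1]]))
})

test_that("post hoc letters agree with the pairwise decisions on data", {
  set.seed(8)
  vals <- c(rnorm(15, 0), rnorm(15, 0.2), rnorm(15, 6))
  g <- rep(c("a", "b", "c"), each = 15)
  res <- kruskal_wallis(vals, g)
  for (i in seq_len(nrow(res$pairwise))) {
    share <- any(strsplit(res$letters[[res$pairwise$group1[i]]], "")[[1]] %in%
                   strsplit(res$letters[[res$pairwise$group2[i]]], "")[[1]])
    expect_equal(share, res$pairwise$p[i] >= res$alpha)
  }
})

test_that("Spearman grid: anchors and Benjamini-Hochberg behaviour", {
  # BH step-up on the worked example
  expect_equal(p.adjust(c(0.005, 0.01, 0.03, 0.04), "BH"),
               c(0.02, 0.02, 0.04, 0.04))
  # brute-force BH oracle: adjusted_i = min over j >= i (sorted) of p_j*m/j
  p <- c(0.011, 0.2, 0.04, 0.003)
  o <- order(p); m <- length(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  expect_equal(p.adjust(p, "BH"), adj)

  set.seed(9)
  d <- data.frame(basin = rep(c("X", "Y"), each = 10),
                  dist_from_trough = runif(20), ph = runif(20, 8, 10),
                  ec = runif(20, 100, 900))
  d$idx <- d$ec  # a row variable duplicating a column
  d$noise <- rnorm(20)
  g <- spearman_grid(d, rows = c("idx", "noise"), scope = "regional")
  expect_equal(g$rho[g$row == "idx" & g$col == "ec"], 1)
  # adjusted p never falls below raw, never above one, monotone in raw order
  expect_true(all(g$p_adjusted >= g$p_raw - 1e-12))
  expect_true(all(g$p_adjusted <= 1))
  one <- spearman_grid(d, rows = "noise", cols = "ph", scope = "regional")
  expect_equal(one$p_adjusted, one$p_raw)
  gb <- spearman_grid(d, rows = "noise", scope = "per_basin")
  expect_setequal(unique(gb$scope_cell), c("X", "Y"))
  expect_error(spearman_grid(d[1:3, ], rows = "noise"), "fewer than 5")
})

test_that("phylum regressions recover exact and compositional structure", {
  x <- seq(0.1, 0.5, length.out = 10)
  # exact fit triggers lm's perfect-fit warning; the estimates are the point
  res <- suppressWarnings(phylum_regressions(data.frame(A = x, B = 2 * x),
                                             cbind("A", "B")))
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$r2, 1, tolerance = 1e-12)
  # two phyla trading off under a constant sum regress negatively
  set.seed(10)
  a <- runif(12, 0.2, 0.6)
  res2 <- suppressWarnings(phylum_regressions(data.frame(A = a, B = 0.8 - a),
                                              cbind("A", "B")))
  expect_lt(res2$slope, 0)
  expect_error(phylum_regressions(data.frame(A = a), cbind("A", "Zz")),
               "unknown phylum")
})

test_that("regression slope test holds its nominal size", {
  set.seed(11)
  rej <- 0
  for (i in 1:1000) {
    d <- data.frame(A = rnorm(20), B = rnorm(20))
    if (phylum_regressions(d, cbind("A", "B"))$p_slope < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 1000, 0.03)
  expect_lte(rej / 1000, 0.07)
})
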