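test_that("Mantel statistic hits its algebraic anchors", {
  A <- random_distance(7, seed = 1)
  expect_equal(mantel_test(A, A, n_perm = 99, seed = 1)$r, 1)
  # a rank-reversing transform of the entries flips the correlation
  B <- A
  B[upper.tri(B)] <- max(A) + 0.5 - A[upper.tri(A)]
  B[lower.tri(B)] <- t(B)[lower.tri(B)]
  expect_equal(mantel_test(A, B, n_perm = 99, seed = 1)$r, -1)
  # the statistic is symmetric in its arguments
  C <- random_distance(7, seed = 2)
  expect_equal(mantel_test(A, C, n_perm = 0)$r, mantel_test(C, A, n_perm = 0)$r)
  expect_error(mantel_test(A, random_distance(7, 3, labels = letters[1:7]),
                           99), "labels")
})

test_that("Mantel matches vegan and the exhaustive enumeration oracle", {
  A <- random_distance(6, seed = 10)
  B <- random_distance(6, seed = 11)
  res <- mantel_test(A, B, exhaustive = TRUE)
  expect_equal(res$r,
               unname(vegan::mantel(as.dist(A), as.dist(B),
                                    method = "spearman",
                                    permutations = 0)$statistic))
  expect_equal(res$p, oracle_mantel_exact(A, B))
  expect_equal(res$n_perm, factorial(6))
  # exhaustive p is label-order invariant, hence exactly symmetric
  expect_equal(res$p, mantel_test(B, A, exhaustive = TRUE)$p)

  A5 <- random_distance(5, seed = 12)
  B5 <- random_distance(5, seed = 13)
  expect_equal(mantel_test(A5, B5, exhaustive = TRUE)$p,
               oracle_mantel_exact(A5, B5))
})

test_that("permutation p-values respect the add-one floor", {
  A <- random_distance(8, seed = 4)
  res <- mantel_test(A, A, n_perm = 99, seed = 7)
  expect_gte(res$p, 1 / (99 + 1))
  expect_lte(res$p, 1)
  res2 <- mantel_test(A, A, n_perm = 99, seed = 7)
  expect_identical(res$p, res2$p)  # seeded determinism
})

test_that("partial Mantel reduces correctly and matches its oracle", {
  A <- random_distance(6, seed = 21)
  B <- random_distance(6, seed = 22)
  C <- random_distance(6, seed = 23)
  # identity of A and B forces r = 1 whatever the (non-degenerate) control
  expect_equal(partial_mantel_test(A, A, C, n_perm = 99, seed = 1)$r, 1)
  # the formula route agrees with residual-based partial correlation and
  # exhaustive enumeration agrees with the independent oracle
  res <- partial_mantel_test(A, B, C, exhaustive = TRUE)
  up <- upper.tri(A)
  ra <- rank(A[up]); rb <- rank(B[up]); rc <- rank(C[up])
  r_resid <- cor(resid(lm(ra ~ rc)), resid(lm(rb ~ rc)))
  expect_equal(res$r, r_resid, tolerance = 1e-12)
  expect_equal(res$p, oracle_partial_mantel_exact(A, B, C))
  # perfectly correlated control is degenerate
  expect_error(partial_mantel_test(A, B, A, n_perm = 9), "degenerate")
})

test_that("ANOSIM anchors: perfect separation, null mean, exact p", {
  # two tight clusters: all within-distances below all between-distances
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  expect_equal(anosim_test(D, g, n_perm = 99, seed = 1)$R, 1)

  # exact p over the 20 distinct relabelings of a 3+3 split
  res <- anosim_test(D, g, exhaustive = TRUE)
  orc <- oracle_anosim_exact(D, g)
  expect_equal(res$n_perm, 20)
  expect_equal(orc$n_distinct, 20)
  expect_equal(res$p, orc$p)

  # rank basis: any strictly monotone transform leaves R unchanged
  Dm <- D^2
  expect_equal(anosim_test(Dm, g, n_perm = 0)$R,
               anosim_test(D, g, n_perm = 0)$R)

  # statistic agrees with vegan
  D2 <- random_distance(10, seed = 31)
  g2 <- rep(c("a", "b"), 5)
  expect_equal(anosim_test(D2, g2, n_perm = 0)$R,
               unname(vegan::anosim(as.dist(D2), g2,
                                    permutations = 0)$statistic))

  # shuffled labels are centred on zero
  set.seed(99)
  stats_null <- replicate(1000, anosim_test(D2, sample(g2), n_perm = 0)$R)
  expect_lt(abs(mean(stats_null)), 3 * sd(stats_null) / sqrt(1000))

  expect_error(anosim_test(D2, c(rep("a", 9), "b"), 99), ">= 2 samples")
})

test_that("PERMANOVA reproduces classical ANOVA on Euclidean distances", {
  set.seed(5)
  y <- rnorm(18) + rep(c(0, 1, 3), each = 6)
  g <- factor(rep(c("a", "b", "c"), each = 6))
  D <- as.matrix(dist(y))
  dimnames(D) <- list(paste0("s", 1:18), paste0("s", 1:18))
  res <- permanova(D, data.frame(g = g), "g", n_perm = 99, seed = 1)
  fit <- summary(lm(y ~ g))
  expect_equal(res$table$R2, fit$r.squared, tolerance = 1e-9)
  expect_equal(res$table$F, fit$fstatistic[["value"]], tolerance = 1e-9)
})

test_that("PERMANOVA partitions sequentially and sums to one", {
  set.seed(6)
  n <- 24
  dat <- data.frame(g = factor(rep(letters[1:3], each = 8)),
                    x = rnorm(n), z = rnorm(n))
  Y <- matrix(rnorm(n * 5), n) + model.matrix(~ dat$g)[, 2:3] %*%
    matrix(rnorm(10), 2)
  D <- as.matrix(dist(Y))
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  res1 <- permanova(D, dat, c("g", "x", "z"), n_perm = 199, seed = 2)
  expect_equal(sum(res1$table$R2) + res1$residual_r2, 1, tolerance = 1e-9)
  expect_true(all(res1$table$R2 >= 0))
  # order of entry changes per-term shares, never the total
  res2 <- permanova(D, dat, c("z", "x", "g"), n_perm = 0, seed = 2)
  expect_equal(sum(res2$table$R2), sum(res1$table$R2), tolerance = 1e-9)
  # rescaling all distances leaves every R2 identical
  res3 <- permanova(2.5 * D, dat, c("g", "x", "z"), n_perm = 0)
  expect_equal(res3$table$R2, res1$table$R2, tolerance = 1e-12)
  # agreement with vegan's sequential adonis
  ad <- suppressWarnings(vegan::adonis2(as.dist(D) ~ g + x + z, data = dat,
                                        permutations = 2, by = "terms"))
  expect_equal(res1$table$R2, ad$R2[1:3], tolerance = 1e-9)
  # intercept-only: everything is residual
  res0 <- permanova(D, dat, character(0), n_perm = 99)
  expect_equal(res0$residual_r2, 1)
  # collinear columns are dropped with a warning naming them
  dat$x2 <- dat$x
  expect_warning(permanova(D, dat, c("x", "x2"), n_perm = 0), "collinear")
})

test_that("Mantel correlogram recovers structure and partitions pairs", {
  # two spatial clusters whose communities mirror the geography
  xy <- rbind(matrix(rnorm(16, 0, 0.1), 8), matrix(rnorm(16, 5, 0.1), 8))
  set.seed(41)
  comm <- xy + matrix(rnorm(32, 0, 0.2), 16)
  sd_m <- as.matrix(dist(xy)); cd_m <- as.matrix(dist(comm))
  ids <- paste0("s", 1:16)
  dimnames(sd_m) <- dimnames(cd_m) <- list(ids, ids)
  res <- mantel_correlogram(cd_m, sd_m, n_classes = 4, n_perm = 99, seed = 1)
  cl <- res$classes
  expect_gt(cl$r[1], 0)
  expect_equal(sum(cl$n_pairs), 16 * 15 / 2)
  expect_true(all(cl$p_corrected >= cl$p))
  expect_true(any(cl$reliable) && !all(cl$reliable))
})
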