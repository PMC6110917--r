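test_that("default configuration encodes the nested 3x8x5 design", {
  cfg <- default_config()
  expect_identical(cfg$n_basins, 3L)
  expect_identical(cfg$polygons_per_basin, 8L)
  expect_equal(cfg$transect_positions, c(0, 0.4, 0.8, 2, 6))
  expect_equal(cfg$basin_ph_means, c(8.77, 10.03, 9.57))
  expect_equal(cfg$basin_ec_means, c(361, 144, 788))
  # local gradients: pH only in the Bonney-like basin, EC only Fryxell-like
  expect_true(cfg$local_slope_ph[1] > 0 && all(cfg$local_slope_ph[-1] == 0))
  expect_true(cfg$local_slope_ec[3] > 0 && all(cfg$local_slope_ec[-3] == 0))
  pd <- cfg$phylum_defs
  expect_true(all(pd$ec_coef[pd$phylum %in%
    c("Deinococcus-Thermus", "Gemmatimonadetes")] > 0))
  expect_true(all(pd$ec_coef[pd$phylum %in%
    c("Acidobacteria", "Bacteroidetes", "Proteobacteria")] < 0))
  frame <- generate_landscape(cfg)
  expect_equal(nrow(frame), 120L)
  expect_false(anyDuplicated(frame$sample_id) > 0)
  expect_true(all(frame$ec > 0))
  expect_true(all(frame$ph >= 0 & frame$ph <= 14))
  # one sample per (basin, polygon, position)
  tab <- table(frame$polygon)
  expect_true(all(tab == length(cfg$transect_positions)))
})

test_that("config validation rejects inconsistent inputs", {
  cfg <- default_config()
  bad <- cfg; bad$basin_ph_means <- c(8, 9)
  expect_error(generate_landscape(bad), "length n_basins")
  bad <- cfg; bad$basin_ec_means[2] <- -5
  expect_error(generate_landscape(bad), "positive")
  frame <- generate_landscape(cfg)
  frame$ph[3] <- NA
  expect_error(generate_community(frame, cfg), "complete ph and ec")
})

test_that("zero noise and zero slopes reproduce basin means exactly", {
  cfg <- default_config(seed = 5)
  cfg$polygon_sd_ph <- cfg$polygon_sd_ec <- 0
  cfg$noise_sd_ph <- cfg$noise_sd_ec <- 0
  cfg$local_slope_ph <- cfg$local_slope_ec <- rep(0, 3)
  frame <- generate_landscape(cfg)
  for (b in seq_len(3)) {
    sub <- frame[frame$basin == cfg$basin_names[b], ]
    expect_equal(unique(sub$ph), cfg$basin_ph_means[b])
    expect_equal(unique(sub$ec), cfg$basin_ec_means[b], tolerance = 1e-12)
  }
  # degenerate landscape maximizes the Kruskal-Wallis pH statistic:
  # perfectly separated groups attain the no-tie upper bound
  kw <- kruskal_wallis(frame$ph, frame$basin)
  n <- nrow(frame)
  rk_means <- tapply(rank(frame$ph), frame$basin, mean)
  h <- 12 / (n * (n + 1)) *
    sum(table(frame$basin) * (rk_means - (n + 1) / 2)^2)
  # within-group values are all tied, so the attainable maximum carries the
  # mid-rank tie correction
  tie <- table(frame$ph)
  h_max <- h / (1 - sum(tie^3 - tie) / (n^3 - n))
  expect_equal(kw$chi2, h_max)
})

test_that("same seed gives bit-identical landscape and community", {
  cfg <- default_config(seed = 11)
  f1 <- generate_landscape(cfg)
  f2 <- generate_landscape(cfg)
  expect_identical(f1, f2)
  c1 <- generate_community(f1, cfg)
  c2 <- generate_community(f2, cfg)
  expect_identical(c1$counts, c2$counts)
})

test_that("basin mean EC matches the configured arithmetic mean", {
  # Monte-Carlo over replicate landscapes: the log-normal model is
  # mean-corrected, so per-basin average EC is an unbiased estimate
  cfg <- default_config()
  means <- sapply(1:200, function(s) {
    cfg$seed <- s
    fr <- generate_landscape(cfg)
    tapply(fr$ec, fr$basin, mean)[cfg$basin_names]
  })
  for (b in seq_len(3)) {
    est <- mean(means[b, ])
    se <- sd(means[b, ]) / sqrt(ncol(means))
    expect_lt(abs(est - cfg$basin_ec_means[b]), 3 * se)
  }
})

test_that("community counts obey their invariants", {
  cfg <- default_config(seed = 3)
  frame <- generate_landscape(cfg)
  com <- generate_community(frame, cfg)
  expect_true(all(com$counts >= 0))
  expect_identical(rownames(com$counts), frame$sample_id)
  expect_true(all(colnames(com$counts) %in% names(com$taxonomy)))
  expect_setequal(unique(com$taxonomy), cfg$phylum_defs$phylum)
})

test_that("null phylum coefficients give flat phylum responses", {
  cfg <- default_config(seed = 9)
  cfg$phylum_defs$ph_coef[] <- 0
  cfg$phylum_defs$ec_coef[] <- 0
  frame <- generate_landscape(cfg)
  com <- generate_community(frame, cfg)
  pa <- phylum_abundance(com)
  # mean relative abundances track the softmax of the intercepts and no
  # phylum correlates systematically with EC
  expect_equal(colMeans(pa)[cfg$phylum_defs$phylum],
               setNames(cfg$phylum_defs$base_abundance,
                        cfg$phylum_defs$phylum),
               tolerance = 0.1)
  rho <- apply(pa, 2, function(x) cor(x, frame$ec, method = "spearman"))
  expect_lt(mean(abs(rho)), 0.25)
})

test_that("a strong single-phylum EC response is recovered", {
  hits <- 0
  for (s in 1:20) {
    cfg <- default_config(seed = 100 + s)
    cfg$phylum_defs$ph_coef[] <- 0
    cfg$phylum_defs$ec_coef[] <- 0
    cfg$phylum_defs$ec_coef[cfg$phylum_defs$phylum == "Gemmatimonadetes"] <- 5
    frame <- generate_landscape(cfg)
    com <- generate_community(frame, cfg)
    rho <- cor(frame$ec, phylum_abundance(com)[, "Gemmatimonadetes"],
               method = "spearman")
    if (rho > 0.8) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("richness-EC coupling depresses rarefied richness at high EC", {
  neg <- 0
  for (s in 1:20) {
    cfg <- default_config(seed = 200 + s)
    cfg$richness_ec_coefficient <- 2
    frame <- generate_landscape(cfg)
    com <- generate_community(frame, cfg)
    rar <- rarefy(com, 500, seed = s)
    ids <- rownames(rar$counts)
    rho <- cor(frame[ids, "ec"], observed_species(rar)[ids],
               method = "spearman")
    if (rho < 0) neg <- neg + 1
  }
  expect_gte(neg, 18)
})

test_that("dual-regime fixture has the designed structure", {
  d <- simulate_dual_regime(n = 150, breakpoint = 500, seed = 4)
  expect_equal(nrow(d), 150)
  below <- d$ec < 500
  expect_gt(cor(d$ph[below], d$observed_species[below]), 0.9)
  expect_lt(cor(d$ec[!below], d$observed_species[!below]), -0.9)
  expect_lt(abs(cor(d$ph, d$ec)), 0.3)
})
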