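#' Pipeline run configuration
#'
#' Bundles the knobs of a full multi-scale run. Defaults mirror the
#' analysis' standard settings: rarefaction to 500 reads, 999 permutations,
#' window of 10 samples stepping by 1, bins of 5 uS/cm (EC) and 0.05 pH
#' units.
#'
#' @param depth Rarefaction depth (>= 1).
#' @param n_perm Permutations for every matrix test (>= 99).
#' @param seed Integer run seed; every stochastic step derives its own
#'   logged substream from it.
#' @param scales Subset of `c("regional", "basin", "local")`.
#' @param window_size,window_step Sliding-window parameters.
#' @param ec_bin,ph_bin Bin widths for importance-profile normalization.
#' @param min_local_n Minimum samples per polygon for local tests; below it
#'   the polygon is reported as `"ND"`.
#' @return A `run_config` list.
#' @export
run_config <- function(depth = 500, n_perm = 999, seed = 1L,
                       scales = c("regional", "basin", "local"),
                       window_size = 10, window_step = 1,
                       ec_bin = 5, ph_bin = 0.05, min_local_n = 4) {
  stopifnot(depth >= 1, n_perm >= 99, length(scales) >= 1,
            all(scales %in% c("regional", "basin", "local")))
  structure(list(depth = depth, n_perm = n_perm, seed = as.integer(seed),
                 scales = scales, window_size = window_size,
                 window_step = window_step, ec_bin = ec_bin, ph_bin = ph_bin,
                 min_local_n = min_local_n),
            class = "run_config")
}

euclid_distance <- function(x, labels, metric) {
  as_distance_matrix(as.matrix(stats::dist(x)), labels = labels,
                     metric = metric)
}

# Mantel + partial Mantel battery for one scope: edaphic and community
# structure against a spatial distance matrix
mantel_block <- function(meta, comp_d, space_d, n_perm, seed, scope) {
  ids <- rownames(space_d)
  ph_d <- euclid_distance(meta$ph, ids, "euclidean_ph")
  ec_d <- euclid_distance(meta$ec, ids, "euclidean_ec")
  rich_d <- euclid_distance(meta$observed_species, ids, "euclidean_richness")
  sub <- function(nm) substream_seed(seed, paste0(scope, ":", nm))
  list(
    mantel = list(
      ph = mantel_test(ph_d, space_d, n_perm, sub("mantel_ph")),
      ec = mantel_test(ec_d, space_d, n_perm, sub("mantel_ec")),
      composition = mantel_test(comp_d, space_d, n_perm, sub("mantel_comp")),
      richness = mantel_test(rich_d, space_d, n_perm, sub("mantel_rich"))
    ),
    partial_mantel = list(
      composition_ph = partial_mantel_test(comp_d, ph_d, space_d, n_perm,
                                           sub("pmantel_comp_ph")),
      composition_ec = partial_mantel_test(comp_d, ec_d, space_d, n_perm,
                                           sub("pmantel_comp_ec")),
      richness_ph = partial_mantel_test(rich_d, ph_d, space_d, n_perm,
                                        sub("pmantel_rich_ph")),
      richness_ec = partial_mantel_test(rich_d, ec_d, space_d, n_perm,
                                        sub("pmantel_rich_ec"))
    )
  )
}

#' Run the full multi-scale analysis
#'
#' Orchestrates the pipeline at up to three spatial scales. Regional:
#' pooled Mantel/partial Mantel (space = planar coordinates), ANOSIM of
#' basins on Bray-Curtis, sequential PERMANOVA (basin, EC, pH, distance from
#' trough) and CCA on the Jaccard/chi-square community, Kruskal-Wallis
#' basin contrasts of edaphic and alpha-diversity variables, and the
#' sliding-window LMG model along both gradients. Basin: per-basin
#' Mantel/partial Mantel, PERMANOVA and CCA (EC, pH, distance). Local: per
#' polygon, Mantel tests of pH, EC, composition and richness against
#' distance-from-trough; polygons with fewer retained samples than
#' `min_local_n` are reported `"ND"`.
#'
#' @param community A `community_matrix`.
#' @param metadata A `sample_frame` covering every community sample.
#' @param config A [run_config()].
#' @return A `scale_report` list with elements `rarefied`, `alpha`,
#'   `regional`, `basin`, `local`, `config`.
#' @export
run_scales <- function(community, metadata, config = run_config()) {
  orphans_c <- setdiff(rownames(community$counts), metadata$sample_id)
  orphans_m <- setdiff(metadata$sample_id, rownames(community$counts))
  if (length(orphans_c) || length(orphans_m)) {
    stop("label mismatch between community and metadata; orphans: ",
         paste(c(orphans_c, orphans_m), collapse = ", "))
  }
  seed <- config$seed
  rar <- rarefy(community, depth = config$depth,
                seed = substream_seed(seed, "rarefy"))
  ids <- rownames(rar$counts)
  meta <- as.data.frame(metadata)[ids, , drop = FALSE]
  meta$observed_species <- observed_species(rar)[ids]
  meta$inverse_simpson <- inverse_simpson(rar)[ids]
  meta$goods_coverage <- goods_coverage(rar)[ids]

  jac <- beta_distances(rar, "jaccard")
  bray <- beta_distances(rar, "bray_curtis")

  report <- list(rarefied = list(n_retained = length(ids),
                                 dropped = rar$dropped_samples,
                                 depth = rar$depth),
                 alpha = meta[, c("sample_id", "basin", "polygon",
                                  "dist_from_trough", "ph", "ec",
                                  "observed_species", "inverse_simpson",
                                  "goods_coverage")],
                 config = config)

  if ("regional" %in% config$scales) {
    space_d <- euclid_distance(meta[, c("easting", "northing")], ids,
                               "euclidean_space")
    kw <- lapply(c(ph = "ph", ec = "ec",
                   observed_species = "observed_species",
                   inverse_simpson = "inverse_simpson"),
                 function(v) kruskal_wallis(meta[[v]], meta$basin))
    win <- lapply(c(ph = "ph", ec = "ec"), function(g) {
      prof <- sliding_windows(meta, ordering_variable = g,
                              window_size = config$window_size,
                              step = config$window_step)
      normalize_profile(prof, if (g == "ph") config$ph_bin else config$ec_bin)
    })
    cca <- suppressMessages(
      cca_fit(rar, meta[, c("basin", "ec", "ph", "dist_from_trough")]))
    cca <- suppressMessages(cca_permutation_test(
      cca, rar, meta[, c("basin", "ec", "ph", "dist_from_trough")],
      n_perm = config$n_perm, seed = substream_seed(seed, "regional:cca")))
    report$regional <- c(
      mantel_block(meta, jac, space_d, config$n_perm, seed, "regional"),
      list(
        anosim = anosim_test(bray, meta$basin, config$n_perm,
                             substream_seed(seed, "regional:anosim")),
        permanova = permanova(jac, meta,
                              c("basin", "ec", "ph", "dist_from_trough"),
                              config$n_perm,
                              substream_seed(seed, "regional:permanova")),
        cca = cca,
        kruskal_wallis = kw,
        importance = c(win, list(
          dominance = dominance_summary(win$ph, win$ec))),
        correlogram = mantel_correlogram(
          jac, space_d, n_perm = config$n_perm,
          seed = substream_seed(seed, "regional:correlogram"))
      ))
  }

  if ("basin" %in% config$scales) {
    report$basin <- lapply(split(seq_along(ids), meta$basin), function(ix) {
      m <- meta[ix, , drop = FALSE]
      bids <- m$sample_id
      comp <- as_distance_matrix(jac[bids, bids], metric = "jaccard")
      space_d <- euclid_distance(m[, c("easting", "northing")], bids,
                                 "euclidean_space")
      scope <- paste0("basin:", m$basin[1])
      cons <- m[, c("ec", "ph", "dist_from_trough")]
      rsub <- rar; rsub$counts <- rar$counts[bids, , drop = FALSE]
      cca <- suppressMessages(cca_fit(rsub, cons))
      cca <- suppressMessages(
        cca_permutation_test(cca, rsub, cons, config$n_perm,
                             substream_seed(seed, paste0(scope, ":cca"))))
      c(mantel_block(m, comp, space_d, config$n_perm, seed, scope),
        list(permanova = permanova(comp, m, c("ec", "ph", "dist_from_trough"),
                                   config$n_perm,
                                   substream_seed(seed, paste0(scope, ":permanova"))),
             cca = cca, n = length(bids)))
    })
  }

  if ("local" %in% config$scales) {
    polys <- unique(metadata$polygon)
    report$local <- lapply(stats::setNames(polys, polys), function(poly) {
      m <- meta[meta$polygon == poly, , drop = FALSE]
      if (nrow(m) < config$min_local_n) {
        return(list(status = "ND", n = nrow(m)))
      }
      pids <- m$sample_id
      trough_d <- euclid_distance(m$dist_from_trough, pids,
                                  "euclidean_trough")
      comp <- as_distance_matrix(jac[pids, pids], metric = "jaccard")
      scope <- paste0("local:", m$polygon[1])
      sub <- function(nm) substream_seed(seed, paste0(scope, ":", nm))
      list(status = "OK", n = nrow(m),
           mantel = list(
             ph = mantel_test(euclid_distance(m$ph, pids, "euclidean_ph"),
                              trough_d, config$n_perm, sub("ph")),
             ec = mantel_test(euclid_distance(m$ec, pids, "euclidean_ec"),
                              trough_d, config$n_perm, sub("ec")),
             composition = mantel_test(comp, trough_d, config$n_perm,
                                       sub("composition")),
             richness = mantel_test(
               euclid_distance(m$observed_species, pids, "euclidean_rich"),
               trough_d, config$n_perm, sub("richness"))))
    })
  }
  class(report) <- "scale_report"
  report
}

#' Write a scale report to disk
#'
#' Emits a JSON summary of every test outcome (statistics, p-values,
#' permutation counts and seeds, so any single result can be replayed), an
#' alpha-diversity TSV, and — when present — the normalized importance
#' profiles as TSV.
#'
#' @param report A `scale_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- file.path(dir, "alpha_diversity.tsv")
  utils::write.table(report$alpha, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$regional$importance)) {
    for (g in c("ph", "ec")) {
      p <- file.path(dir, paste0("importance_", g, ".tsv"))
      utils::write.table(as.data.frame(report$regional$importance[[g]]), p,
                         sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  strip <- function(x) {
    if (inherits(x, c("mantel_outcome", "anosim_outcome",
                      "group_test_outcome", "cca_model",
                      "correlogram_outcome", "permanova_outcome",
                      "dominance_summary"))) {
      lapply(unclass(x), strip)
    } else if (inherits(x, "lmg_decomposition")) {
      list(shares = as.list(x$lmg_share), model_r2 = x$model_r2)
    } else if (is.list(x) && is.null(dim(x)) && !is.data.frame(x)) {
      lapply(x, strip)
    } else if (is.matrix(x)) {
      NULL  # score matrices are not serialized into the summary
    } else x
  }
  p <- file.path(dir, "report.json")
  jsonlite::write_json(strip(unclass(report)[setdiff(names(report), "alpha")]),
                       p, auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.mantel_outcome <- function(x, ...) {
  cat(sprintf("Mantel%s: r = %.3f, p = %s (n_perm = %d, tail = %s)\n",
              if (isTRUE(x$exhaustive)) " [exhaustive]" else "",
              x$r, format.pval(x$p, digits = 3), x$n_perm, x$tail))
  invisible(x)
}

#' @export
print.anosim_outcome <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %s (n_perm = %d)\n",
              x$R, format.pval(x$p, digits = 3), x$n_perm))
  invisible(x)
}

#' @export
print.permanova_outcome <- function(x, ...) {
  cat("PERMANOVA (sequential):\n")
  tab <- x$table
  tab$R2 <- round(tab$R2, 4); tab$F <- round(tab$F, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual: df = %d, R2 = %.4f\n", x$residual_df, x$residual_r2))
  invisible(x)
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf(paste0("CCA: total inertia %.4f; constrained %.4f (%.1f%%), ",
                     "unconstrained %.4f\n"),
              x$total_inertia, x$constrained_inertia,
              100 * x$constrained_proportion, x$unconstrained_inertia))
  if (!is.na(x$model_f)) {
    cat(sprintf("model chi2 = %.4f, F = %.3f, p = %s (n_perm = %d)\n",
                x$model_chi2, x$model_f, format.pval(x$model_p, digits = 3),
                x$n_perm))
  }
  invisible(x)
}

#' @export
print.group_test_outcome <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi2 = %.2f, df = %d, p = %s\n",
              x$chi2, x$df, format.pval(x$p, digits = 3)))
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}
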