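#' Kruskal-Wallis test with post hoc letter groupings
#'
#' Rank-sum test across groups (mid-rank tie correction, chi-square
#' approximation via [stats::kruskal.test()]), followed by pairwise post hoc
#' comparisons — Tukey HSD applied to the rank-transformed values, a
#' rank-based reconciliation of the common "Kruskal-Wallis + Tukey" pairing
#' — summarized as a compact letter display: two groups share a letter iff
#' their post hoc p-value is at least `alpha`.
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 non-empty groups).
#' @param alpha Significance level for the letter display.
#' @return A `group_test_outcome`: `chi2`, `df`, `p`, `pairwise` (data frame
#'   of pairwise post hoc p-values), `letters` (named character per group).
#' @export
kruskal_wallis <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("every group must be non-empty")
  if (length(unique(values)) == 1L) {
    # fully tied data: no evidence of group differences (the chi-square
    # statistic's tie correction is otherwise 0/0)
    lv <- levels(groups)
    cmb <- utils::combn(lv, 2)
    pairwise <- data.frame(group1 = cmb[2, ], group2 = cmb[1, ],
                           diff = 0, p = 1, stringsAsFactors = FALSE)
    return(structure(list(chi2 = 0, df = nlevels(groups) - 1L, p = 1,
                          pairwise = pairwise,
                          letters = stats::setNames(rep("a", nlevels(groups)), lv),
                          alpha = alpha),
                     class = "group_test_outcome"))
  }
  kw <- stats::kruskal.test(values, groups)
  rk <- rank(values)
  tuk <- stats::TukeyHSD(stats::aov(rk ~ groups))$groups
  pairs <- do.call(rbind, strsplit(rownames(tuk), "-", fixed = TRUE))
  pairwise <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                         diff = tuk[, "diff"], p = tuk[, "p adj"],
                         stringsAsFactors = FALSE, row.names = NULL)
  letters <- compact_letters(levels(groups), pairwise, alpha)
  structure(list(chi2 = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value, pairwise = pairwise, letters = letters,
                 alpha = alpha),
            class = "group_test_outcome")
}

#' Compact letter display from pairwise p-values
#'
#' Insert-and-absorb algorithm: groups sharing a letter are pairwise
#' non-significant at `alpha`.
#'
#' @param groups Character vector of group names.
#' @param pairwise Data frame with `group1`, `group2`, `p`.
#' @param alpha Significance threshold.
#' @return Named character vector of letter strings per group.
#' @export
compact_letters <- function(groups, pairwise, alpha = 0.05) {
  k <- length(groups)
  # insert-absorb: start with one set holding everything; every significant
  # pair splits each set containing both members into two children, then
  # sets that became subsets of others are absorbed
  sets <- list(groups)
  for (i in seq_len(nrow(pairwise))) {
    if (!(pairwise$p[i] < alpha)) next
    g1 <- pairwise$group1[i]; g2 <- pairwise$group2[i]
    nxt <- list()
    for (s in sets) {
      if (all(c(g1, g2) %in% s)) {
        nxt <- c(nxt, list(setdiff(s, g1), setdiff(s, g2)))
      } else {
        nxt <- c(nxt, list(s))
      }
    }
    keep <- rep(TRUE, length(nxt))
    for (a in seq_along(nxt)) {
      for (b in seq_along(nxt)) {
        if (a == b || !keep[a] || !keep[b]) next
        a_in_b <- all(nxt[[a]] %in% nxt[[b]])
        proper <- length(nxt[[a]]) < length(nxt[[b]])
        if (a_in_b && (proper || a > b)) keep[a] <- FALSE
      }
    }
    sets <- nxt[keep]
  }
  sets <- sets[order(vapply(sets, function(s) match(s[1], groups), numeric(1)))]
  out <- stats::setNames(rep("", k), groups)
  for (s in seq_along(sets)) {
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  }
  out
}

#' Spearman correlation grid with Benjamini-Hochberg correction
#'
#' Correlates each row variable (phylum relative abundance or diversity
#' index) with each edaphic/spatial column, at the regional scope or within
#' each basin. Raw p-values use the t approximation; BH adjustment is
#' applied within each column family per scope cell.
#'
#' @param data Data frame holding all variables plus (for `per_basin`) a
#'   `basin` column.
#' @param rows Character vector of row-variable names.
#' @param cols Character vector of column-variable names (default the three
#'   gradient axes).
#' @param scope `"regional"` or `"per_basin"`.
#' @return A `correlation_grid` data frame: `scope_cell`, `row`, `col`,
#'   `rho`, `p_raw`, `p_adjusted`, `n`.
#' @export
spearman_grid <- function(data, rows,
                          cols = c("dist_from_trough", "ph", "ec"),
                          scope = c("regional", "per_basin")) {
  scope <- match.arg(scope)
  if (!all(c(rows, cols) %in% names(data))) {
    stop("missing variables: ",
         paste(setdiff(c(rows, cols), names(data)), collapse = ", "))
  }
  cells <- if (scope == "regional") list(regional = data) else {
    split(data, data$basin)
  }
  recs <- list()
  for (cell in names(cells)) {
    d <- cells[[cell]]
    if (nrow(d) < 5) stop("scope cell '", cell, "' has fewer than 5 samples")
    for (cl in cols) {
      block <- do.call(rbind, lapply(rows, function(rw) {
        ct <- suppressWarnings(
          stats::cor.test(d[[rw]], d[[cl]], method = "spearman",
                          exact = FALSE))
        data.frame(scope_cell = cell, row = rw, col = cl,
                   rho = unname(ct$estimate), p_raw = ct$p.value,
                   n = sum(stats::complete.cases(d[, c(rw, cl)])),
                   stringsAsFactors = FALSE)
      }))
      block$p_adjusted <- stats::p.adjust(block$p_raw, method = "BH")
      recs[[length(recs) + 1L]] <- block
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("correlation_grid", class(out))
  out
}

#' Pairwise phylum-abundance regressions along transects
#'
#' Ordinary least squares of one phylum's relative abundance on another's,
#' as used to characterize phylum trade-offs along polygon transects.
#'
#' @param phyla Data frame or matrix of per-sample phylum relative
#'   abundances (columns named by phylum).
#' @param pairs Data frame or 2-column matrix of (independent, dependent)
#'   phylum names.
#' @return Data frame with `independent`, `dependent`, `intercept`, `slope`,
#'   `r2`, `p_slope`, `n`.
#' @export
phylum_regressions <- function(phyla, pairs) {
  phyla <- as.data.frame(phyla)
  pairs <- as.matrix(pairs)
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    iv <- pairs[i, 1]; dv <- pairs[i, 2]
    if (!all(c(iv, dv) %in% names(phyla))) {
      stop("unknown phylum in pair: ", iv, " / ", dv)
    }
    fit <- stats::lm(phyla[[dv]] ~ phyla[[iv]])
    sm <- summary(fit)
    data.frame(independent = iv, dependent = dv,
               intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               r2 = sm$r.squared,
               p_slope = sm$coefficients[2, 4],
               n = nrow(phyla), stringsAsFactors = FALSE)
  }))
}
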