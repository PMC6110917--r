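#' Rarefy a community to a fixed depth
#'
#' Subsamples each sample's reads without replacement (one hypergeometric
#' draw per sample) down to `depth`. Samples with fewer reads than `depth`
#' are dropped and listed, mirroring the usual practice of standardizing
#' sequencing effort before diversity analysis.
#'
#' @param community A `community_matrix`.
#' @param depth Target reads per sample (default 500).
#' @param seed Integer seed; rarefaction is deterministic given it.
#' @return A `rarefied_community`: list with `counts`, `depth`,
#'   `dropped_samples`, `seed`, `taxonomy`.
#' @export
rarefy <- function(community, depth = 500, seed = 1L) {
  stopifnot(inherits(community, "community_matrix"), depth >= 1)
  counts <- community$counts
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples fall below the rarefaction depth")
  dropped <- rownames(counts)[!keep]
  sub <- counts[keep, , drop = FALSE]
  with_substream(seed, "rarefy", {
    for (s in seq_len(nrow(sub))) {
      x <- sub[s, ]
      tot <- sum(x)
      if (tot == depth) next
      reads <- rep.int(seq_along(x), x)
      picked <- sample(reads, depth, replace = FALSE)
      sub[s, ] <- tabulate(picked, nbins = length(x))
    }
    structure(list(counts = sub, depth = as.integer(depth),
                   dropped_samples = dropped, seed = as.integer(seed),
                   taxonomy = community$taxonomy),
              class = "rarefied_community")
  })
}

count_input <- function(x) {
  if (is.list(x) && !is.null(x$counts)) x$counts
  else if (is.matrix(x)) x
  else matrix(x, nrow = 1, dimnames = list("sample", NULL))
}

#' Observed species (richness)
#'
#' Number of OTUs with non-zero count, per sample.
#'
#' @param x A counts vector, samples x OTUs matrix, or community object.
#' @return Named integer vector (scalar for a single vector input).
#' @export
observed_species <- function(x) {
  m <- count_input(x)
  out <- rowSums(m > 0)
  if (length(out) == 1L && is.null(dim(x))) unname(out) else out
}

#' Inverse Simpson diversity
#'
#' `1 / sum(p_i^2)` with `p_i` the within-sample relative abundances; equals
#' S for S equally abundant taxa and 1 for a monoculture.
#'
#' @inheritParams observed_species
#' @return Numeric vector of indices.
#' @export
inverse_simpson <- function(x) {
  m <- count_input(x)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("inverse Simpson requires positive sample totals")
  out <- 1 / rowSums((m / tot)^2)
  if (length(out) == 1L && is.null(dim(x))) unname(out) else out
}

#' Good's coverage
#'
#' `1 - singletons / reads`: the estimated fraction of the community captured
#' at the realized sequencing depth.
#'
#' @inheritParams observed_species
#' @return Numeric vector of proportions in [0, 1].
#' @export
goods_coverage <- function(x) {
  m <- count_input(x)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("Good's coverage requires positive sample totals")
  out <- 1 - rowSums(m == 1) / tot
  if (length(out) == 1L && is.null(dim(x))) unname(out) else out
}

#' Beta-diversity distance matrix
#'
#' Bray-Curtis on counts (`1 - 2 * sum(min) / sum(total)`) or Jaccard on
#' presence/absence (`1 - shared / union`), both in [0, 1]. Computation is
#' delegated to [vegan::vegdist()].
#'
#' @param rarefied A `rarefied_community` (or `community_matrix`).
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return A `dist_matrix` (square labelled matrix with a `metric`
#'   attribute).
#' @export
beta_distances <- function(rarefied, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  counts <- count_input(rarefied)
  if (nrow(counts) < 2) stop("need at least two retained samples")
  d <- switch(metric,
    bray_curtis = vegan::vegdist(counts, method = "bray"),
    jaccard = vegan::vegdist(counts, method = "jaccard", binary = TRUE)
  )
  as_distance_matrix(as.matrix(d), metric = metric)
}
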