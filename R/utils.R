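#' Derive a reproducible substream seed
#'
#' Every stochastic step in the pipeline draws its own RNG seed from the run
#' seed plus a text label, so that independent analyses never share a random
#' stream and every reported statistic can be replayed from its logged seed.
#'
#' @param seed Integer run seed.
#' @param label Character label naming the consumer (e.g. "rarefy",
#'   "mantel:ph").
#' @return An integer in [0, 2^31 - 2] suitable for [set.seed()].
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

# run `expr` under a temporary RNG state seeded from (seed, label), restoring
# the caller's stream afterwards
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  expr
}

# upper off-diagonal entries of a square symmetric matrix, in column order
upper_entries <- function(m) m[upper.tri(m)]

# coerce dist / matrix input to a labelled square matrix and sanity-check it
as_square_distance <- function(d, what = "distance matrix") {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop(what, " must be square")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  }
  if (max(abs(m - t(m))) > 1e-8) stop(what, " must be symmetric")
  if (any(abs(diag(m)) > 1e-8)) stop(what, " must have a zero diagonal")
  m
}

#' Construct a labelled distance matrix
#'
#' @param values Square symmetric numeric matrix (or `dist`) with zero
#'   diagonal.
#' @param labels Optional sample labels; defaults to the matrix dimnames.
#' @param metric Name of the dissimilarity metric.
#' @return A `dist_matrix`: a square numeric matrix with a `metric`
#'   attribute.
#' @export
as_distance_matrix <- function(values, labels = NULL, metric = "unknown") {
  m <- as_square_distance(values)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(m))
    rownames(m) <- colnames(m) <- labels
  }
  attr(m, "metric") <- metric
  class(m) <- c("dist_matrix", class(m))
  m
}

check_same_labels <- function(...) {
  mats <- list(...)
  lab <- rownames(mats[[1]])
  for (m in mats[-1]) {
    if (!identical(rownames(m), lab)) {
      stop("distance matrices must share identical sample labels and order")
    }
  }
  invisible(lab)
}

# all permutations of 1..n as a list (n small; used for exhaustive tests)
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- as.integer(append(p, n, after = pos - 1L))
    }
  }
  out
}
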