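#' Discretize continuous expression data
#'
#' Maps each gene's continuous profile independently onto integer levels
#' `0..levels-1` before scoring.  Equal-frequency binning (the default) places
#' the level boundaries at the empirical quantiles `k/levels`; equal-width
#' splits the observed `[min, max]` range uniformly.  A value that falls
#' exactly on a boundary is assigned to the lower level.
#'
#' A gene with constant expression cannot be binned: it is mapped entirely to
#' level 0 with a warning, and its declared arity is still `levels`, so the
#' degrees of freedom of any test involving it overcount.
#'
#' @param mat numeric matrix, genes x time (one series), or a list of such
#'   matrices.  Finite values required.
#' @param levels number of discrete levels per gene (>= 2, default 3).
#' @param method `"freq"` (equal-frequency, default) or `"width"`.
#' @param gene_names optional identifiers; default `rownames(mat)` or `G1..Gn`.
#' @param periodic passed through to the resulting dataset.
#' @return list with `dataset` (a [ccit_dataset] with every arity = `levels`)
#'   and `boundaries` (per-gene numeric vectors of the `levels - 1` cut
#'   points).
#' @examples
#' m <- matrix(rnorm(40), nrow = 4)
#' d <- discretize(m, levels = 3)
#' table(d$dataset$series[[1]][1, ])
#' @export
discretize <- function(mat, levels = 3L, method = c("freq", "width"),
                       gene_names = NULL, periodic = FALSE) {
  method <- match.arg(method)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("levels must be an integer >= 2")
  series <- if (is.matrix(mat)) list(mat) else mat
  if (!all(vapply(series, is.matrix, TRUE))) stop("mat must be matrix or list")
  n <- nrow(series[[1L]])
  if (is.null(gene_names)) gene_names <- rownames(series[[1L]])
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  all_vals <- do.call(cbind, series)
  if (any(!is.finite(all_vals))) stop("expression values must be finite")

  boundaries <- vector("list", n)
  names(boundaries) <- gene_names
  out <- lapply(series, function(m) matrix(0L, n, ncol(m)))
  for (g in seq_len(n)) {
    x <- all_vals[g, ]
    if (max(x) == min(x)) {
      warning("gene ", gene_names[g], " has constant expression; ",
              "all values mapped to level 0 (declared arity still ", levels,
              ", degrees of freedom will overcount)")
      boundaries[[g]] <- rep(NA_real_, levels - 1L)
      next
    }
    b <- if (method == "freq") {
      stats::quantile(x, probs = seq_len(levels - 1L) / levels, names = FALSE)
    } else {
      seq(min(x), max(x), length.out = levels + 1L)[2:levels]
    }
    ## boundaries may collide under heavy ties; nudge to keep them usable
    b <- cummax(b)
    boundaries[[g]] <- b
    for (s in seq_along(series)) {
      lev <- findInterval(series[[s]][g, ], b, left.open = TRUE)
      out[[s]][g, ] <- as.integer(lev)
    }
  }
  gt <- gene_table(gene_names, levels)
  for (s in seq_along(out)) rownames(out[[s]]) <- gene_names
  list(dataset = ccit_dataset(out, gt, periodic = periodic),
       boundaries = boundaries)
}

#' Accept an already-discretized integer matrix as a dataset
#'
#' Convenience wrapper: values must already be integers in `[0, levels)`.
#'
#' @inheritParams discretize
#' @param levels declared arity for every gene.
#' @return a [ccit_dataset].
#' @export
as_discrete_dataset <- function(mat, levels, gene_names = NULL,
                                periodic = FALSE) {
  series <- if (is.matrix(mat)) list(mat) else mat
  n <- nrow(series[[1L]])
  if (is.null(gene_names)) gene_names <- rownames(series[[1L]])
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  message("treating input as pre-discretized with ", levels, " levels")
  ccit_dataset(series, gene_table(gene_names, levels), periodic = periodic)
}
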