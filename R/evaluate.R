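#' Confusion counts of an inferred network against a ground truth
#'
#' Order-agnostic mode collapses both networks to ordered gene pairs: an arc
#' at any lag (including 0) counts as an edge, duplicates across lags merge,
#' and the evaluation universe is the `n(n-1)` ordered non-self pairs.
#' Order-aware mode requires an exact `(regulator, target, lag)` match over
#' the universe of ordered pairs times lags `0..d_max`.
#'
#' @param inferred,truth [ccit_network]s over the same gene set.
#' @param mode `"agnostic"` (default) or `"aware"`.
#' @param include_self include self-pairs in the universe (only meaningful
#'   when lagged self-arcs are in play; default `FALSE`).
#' @return object of class `"confusion"`: list with `tp`, `fp`, `tn`, `fn`,
#'   `mode`, `universe`.
#' @export
confusion <- function(inferred, truth, mode = c("agnostic", "aware"),
                      include_self = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(inferred, "ccit_network"),
            inherits(truth, "ccit_network"))
  if (!identical(inferred$genes$names, truth$genes$names)) {
    stop("inferred and truth networks have different gene sets")
  }
  n <- length(truth$genes$names)
  if (mode == "agnostic") {
    key <- function(net) unique(paste(net$arcs$from, net$arcs$to))
    universe <- n * (n - 1L) + if (include_self) n else 0L
  } else {
    d_max <- max(inferred$d_max, truth$d_max)
    key <- function(net) paste(net$arcs$from, net$arcs$to, net$arcs$lag)
    universe <- (n * (n - 1L) + if (include_self) n else 0L) * (d_max + 1L)
  }
  ki <- key(inferred); kt <- key(truth)
  tp <- length(intersect(ki, kt))
  fp <- length(setdiff(ki, kt))
  fn <- length(setdiff(kt, ki))
  tn <- universe - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, mode = mode,
                 universe = universe), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("Confusion (%s, universe %d): TP %d  FP %d  TN %d  FN %d\n",
              x$mode, x$universe, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Network-reconstruction performance measures
#'
#' Sensitivity `Se = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, precision
#' `Pr = TP/(TP+FP)`, and the F-score, the harmonic mean of precision and
#' sensitivity `F = 2*Pr*Se/(Pr+Se)`.  A 0/0 ratio is reported as `NaN` with
#' a warning.
#'
#' @param x a `"confusion"` object, or a list with `tp`, `fp`, `tn`, `fn`.
#' @return named numeric vector `c(Se, Sp, Pr, F)`.
#' @examples
#' grn_metrics(list(tp = 5, fn = 3, fp = 0, tn = 10))
#' @export
grn_metrics <- function(x) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0)")
      return(NaN)
    }
    num / den
  }
  se <- ratio(x$tp, x$tp + x$fn, "sensitivity")
  sp <- ratio(x$tn, x$tn + x$fp, "specificity")
  pr <- ratio(x$tp, x$tp + x$fp, "precision")
  f <- if (is.nan(se) || is.nan(pr) || se + pr == 0) {
    warning("F-score undefined")
    NaN
  } else 2 * pr * se / (pr + se)
  c(Se = se, Sp = sp, Pr = pr, F = f)
}

#' Power-law fit of a network's degree distribution
#'
#' Computes the total (in + out) degree of every gene, tabulates the
#' frequency of each positive degree, and fits ordinary least squares of
#' `log10(frequency)` on `log10(degree)`.  A high coefficient of
#' determination supports a scale-free reading of the inferred topology.
#'
#' @param network a non-empty [ccit_network].
#' @return list with `r_squared`, `slope`, and `degrees` (data.frame
#'   `degree`/`frequency`).
#' @export
powerlaw_r2 <- function(network) {
  stopifnot(inherits(network, "ccit_network"))
  n <- length(network$genes$names)
  if (nrow(network$arcs) == 0L) stop("network has no arcs")
  deg <- tabulate(network$arcs$from, nbins = n) +
    tabulate(network$arcs$to, nbins = n)
  tab <- table(deg[deg > 0L])
  if (length(tab) < 3L) {
    stop("need at least 3 distinct positive degrees for a power-law fit")
  }
  df <- data.frame(degree = as.integer(names(tab)),
                   frequency = as.integer(tab))
  fit <- stats::lm(log10(frequency) ~ log10(degree), data = df)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       degrees = df)
}
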