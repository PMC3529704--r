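#' Effective sample count under lagged alignment
#'
#' When a child is scored against parents whose maximum regulation order is
#' `delta`, an aperiodic series of `N` time points yields only `N - delta`
#' usable samples: the first `delta` child observations have no aligned
#' parent values.  Periodic data wraps around, so all `N` samples remain
#' usable.
#'
#' @param N number of time points in one series (>= 1).
#' @param delta maximum regulation order over the parent set (>= 0).
#' @param periodic logical.
#' @return integer count of usable aligned samples.
#' @examples
#' effective_sample_count(50, 3, periodic = FALSE)  # 47
#' effective_sample_count(50, 3, periodic = TRUE)   # 50
#' @export
effective_sample_count <- function(N, delta, periodic = FALSE) {
  N <- as.integer(N); delta <- as.integer(delta)
  stopifnot(N >= 1L, delta >= 0L)
  if (periodic) return(N)
  if (delta >= N) {
    stop("aperiodic series of ", N, " time points cannot align lag ", delta,
         " (empty alignment)")
  }
  N - delta
}

#' Build the lag-aligned sample table for a child and its parents
#'
#' Produces the table over which the child's mutual information with its
#' mixed-lag parent set is computed.  For an aperiodic series of `N_s` time
#' points, the child contributes times `t = delta_i .. N_s - 1` (0-based) and
#' each parent is read at `t - lag`; a periodic series contributes all `N_s`
#' rows with the parent index taken modulo `N_s`.  Multiple series are
#' aligned independently and their rows pooled -- a lag never crosses a
#' series boundary.  An aperiodic series too short for `delta_i` contributes
#' zero rows.
#'
#' @param dataset a [ccit_dataset].
#' @param child gene index or name.
#' @param parents data.frame with columns `parent` (index or name) and `lag`,
#'   or `NULL`/empty for a child-only table.
#' @return list with `child` (integer vector of child levels), `parents`
#'   (matrix with one column per (parent, lag), `effective_n` rows),
#'   `effective_n`, and `max_lag`.
#' @export
build_aligned_table <- function(dataset, child, parents = NULL) {
  stopifnot(inherits(dataset, "ccit_dataset"))
  child <- gene_index(dataset$genes, child)
  if (is.null(parents) || nrow(parents) == 0L) {
    parents <- data.frame(parent = integer(0), lag = integer(0))
  } else {
    parents <- data.frame(parent = gene_index(dataset$genes, parents$parent),
                          lag = as.integer(parents$lag))
    if (any(parents$lag < 0L)) stop("negative lag")
    if (anyDuplicated(paste(parents$parent, parents$lag))) {
      stop("duplicate (parent, lag) pair")
    }
  }
  delta <- if (nrow(parents) > 0L) max(parents$lag) else 0L
  np <- nrow(parents)

  child_rows <- integer(0)
  parent_rows <- matrix(integer(0), nrow = 0L, ncol = np)
  for (m in dataset$series) {
    N_s <- ncol(m)
    if (dataset$periodic) {
      t_child <- seq_len(N_s)                       # 1-based columns
    } else {
      if (N_s < delta + 1L) next                    # too short: no rows
      t_child <- seq.int(delta + 1L, N_s)
    }
    child_rows <- c(child_rows, m[child, t_child])
    if (np > 0L) {
      pr <- vapply(seq_len(np), function(j) {
        tp <- t_child - parents$lag[j]
        if (dataset$periodic) tp <- ((tp - 1L) %% N_s) + 1L
        m[parents$parent[j], tp]
      }, integer(length(t_child)))
      if (!is.matrix(pr)) pr <- matrix(pr, ncol = np)
      parent_rows <- rbind(parent_rows, pr)
    }
  }
  if (length(child_rows) == 0L) {
    stop("no series long enough to align maximum lag ", delta)
  }
  list(child = as.integer(child_rows),
       parents = parent_rows,
       effective_n = length(child_rows),
       max_lag = delta)
}
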