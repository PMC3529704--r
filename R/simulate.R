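#' Random delay-annotated network
#'
#' Draws `n_arcs` distinct `(regulator, target, lag)` triples: the ordered
#' gene pair uniformly among non-self pairs, the lag uniformly from
#' `lag_pool`, rejecting draws that would duplicate a triple or close an
#' instantaneous cycle.
#'
#' @param genes a [gene_table], or an integer gene count (binary genes named
#'   `G1..Gn` are created).
#' @param n_arcs number of arcs.
#' @param d_max maximum lag of the resulting network.
#' @param lag_pool lags to draw from (default `0:d_max`).
#' @param seed optional integer seed.
#' @param max_tries rejection budget before giving up (default
#'   `1000 * (n_arcs + 1)`).
#' @return a [ccit_network].
#' @export
random_network <- function(genes, n_arcs, d_max = 3L, lag_pool = NULL,
                          seed = NULL, max_tries = NULL) {
  if (!inherits(genes, "gene_table")) {
    genes <- gene_table(paste0("G", seq_len(genes)), 2L)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(lag_pool)) lag_pool <- 0:d_max
  stopifnot(all(lag_pool >= 0L), all(lag_pool <= d_max))
  n <- length(genes$names)
  n_arcs <- as.integer(n_arcs)
  if (is.null(max_tries)) max_tries <- 1000L * (n_arcs + 1L)
  arcs <- empty_arcs()
  tries <- 0L
  while (nrow(arcs) < n_arcs) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n_arcs, " arcs after ", max_tries, " tries")
    }
    from <- sample.int(n, 1L)
    to <- sample.int(n, 1L)
    if (from == to) next
    lag <- sample(lag_pool, 1L)
    if (has_arc(arcs, from, to, lag)) next
    if (lag == 0L && lag0_reaches(arcs, to, from)) next
    arcs <- rbind(arcs, data.frame(from = from, to = to, lag = lag))
  }
  ccit_network(genes, arcs, d_max = d_max)
}

## Mixed-radix row index (1-based) of a parent configuration: the first
## parent varies fastest.  `values` in [0, arity); `arities` same length.
config_index <- function(values, arities) {
  idx <- 0L
  radix <- 1L
  for (j in seq_along(values)) {
    idx <- idx + values[j] * radix
    radix <- radix * arities[j]
  }
  idx + 1L
}

#' Build a conditional probability table
#'
#' Realizes one of the simulator's CPD families as an explicit table with one
#' row per joint parent configuration (first listed parent varying fastest)
#' and one column per child level.
#'
#' Families:
#' * `"binomial"` -- noisy regulation of a binary child by binary parents.
#'   With one parent, excitation gives `P(on|on) = 0.9`, `P(on|off) = 0.1`
#'   and inhibition the reverse.  With several parents the per-parent
#'   excitation/inhibition flags vote: the child is on with probability 0.9
#'   when a strict majority of parents is in its activating state, 0.1 under
#'   a strict minority, and 0.5 on a tie.
#' * `"xor"` -- noisy XOR-style co-regulation of a binary child by exactly
#'   two binary parents: `P(on|on,on) = P(on|off,off) = 0.1`,
#'   `P(on|on,off) = P(on|off,on) = 0.9`.
#' * `"dirichlet"` -- each row drawn from `Dirichlet(ess * a_j)` where the
#'   base measure `a_j` is the normalized harmonic vector
#'   `(1, 1/2, ..., 1/k)` cyclically right-shifted by `j mod k` positions for
#'   the j-th parent configuration.
#' * `"table"` -- an explicit probability table supplied in `params$table`.
#'
#' @param family one of `"binomial"`, `"xor"`, `"dirichlet"`, `"table"`.
#' @param parent_arities integer vector (may be empty for a root marginal).
#' @param child_arity number of child levels.
#' @param params family parameters: `excite` (logical per parent),
#'   `p_high`/`p_low` (defaults 0.9/0.1), `ess` (equivalent sample size,
#'   default 10), `table`.
#' @param seed optional seed (Dirichlet family only).
#' @return object of class `"ccit_cpd"`: list with `family`,
#'   `parent_arities`, `child_arity`, `table`.
#' @export
make_cpd <- function(family = c("binomial", "xor", "dirichlet", "table"),
                     parent_arities, child_arity, params = list(),
                     seed = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(as.integer(seed))
  parent_arities <- as.integer(parent_arities)
  child_arity <- as.integer(child_arity)
  p_high <- if (is.null(params$p_high)) 0.9 else params$p_high
  p_low <- if (is.null(params$p_low)) 0.1 else params$p_low
  n_cfg <- if (length(parent_arities)) prod(parent_arities) else 1L
  tab <- switch(family,
    binomial = {
      s <- length(parent_arities)
      if (s < 1L || child_arity != 2L || any(parent_arities != 2L)) {
        stop("binomial family needs a binary child and >= 1 binary parents")
      }
      excite <- if (is.null(params$excite)) rep(TRUE, s) else params$excite
      if (length(excite) != s) stop("need one excite flag per parent")
      t <- matrix(0, n_cfg, 2L)
      for (cfg in seq_len(n_cfg)) {
        v <- cfg_values(cfg, parent_arities)
        match_n <- sum((v == 1L) == excite)
        p_on <- if (2L * match_n > s) p_high
                else if (2L * match_n < s) p_low else 0.5
        t[cfg, ] <- c(1 - p_on, p_on)
      }
      t
    },
    xor = {
      if (child_arity != 2L || length(parent_arities) != 2L ||
          any(parent_arities != 2L)) {
        stop("xor family needs a binary child and exactly 2 binary parents")
      }
      t <- matrix(0, 4L, 2L)
      for (cfg in 1:4) {
        v <- cfg_values(cfg, parent_arities)
        p_on <- if (sum(v) == 1L) p_high else p_low
        t[cfg, ] <- c(1 - p_on, p_on)
      }
      t
    },
    dirichlet = {
      ess <- if (is.null(params$ess)) 10 else params$ess
      k <- child_arity
      basis <- (1 / seq_len(k)) / sum(1 / seq_len(k))
      t <- matrix(0, n_cfg, k)
      for (j in seq_len(n_cfg)) {
        shift <- j %% k
        a <- basis[((seq_len(k) - 1L - shift) %% k) + 1L]
        g <- stats::rgamma(k, shape = ess * a)
        t[j, ] <- g / sum(g)
      }
      t
    },
    table = {
      t <- as.matrix(params$table)
      if (nrow(t) != n_cfg || ncol(t) != child_arity) {
        stop("explicit table must be ", n_cfg, " x ", child_arity)
      }
      t
    })
  if (any(tab < 0) || any(abs(rowSums(tab) - 1) > 1e-12)) {
    stop("CPD rows must be probability vectors summing to 1")
  }
  structure(list(family = family, parent_arities = parent_arities,
                 child_arity = child_arity, table = tab),
            class = "ccit_cpd")
}

## Inverse of config_index: the parent values (0-based) of row `cfg`.
cfg_values <- function(cfg, arities) {
  v <- integer(length(arities))
  cfg <- cfg - 1L
  for (j in seq_along(arities)) {
    v[j] <- cfg %% arities[j]
    cfg <- cfg %/% arities[j]
  }
  v
}

#' Ground truth: network plus generating distributions
#'
#' @param network a [ccit_network].
#' @param cpds list of one [make_cpd()] object per gene; each gene's CPD must
#'   cover exactly the joint states of its parents (a 1-row marginal for a
#'   parentless gene).
#' @param confounders indices of genes deliberately left without any arcs.
#' @return object of class `"ccit_truth"`.
#' @export
ccit_truth <- function(network, cpds, confounders = integer(0)) {
  stopifnot(inherits(network, "ccit_network"))
  n <- length(network$genes$names)
  if (length(cpds) != n) stop("need one CPD per gene")
  for (i in seq_len(n)) {
    ps <- parent_set(network, i)
    want <- if (nrow(ps)) prod(network$genes$arities[ps$parent]) else 1L
    if (nrow(cpds[[i]]$table) != want ||
        cpds[[i]]$child_arity != network$genes$arities[i]) {
      stop("CPD of gene ", network$genes$names[i],
           " does not match its parents' joint states")
    }
  }
  structure(list(network = network, cpds = cpds,
                 confounders = as.integer(confounders)),
            class = "ccit_truth")
}

#' Forward-sample discrete time series from a ground truth
#'
#' The joint transition model factorizes per gene: each gene at time `t` is
#' conditioned on its lag-0 parents in the same slice and its lagged parents
#' `lag` slices back.  The first `d_max` slices are drawn from per-gene
#' uniform marginals; from then on each slice is sampled in lag-0
#' topological order.  Deterministic given `seed`.
#'
#' @param truth a [ccit_truth].
#' @param N time points per series (must exceed the network's `d_max`).
#' @param n_series number of independent series (default 1).
#' @param seed optional integer seed.
#' @param burn_in leading slices to discard after sampling (default 0).
#' @return a [ccit_dataset].
#' @export
sample_timeseries <- function(truth, N, n_series = 1L, seed = NULL,
                              burn_in = 0L) {
  stopifnot(inherits(truth, "ccit_truth"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  net <- truth$network
  genes <- net$genes
  n <- length(genes$names)
  d <- net$d_max
  N <- as.integer(N); burn_in <- as.integer(burn_in)
  if (N <= d) stop("need more than d_max = ", d, " time points")
  a0 <- net$arcs[net$arcs$lag == 0L, , drop = FALSE]
  g0 <- igraph::graph_from_data_frame(
    data.frame(from = as.character(a0$from), to = as.character(a0$to)),
    vertices = data.frame(name = as.character(seq_len(n))))
  topo <- as.integer(names(igraph::topo_sort(g0)))
  psets <- lapply(seq_len(n), function(i) parent_set(net, i))
  series <- vector("list", n_series)
  total <- N + burn_in
  for (s in seq_len(n_series)) {
    m <- matrix(0L, n, total)
    for (t in seq_len(min(d, total))) {
      m[, t] <- vapply(genes$arities,
                       function(r) sample.int(r, 1L) - 1L, 0L)
    }
    if (total > d) for (t in seq.int(d + 1L, total)) {
      for (i in topo) {
        ps <- psets[[i]]
        row <- if (nrow(ps) == 0L) 1L else {
          vals <- vapply(seq_len(nrow(ps)), function(j) {
            m[ps$parent[j], t - ps$lag[j]]
          }, 0L)
          config_index(vals, genes$arities[ps$parent])
        }
        pr <- truth$cpds[[i]]$table[row, ]
        m[i, t] <- sample.int(genes$arities[i], 1L, prob = pr) - 1L
      }
    }
    rownames(m) <- genes$names
    series[[s]] <- m[, (burn_in + 1L):total, drop = FALSE]
  }
  ccit_dataset(series, genes, periodic = FALSE)
}

#' Benchmark ground truths and datasets
#'
#' Two self-contained generators mirroring the package's synthetic study
#' conditions:
#' * `"yeast"` -- a binary 12-gene sub-network with 11 random arcs, each arc
#'   assigned a regulation order drawn uniformly from 0--3; a child with
#'   exactly two parents is noisy-XOR co-regulated with probability 1/2 and
#'   otherwise (like every other regulated child) subject to noisy binomial
#'   regulation with random excitation/inhibition flags; 8 unconnected
#'   confounder genes are appended, for 20 genes in total.
#' * `"dirichlet"` -- 35 three-level genes with 52 random arcs of order 1 or
#'   2 and conditional rows drawn from the shifted-harmonic Dirichlet prior
#'   with equivalent sample size 10.
#'
#' @param preset `"yeast"` or `"dirichlet"`.
#' @param N time points per series.
#' @param n_series number of series (default 1).
#' @param seed optional integer seed.
#' @return list with `truth` (a [ccit_truth]) and `dataset` (a
#'   [ccit_dataset]).
#' @export
make_benchmark <- function(preset = c("yeast", "dirichlet"), N,
                           n_series = 1L, seed = NULL) {
  preset <- match.arg(preset)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (preset == "yeast") {
    n_core <- 12L; n_conf <- 8L
    genes <- gene_table(paste0("G", seq_len(n_core + n_conf)), 2L)
    core <- random_network(gene_table(paste0("G", seq_len(n_core)), 2L),
                           n_arcs = 11L, d_max = 3L)
    net <- ccit_network(genes, core$arcs, d_max = 3L)
    cpds <- vector("list", n_core + n_conf)
    for (i in seq_len(n_core + n_conf)) {
      ps <- parent_set(net, i)
      cpds[[i]] <- if (nrow(ps) == 0L) {
        make_cpd("table", integer(0), 2L, params = list(table = rbind(c(.5, .5))))
      } else if (nrow(ps) == 2L && stats::runif(1) < 0.5) {
        make_cpd("xor", rep(2L, 2L), 2L)
      } else {
        make_cpd("binomial", rep(2L, nrow(ps)), 2L,
                 params = list(excite = sample(c(TRUE, FALSE), nrow(ps),
                                               replace = TRUE)))
      }
    }
    truth <- ccit_truth(net, cpds,
                        confounders = seq.int(n_core + 1L, n_core + n_conf))
  } else {
    n <- 35L
    genes <- gene_table(paste0("G", seq_len(n)), 3L)
    net <- random_network(genes, n_arcs = 52L, d_max = 2L, lag_pool = 1:2)
    cpds <- lapply(seq_len(n), function(i) {
      ps <- parent_set(net, i)
      make_cpd("dirichlet",
               if (nrow(ps)) rep(3L, nrow(ps)) else integer(0), 3L,
               params = list(ess = 10))
    })
    truth <- ccit_truth(net, cpds)
  }
  list(truth = truth,
       dataset = sample_timeseries(truth, N = N, n_series = n_series))
}
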