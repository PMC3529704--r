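#' Search configuration
#'
#' @param score_config a [score_config()].
#' @param max_iterations upper bound on greedy moves (default 500).
#' @param restarts number of additional random-restart runs beyond the run
#'   from the empty graph (default 0).
#' @param seed integer seed making the whole search deterministic.
#' @param forbid_multi_lag_pairs if `TRUE`, at most one arc (any lag) per
#'   ordered gene pair (default `FALSE`).
#' @return list of class `"search_config"`.
#' @export
search_config <- function(score_config = ccitnet::score_config(),
                          max_iterations = 500L, restarts = 0L,
                          seed = NULL, forbid_multi_lag_pairs = FALSE) {
  stopifnot(max_iterations >= 1L)
  structure(list(score_config = score_config,
                 max_iterations = as.integer(max_iterations),
                 restarts = as.integer(restarts), seed = seed,
                 forbid_multi_lag_pairs = isTRUE(forbid_multi_lag_pairs)),
            class = "search_config")
}

## Is `to` able to reach `from` through lag-0 arcs?  If so, adding the lag-0
## arc from -> to would close an instantaneous cycle.
lag0_reaches <- function(arcs, start, goal) {
  a0 <- arcs[arcs$lag == 0L, , drop = FALSE]
  if (nrow(a0) == 0L) return(FALSE)
  frontier <- start
  seen <- start
  while (length(frontier) > 0L) {
    nxt <- unique(a0$to[a0$from %in% frontier])
    nxt <- setdiff(nxt, seen)
    if (goal %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

has_arc <- function(arcs, from, to, lag = NULL) {
  if (is.null(lag)) return(any(arcs$from == from & arcs$to == to))
  any(arcs$from == from & arcs$to == to & arcs$lag == lag)
}

#' Candidate single-arc moves from a network
#'
#' Enumerates the classical local-search neighborhood: every arc addition,
#' deletion, and reversal (reversal keeps the lag) that leaves the network
#' valid -- lag-0 acyclicity, the per-child fan-in cap, the self-arc policy,
#' and optionally the one-arc-per-pair restriction.
#'
#' @param network a [ccit_network].
#' @param config a [search_config()].
#' @return data.frame with columns `op` (`"add"`, `"delete"`, `"reverse"`),
#'   `from`, `to`, `lag` (gene indices).
#' @export
neighborhood <- function(network, config = search_config()) {
  sc <- config$score_config
  n <- length(network$genes$names)
  arcs <- network$arcs
  d_max <- sc$d_max
  fan_in <- tabulate(arcs$to, nbins = n)
  moves <- list()

  ## additions
  for (from in seq_len(n)) for (to in seq_len(n)) {
    if (from == to && !sc$allow_self_lagged) next
    if (fan_in[to] >= sc$max_fan_in) next
    if (config$forbid_multi_lag_pairs && has_arc(arcs, from, to)) next
    for (lag in 0:d_max) {
      if (from == to && lag == 0L) next
      if (has_arc(arcs, from, to, lag)) next
      if (lag == 0L && lag0_reaches(arcs, to, from)) next
      moves[[length(moves) + 1L]] <- c(1L, from, to, lag)
    }
  }
  ## deletions
  for (r in seq_len(nrow(arcs))) {
    moves[[length(moves) + 1L]] <- c(2L, arcs$from[r], arcs$to[r], arcs$lag[r])
  }
  ## reversals
  for (r in seq_len(nrow(arcs))) {
    from <- arcs$from[r]; to <- arcs$to[r]; lag <- arcs$lag[r]
    if (from == to) next
    if (has_arc(arcs, to, from, lag)) next
    if (fan_in[from] >= sc$max_fan_in) next
    if (config$forbid_multi_lag_pairs &&
        has_arc(arcs[-r, , drop = FALSE], to, from)) next
    if (lag == 0L) {
      rest <- arcs[-r, , drop = FALSE]
      if (lag0_reaches(rest, from, to)) next
    }
    moves[[length(moves) + 1L]] <- c(3L, from, to, lag)
  }
  if (length(moves) == 0L) {
    return(data.frame(op = character(0), from = integer(0),
                      to = integer(0), lag = integer(0)))
  }
  m <- do.call(rbind, moves)
  data.frame(op = c("add", "delete", "reverse")[m[, 1]],
             from = m[, 2], to = m[, 3], lag = m[, 4])
}

## Stable key of a parent set, used for local-score memoization.
ps_key <- function(child, parents) {
  paste0(child, "|", paste(parents$parent, parents$lag,
                           sep = ":", collapse = ","))
}

arcset_key <- function(arcs) {
  arcs <- normalize_arcs(arcs)
  paste(sprintf("%04d-%04d-%02d", arcs$from, arcs$to, arcs$lag),
        collapse = ";")
}

## One greedy best-improvement run from a given starting arc set.
## `memo` caches local scores across runs on the same dataset.
climb_once <- function(dataset, config, arcs0, memo) {
  sc <- config$score_config
  genes <- dataset$genes
  n <- length(genes$names)
  local_of <- function(child, parents) {
    key <- ps_key(child, parents)
    v <- memo[[key]]
    if (is.null(v)) {
      v <- local_breakdown(dataset, child, parents, sc)$local
      memo[[key]] <- v
    }
    v
  }
  pset <- function(arcs, child) {
    p <- arcs[arcs$to == child, c("from", "lag"), drop = FALSE]
    names(p) <- c("parent", "lag")
    p[order(p$lag, p$parent), , drop = FALSE]
  }
  arcs <- normalize_arcs(arcs0)
  locals <- vapply(seq_len(n), function(i) local_of(i, pset(arcs, i)), 0)
  trace <- list()
  net <- ccit_network(genes, arcs, d_max = sc$d_max,
                      allow_self_lagged = sc$allow_self_lagged)
  for (iter in seq_len(config$max_iterations)) {
    net$arcs <- arcs
    mv <- neighborhood(net, config)
    if (nrow(mv) == 0L) break
    gains <- numeric(nrow(mv))
    for (r in seq_len(nrow(mv))) {
      from <- mv$from[r]; to <- mv$to[r]; lag <- mv$lag[r]
      if (mv$op[r] == "add") {
        ps <- pset(arcs, to)
        ps2 <- rbind(ps, data.frame(parent = from, lag = lag))
        gains[r] <- local_of(to, canonical_parents(genes, ps2)) - locals[to]
      } else if (mv$op[r] == "delete") {
        ps <- pset(arcs, to)
        ps2 <- ps[!(ps$parent == from & ps$lag == lag), , drop = FALSE]
        gains[r] <- local_of(to, ps2) - locals[to]
      } else {
        ps_t <- pset(arcs, to)
        ps_t2 <- ps_t[!(ps_t$parent == from & ps_t$lag == lag), ,
                      drop = FALSE]
        ps_f <- pset(arcs, from)
        ps_f2 <- canonical_parents(genes, rbind(
          ps_f, data.frame(parent = to, lag = lag)))
        gains[r] <- (local_of(to, ps_t2) - locals[to]) +
          (local_of(from, ps_f2) - locals[from])
      }
    }
    ## best-improvement; ties prefer deletion > reversal > addition,
    ## then lower lag, then lexicographic (regulator, target)
    prio <- match(mv$op, c("delete", "reverse", "add"))
    ord <- order(-gains, prio, mv$lag, mv$from, mv$to)
    best <- ord[1L]
    if (gains[best] <= 1e-9) break
    from <- mv$from[best]; to <- mv$to[best]; lag <- mv$lag[best]
    if (mv$op[best] == "add") {
      arcs <- rbind(arcs, data.frame(from = from, to = to, lag = lag))
      locals[to] <- local_of(to, pset(arcs, to))
    } else if (mv$op[best] == "delete") {
      arcs <- arcs[!(arcs$from == from & arcs$to == to & arcs$lag == lag), ,
                   drop = FALSE]
      locals[to] <- local_of(to, pset(arcs, to))
    } else {
      arcs <- arcs[!(arcs$from == from & arcs$to == to & arcs$lag == lag), ,
                   drop = FALSE]
      arcs <- rbind(arcs, data.frame(from = to, to = from, lag = lag))
      locals[to] <- local_of(to, pset(arcs, to))
      locals[from] <- local_of(from, pset(arcs, from))
    }
    arcs <- normalize_arcs(arcs)
    trace[[length(trace) + 1L]] <- data.frame(
      iteration = iter, op = mv$op[best],
      regulator = genes$names[from], target = genes$names[to], lag = lag,
      gain = gains[best], total = sum(locals))
  }
  list(arcs = arcs, total = sum(locals),
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(iteration = integer(0), op = character(0),
                    regulator = character(0), target = character(0),
                    lag = integer(0), gain = numeric(0), total = numeric(0)))
}

#' Greedy hill-climbing structure search
#'
#' Learns a delay-annotated network by best-improvement local search over the
#' CCIT score, starting from the empty graph: at each iteration every valid
#' arc addition, deletion and reversal is scored (only the affected nodes'
#' local scores are recomputed, which decomposability makes exact) and the
#' single move with the largest gain is applied; the search stops when no
#' move improves the score.  With `restarts > 0` additional runs start from
#' random valid graphs and the best-scoring result is returned.  The run is
#' fully deterministic given `config$seed`.
#'
#' @param dataset a [ccit_dataset] (discrete levels).
#' @param config a [search_config()].
#' @return list with `network` (the learned [ccit_network]), `score` (a
#'   `"ccit_score"` breakdown) and `trace` (data.frame of applied moves with
#'   running totals).
#' @export
hill_climb <- function(dataset, config = search_config()) {
  stopifnot(inherits(dataset, "ccit_dataset"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  const <- vapply(dataset$series, function(m) {
    apply(m, 1L, function(v) max(v) == min(v))
  }, logical(length(dataset$genes$names)))
  const <- if (is.matrix(const)) apply(const, 1L, all) else const
  if (any(const)) {
    warning("constant gene(s) in data: ",
            paste(dataset$genes$names[const], collapse = ", "),
            "; search proceeds but they carry no signal")
  }
  memo <- new.env(parent = emptyenv())
  best <- climb_once(dataset, config, empty_arcs(), memo)
  if (config$restarts > 0L) {
    n <- length(dataset$genes$names)
    for (r in seq_len(config$restarts)) {
      n_arcs <- sample.int(max(1L, n), 1L)
      start <- random_network(dataset$genes, n_arcs,
                              d_max = config$score_config$d_max)
      cand <- climb_once(dataset, config, start$arcs, memo)
      if (cand$total > best$total + 1e-9 ||
          (abs(cand$total - best$total) <= 1e-9 &&
           arcset_key(cand$arcs) < arcset_key(best$arcs))) {
        best <- cand
      }
    }
  }
  net <- ccit_network(dataset$genes, best$arcs,
                      d_max = config$score_config$d_max,
                      allow_self_lagged = config$score_config$allow_self_lagged)
  list(network = net,
       score = ccit_score(net, dataset, config$score_config),
       trace = best$trace)
}

#' Exhaustive structure search (test oracle)
#'
#' Enumerates every valid network on a small problem and returns the one
#' maximizing the CCIT score.  Decomposability is exploited: per-child local
#' scores are computed for every admissible parent set, lag-0 parent
#' assignments are enumerated globally under the acyclicity constraint, and
#' each child's lagged parents are optimized independently.  Ties are broken
#' toward fewer arcs, then the lexicographically smallest arc set.
#'
#' @param dataset a [ccit_dataset] with at most 4 genes.
#' @param config a [search_config()]; `score_config$d_max` must be <= 1.
#' @return list with `network` and `score` as in [hill_climb()].
#' @export
exhaustive_search <- function(dataset, config = search_config()) {
  sc <- config$score_config
  genes <- dataset$genes
  n <- length(genes$names)
  if (n > 4L || sc$d_max > 1L) {
    stop("exhaustive search is limited to n <= 4 genes and d_max <= 1")
  }
  subsets <- function(x) {
    out <- list(integer(0))
    for (e in x) out <- c(out, lapply(out, function(s) c(s, e)))
    out
  }
  ## candidate parent sets per child, split by lag plane
  best_total <- -Inf; best_arcs <- NULL; best_key <- ""
  per_child <- lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    lag1_pool <- if (sc$allow_self_lagged && sc$d_max >= 1L) seq_len(n)
                 else others
    p0s <- Filter(function(s) length(s) <= sc$max_fan_in, subsets(others))
    p1s <- if (sc$d_max >= 1L) subsets(lag1_pool) else list(integer(0))
    list(others = others, p0s = p0s, p1s = p1s)
  })
  ## local score cache and per-(child, p0) best lagged completion
  local_cache <- new.env(parent = emptyenv())
  local_of <- function(i, p0, p1) {
    key <- paste(i, paste(p0, collapse = ","), paste(p1, collapse = ","),
                 sep = "|")
    v <- local_cache[[key]]
    if (is.null(v)) {
      ps <- data.frame(parent = c(p0, p1),
                       lag = c(rep(0L, length(p0)), rep(1L, length(p1))))
      v <- local_breakdown(dataset, i, ps, sc)$local
      local_cache[[key]] <- v
    }
    v
  }
  best_completion <- function(i, p0) {
    info <- per_child[[i]]
    bv <- -Inf; bp <- integer(0); bk <- ""
    for (p1 in info$p1s) {
      if (length(p0) + length(p1) > sc$max_fan_in) next
      v <- local_of(i, p0, p1)
      k <- paste(sort(p1), collapse = ",")
      better <- v > bv + 1e-9 ||
        (abs(v - bv) <= 1e-9 &&
         (length(p1) < length(bp) ||
          (length(p1) == length(bp) && k < bk)))
      if (better) { bv <- v; bp <- p1; bk <- k }
    }
    list(value = bv, p1 = bp)
  }
  ## enumerate lag-0 assignments (one parent subset per child)
  idx <- rep(1L, n)
  sizes <- vapply(per_child, function(pc) length(pc$p0s), 0L)
  repeat {
    p0 <- lapply(seq_len(n), function(i) per_child[[i]]$p0s[[idx[i]]])
    arcs0 <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (length(p0[[i]]) == 0L) return(NULL)
      data.frame(from = p0[[i]], to = i, lag = 0L)
    }))
    if (is.null(arcs0)) arcs0 <- empty_arcs()
    if (is.null(find_lag0_cycle(arcs0, n))) {
      total <- 0
      arcs <- arcs0
      ok <- TRUE
      for (i in seq_len(n)) {
        bc <- best_completion(i, p0[[i]])
        if (!is.finite(bc$value)) { ok <- FALSE; break }
        total <- total + bc$value
        if (length(bc$p1) > 0L) {
          arcs <- rbind(arcs, data.frame(from = bc$p1, to = i, lag = 1L))
        }
      }
      if (ok) {
        key <- arcset_key(arcs)
        better <- total > best_total + 1e-9 ||
          (abs(total - best_total) <= 1e-9 &&
           (nrow(arcs) < NROW(best_arcs) ||
            (nrow(arcs) == NROW(best_arcs) && key < best_key)))
        if (better) { best_total <- total; best_arcs <- arcs; best_key <- key }
      }
    }
    ## advance mixed-radix counter
    pos <- 1L
    while (pos <= n) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= sizes[pos]) break
      idx[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > n) break
  }
  net <- ccit_network(genes, best_arcs, d_max = sc$d_max,
                      allow_self_lagged = sc$allow_self_lagged)
  list(network = net, score = ccit_score(net, dataset, sc))
}
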