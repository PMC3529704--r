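#' Gene table: identifiers and discrete arities
#'
#' A gene table records the ordered set of gene identifiers together with the
#' number of discrete expression levels (the arity \eqn{r_p}) each gene can
#' take.  Arities drive the degrees of freedom of every conditional
#' independence test, so they are carried alongside the names everywhere a
#' network or dataset travels.
#'
#' @param names character vector of unique, non-empty gene identifiers.
#' @param arities integer vector of per-gene level counts, each >= 2.
#'   A single value is recycled across all genes.
#' @return An object of class `"gene_table"`: a list with elements `names`
#'   and `arities`.
#' @examples
#' gene_table(c("A", "B", "C"), 3)
#' @export
gene_table <- function(names, arities = 2L) {
  names <- as.character(names)
  if (length(names) == 0L) stop("gene table needs at least one gene")
  if (anyDuplicated(names)) {
    stop("duplicate gene names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (any(!nzchar(names))) stop("gene names must be non-empty")
  arities <- as.integer(arities)
  if (length(arities) == 1L) arities <- rep(arities, length(names))
  if (length(arities) != length(names)) {
    stop("arities must have length 1 or length(names)")
  }
  if (any(is.na(arities)) || any(arities < 2L)) {
    stop("every arity must be an integer >= 2")
  }
  structure(list(names = names, arities = arities), class = "gene_table")
}

#' @export
print.gene_table <- function(x, ...) {
  cat("Gene table with", length(x$names), "genes, arities",
      paste(unique(x$arities), collapse = "/"), "\n")
  invisible(x)
}

#' @export
length.gene_table <- function(x) length(x$names)

## Resolve gene references (names or indices) to integer indices.
gene_index <- function(genes, x) {
  if (is.character(x)) {
    i <- match(x, genes$names)
    if (anyNA(i)) stop("unknown gene(s): ", paste(x[is.na(i)], collapse = ", "))
    return(i)
  }
  i <- as.integer(x)
  if (any(is.na(i)) || any(i < 1L) || any(i > length(genes$names))) {
    stop("gene index out of range")
  }
  i
}

## Canonical empty arc frame.
empty_arcs <- function() {
  data.frame(from = integer(0), to = integer(0), lag = integer(0))
}

## Normalize an arc data.frame: integer columns, canonical order, no row names.
normalize_arcs <- function(arcs) {
  if (is.null(arcs) || nrow(arcs) == 0L) return(empty_arcs())
  arcs <- data.frame(from = as.integer(arcs$from),
                     to   = as.integer(arcs$to),
                     lag  = as.integer(arcs$lag))
  arcs <- arcs[order(arcs$from, arcs$to, arcs$lag), , drop = FALSE]
  rownames(arcs) <- NULL
  arcs
}

## Find one directed cycle among lag-0 arcs, as a vector of gene indices,
## or NULL if the instantaneous subgraph is acyclic.
find_lag0_cycle <- function(arcs, n) {
  a0 <- arcs[arcs$lag == 0L, , drop = FALSE]
  if (nrow(a0) == 0L) return(NULL)
  adj <- split(a0$to, factor(a0$from, levels = seq_len(n)))
  state <- integer(n)                  # 0 unseen, 1 on stack, 2 done
  parent <- integer(n)
  for (root in seq_len(n)) {
    if (state[root] != 0L) next
    stack <- root
    state[root] <- 1L
    iter <- list(adj[[root]])
    while (length(stack) > 0L) {
      v <- stack[length(stack)]
      nb <- iter[[length(iter)]]
      if (length(nb) == 0L) {
        state[v] <- 2L
        stack <- stack[-length(stack)]
        iter <- iter[-length(iter)]
        next
      }
      w <- nb[1L]
      iter[[length(iter)]] <- nb[-1L]
      if (state[w] == 1L) {
        pos <- match(w, stack)
        return(c(stack[pos:length(stack)], w))
      }
      if (state[w] == 0L) {
        state[w] <- 1L
        parent[w] <- v
        stack <- c(stack, w)
        iter <- c(iter, list(adj[[w]]))
      }
    }
  }
  NULL
}

#' Delay-annotated gene regulatory network
#'
#' Holds instantaneous (lag 0) and time-delayed arcs in a single structure:
#' each arc is a `(regulator, target, lag)` triple, the direct analogue of an
#' adjacency matrix whose first block marks same-slice regulation and whose
#' second block stores the order of delayed regulation.  Validity requires
#' (i) the lag-0 subgraph to be a DAG -- delayed arcs always point forward in
#' time, so they can never close a temporal cycle -- (ii) no lag-0 self-loop,
#' and (iii) at most one arc per `(regulator, target, lag)` triple.  Mutual
#' regulation such as A regulating B instantaneously while B regulates A with
#' delay is therefore representable.
#'
#' @param genes a [gene_table].
#' @param arcs data.frame with columns `from`, `to`, `lag`; `from`/`to` may be
#'   gene names or 1-based indices, `lag` is an integer in `[0, d_max]`.
#' @param d_max maximum allowed regulation order (default 3).
#' @param allow_self_lagged permit lagged self-arcs X -> X with lag >= 1
#'   (default `FALSE`).
#' @return An object of class `"ccit_network"`.
#' @examples
#' g <- gene_table(c("A", "B", "C", "D"), 3)
#' net <- ccit_network(g, data.frame(
#'   from = c("A", "D", "C", "D"), to = c("B", "B", "B", "A"),
#'   lag = c(0, 0, 1, 1)), d_max = 1)
#' net
#' @export
ccit_network <- function(genes, arcs = NULL, d_max = 3L,
                         allow_self_lagged = FALSE) {
  stopifnot(inherits(genes, "gene_table"))
  d_max <- as.integer(d_max)
  if (is.na(d_max) || d_max < 0L) stop("d_max must be a non-negative integer")
  if (!is.null(arcs) && nrow(arcs) > 0L) {
    arcs <- data.frame(from = gene_index(genes, arcs$from),
                       to   = gene_index(genes, arcs$to),
                       lag  = as.integer(arcs$lag))
  }
  arcs <- normalize_arcs(arcs)
  if (nrow(arcs) > 0L) {
    if (any(arcs$lag < 0L) || any(arcs$lag > d_max)) {
      stop("arc lag outside [0, d_max = ", d_max, "]")
    }
    self <- arcs$from == arcs$to
    if (any(self & arcs$lag == 0L)) {
      stop("instantaneous self-loop on gene ",
           genes$names[arcs$from[self & arcs$lag == 0L][1L]])
    }
    if (any(self) && !allow_self_lagged) {
      stop("lagged self-arcs are disabled (set allow_self_lagged = TRUE)")
    }
    key <- paste(arcs$from, arcs$to, arcs$lag)
    if (anyDuplicated(key)) stop("duplicate (regulator, target, lag) arc")
    cyc <- find_lag0_cycle(arcs, length(genes$names))
    if (!is.null(cyc)) {
      stop("instantaneous (lag-0) subgraph has a cycle: ",
           paste(genes$names[cyc], collapse = " -> "))
    }
  }
  structure(list(genes = genes, arcs = arcs, d_max = d_max,
                 allow_self_lagged = allow_self_lagged),
            class = "ccit_network")
}

#' @export
print.ccit_network <- function(x, ...) {
  n0 <- sum(x$arcs$lag == 0L)
  cat("Delay-annotated network:", length(x$genes$names), "genes,",
      nrow(x$arcs), "arcs (", n0, "instantaneous,",
      nrow(x$arcs) - n0, "time-delayed ), d_max =", x$d_max, "\n")
  if (nrow(x$arcs) > 0L) {
    lab <- paste0(x$genes$names[x$arcs$from], " -> ",
                  x$genes$names[x$arcs$to], " [lag ", x$arcs$lag, "]")
    cat(paste(" ", lab, collapse = "\n"), "\n")
  }
  invisible(x)
}

## Parent set of one child as a data.frame(parent, lag), ordered by lag
## then parent index.  This is the child-local view used by the score.
parent_set <- function(net, child) {
  p <- net$arcs[net$arcs$to == child, c("from", "lag"), drop = FALSE]
  names(p) <- c("parent", "lag")
  p <- p[order(p$lag, p$parent), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Discrete gene-expression time-series dataset
#'
#' One or more discrete-valued expression matrices sharing a gene table.
#' Values are integer levels in `[0, arity)` per gene; each series is a
#' genes-by-time matrix.  The `periodic` flag marks data (such as synchronized
#' cell-cycle series) whose time axis wraps around, which changes how lagged
#' samples are aligned.
#'
#' @param series a matrix or list of matrices, genes x time, integer levels.
#' @param genes a [gene_table]; arities bound-check the data.
#' @param periodic logical, treat every series as circular (default `FALSE`).
#' @return An object of class `"ccit_dataset"`.
#' @export
ccit_dataset <- function(series, genes, periodic = FALSE) {
  stopifnot(inherits(genes, "gene_table"))
  if (is.matrix(series)) series <- list(series)
  if (length(series) == 0L) stop("dataset needs at least one series")
  n <- length(genes$names)
  for (s in seq_along(series)) {
    m <- series[[s]]
    if (!is.matrix(m) || nrow(m) != n) {
      stop("series ", s, " is not a ", n, "-row matrix")
    }
    if (ncol(m) < 2L) stop("series ", s, " has fewer than 2 time points")
    storage.mode(m) <- "integer"
    if (any(is.na(m))) stop("series ", s, " contains missing values")
    if (any(m < 0L) || any(m >= genes$arities)) {
      bad <- which(m < 0L | m >= genes$arities, arr.ind = TRUE)[1L, ]
      stop("series ", s, ": value out of [0, arity) for gene ",
           genes$names[bad[1L]], " at time ", bad[2L])
    }
    series[[s]] <- m
  }
  structure(list(series = series, genes = genes, periodic = isTRUE(periodic)),
            class = "ccit_dataset")
}

#' @export
print.ccit_dataset <- function(x, ...) {
  cat("Discrete time-series dataset:", length(x$genes$names), "genes,",
      length(x$series), "series of",
      paste(vapply(x$series, ncol, 0L), collapse = "/"), "time points",
      if (x$periodic) "(periodic)" else "(aperiodic)", "\n")
  invisible(x)
}

## Detect the delimiter of a text table: tab wins if present, else comma.
detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Read a gene-expression matrix from delimited text
#'
#' Reads a TSV/CSV matrix with one header line of identifiers and returns it
#' in genes-by-time orientation together with the gene names, regardless of
#' the orientation on disk.
#'
#' @param path file path; tab- or comma-separated, header line required.
#' @param orientation `"genes_in_rows"` (first column = gene names, remaining
#'   columns = time points) or `"genes_in_columns"` (header = gene names, one
#'   row per time point).
#' @return list with `matrix` (numeric, genes x time) and `genes` (character).
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows",
                                                   "genes_in_columns")) {
  orientation <- match.arg(orientation)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "")
  if (orientation == "genes_in_rows") {
    genes <- df[[1L]]
    body <- df[, -1L, drop = FALSE]
    nums <- as.matrix(body)
  } else {
    genes <- colnames(df)
    nums <- t(as.matrix(df))
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene names in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  val <- suppressWarnings(array(as.numeric(nums), dim(nums)))
  if (any(is.na(val) & !is.na(nums))) {
    bad <- which(is.na(val) & !is.na(nums), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell in ", path, " for gene ", genes[bad[1L]],
         " at time point ", bad[2L], ": '", nums[bad[1L], bad[2L]], "'")
  }
  if (any(is.na(val))) stop("missing values in ", path)
  dimnames(val) <- list(genes, NULL)
  message("read ", length(genes), " genes x ", ncol(val),
          " time points from ", path)
  list(matrix = val, genes = genes)
}

#' Read / write a delay-annotated network as a 3-column edge list
#'
#' The on-disk format is delimited text with a header and three columns:
#' regulator, target, lag.  `write_network_edgelist` followed by
#' `read_network_edgelist` is the identity on arc sets; lag-0 acyclicity is
#' validated on read.
#'
#' @param path file path.
#' @param genes optional [gene_table]; if omitted, genes are collected from
#'   the file in order of first appearance with `default_arity` levels.
#' @param d_max maximum lag for the resulting network (default: largest lag
#'   in the file, or 3 for an empty file).
#' @param default_arity arity assigned when `genes` is not supplied.
#' @param allow_self_lagged passed to [ccit_network()].
#' @return `read_network_edgelist`: a [ccit_network];
#'   `write_network_edgelist`: the path, invisibly.
#' @export
read_network_edgelist <- function(path, genes = NULL, d_max = NULL,
                                  default_arity = 2L,
                                  allow_self_lagged = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) {
    if (is.null(genes)) stop("empty edge list needs an explicit gene table")
    return(ccit_network(genes, NULL, d_max = if (is.null(d_max)) 3L else d_max,
                        allow_self_lagged = allow_self_lagged))
  }
  sep <- detect_sep(path)
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 3L) stop("edge list must have columns regulator, target, lag")
  names(df)[1:3] <- c("from", "to", "lag")
  if (!is.numeric(df$lag)) stop("lag column must be numeric in ", path)
  if (is.null(genes)) {
    seen <- unique(c(rbind(as.character(df$from), as.character(df$to))))
    genes <- gene_table(seen, default_arity)
  }
  if (is.null(d_max)) d_max <- max(3L, max(as.integer(df$lag)))
  message("read ", nrow(df), " arcs from ", path)
  ccit_network(genes, df, d_max = d_max, allow_self_lagged = allow_self_lagged)
}

#' @rdname read_network_edgelist
#' @param network a [ccit_network] to serialize.
#' @export
write_network_edgelist <- function(network, path) {
  stopifnot(inherits(network, "ccit_network"))
  df <- data.frame(regulator = network$genes$names[network$arcs$from],
                   target    = network$genes$names[network$arcs$to],
                   lag       = network$arcs$lag)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network to Graphviz DOT format
#'
#' Lag-0 arcs are drawn solid and unlabeled; delayed arcs carry their lag as
#' an edge label and are drawn dashed.  All genes appear as nodes even when
#' isolated.
#'
#' @param network a [ccit_network].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
export_dot <- function(network, path) {
  stopifnot(inherits(network, "ccit_network"))
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("digraph grn {", paste0("  ", q(network$genes$names), ";"))
  a <- network$arcs
  if (nrow(a) > 0L) {
    attr_str <- ifelse(a$lag == 0L, "",
                       paste0(" [label=\"", a$lag, "\", style=dashed]"))
    lines <- c(lines, paste0("  ", q(network$genes$names[a$from]), " -> ",
                             q(network$genes$names[a$to]), attr_str, ";"))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
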