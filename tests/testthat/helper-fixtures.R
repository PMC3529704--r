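## Shared fixtures: the worked four-gene network with two instantaneous and
## two first-order delayed arcs (A->B and D->B at lag 0, C->B and D->A at
## lag 1), plus small simulated datasets built in code.

worked_network <- function(arity = 3L, d_max = 1L) {
  g <- gene_table(c("A", "B", "C", "D"), arity)
  ccit_network(g, data.frame(from = c("A", "D", "C", "D"),
                             to = c("B", "B", "B", "A"),
                             lag = c(0L, 0L, 1L, 1L)), d_max = d_max)
}

## Binary data generated from the worked structure: B depends jointly on
## (A at lag 0, D at lag 0, C at lag 1) through noisy majority voting,
## A depends on D at lag 1, C and D are fair coins.
worked_truth <- function() {
  net <- worked_network(arity = 2L)
  uni <- make_cpd("table", integer(0), 2L,
                  params = list(table = rbind(c(0.5, 0.5))))
  cpds <- list(
    make_cpd("binomial", 2L, 2L, params = list(excite = TRUE)),     # A | D1
    make_cpd("binomial", rep(2L, 3L), 2L,
             params = list(excite = c(TRUE, FALSE, TRUE))),         # B
    uni,                                                            # C
    uni)                                                            # D
  ccit_truth(net, cpds)
}

## Independent uniform binary noise, n genes x N time points.
noise_dataset <- function(n, N, seed = 1L, arity = 2L) {
  set.seed(seed)
  m <- matrix(sample.int(arity, n * N, replace = TRUE) - 1L, n, N)
  rownames(m) <- paste0("G", seq_len(n))
  ccit_dataset(m, gene_table(rownames(m), arity))
}

## Brute-force plug-in MI over every cell, independent of the package path.
mi_bruteforce <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p); py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) total <- total + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  total
}

## Brute-force conditional MI via the triple sum.
cmi_bruteforce <- function(a) {
  n <- sum(a)
  p <- a / n
  total <- 0
  for (x in seq_len(dim(a)[1])) for (y in seq_len(dim(a)[2])) {
    for (z in seq_len(dim(a)[3])) {
      if (p[x, y, z] > 0) {
        pz <- sum(p[, , z]); pxz <- sum(p[x, , z]); pyz <- sum(p[, y, z])
        total <- total + p[x, y, z] * log(pz * p[x, y, z] / (pxz * pyz))
      }
    }
  }
  total
}
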