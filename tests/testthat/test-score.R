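test_that("plug-in MI matches closed forms and a cell-by-cell oracle", {
  expect_equal(mutual_information(matrix(c(5, 0, 0, 5), 2)), log(2))
  expect_equal(mutual_information(matrix(25, 2, 2)), 0)
  expect_equal(mutual_information(matrix(c(4, 1, 1, 4), 2)),
               mi_bruteforce(matrix(c(4, 1, 1, 4), 2)), tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:20) {
    counts <- matrix(rpois(12, 5), 3, 4)
    if (sum(counts) == 0) next
    expect_equal(mutual_information(counts), mi_bruteforce(counts),
                 tolerance = 1e-12)
    expect_gte(mutual_information(counts), 0)
  }
  expect_error(mutual_information(matrix(0, 2, 2)), "all zero")
  # base conversion for display
  expect_equal(mutual_information(matrix(c(5, 0, 0, 5), 2), base = 2), 1)
})

test_that("conditional MI matches its oracle and degenerate cases", {
  # X independent of Y given Z, exactly
  a <- array(0, c(2, 2, 2))
  a[, , 1] <- outer(c(6, 2), c(3, 1)) / 4
  a[, , 2] <- outer(c(1, 3), c(2, 6)) / 4
  expect_equal(conditional_mi(a), 0, tolerance = 1e-12)
  # constant Z reduces to unconditional MI
  b <- array(0, c(2, 2, 2))
  b[, , 1] <- matrix(c(4, 1, 1, 4), 2)
  expect_equal(conditional_mi(b), mutual_information(b[, , 1]))
  # random tables against the brute-force triple sum
  set.seed(23)
  for (rep in 1:20) {
    cc <- array(rpois(8, 4), c(2, 2, 2))
    if (sum(cc) == 0) next
    expect_equal(conditional_mi(cc), max(cmi_bruteforce(cc), 0),
                 tolerance = 1e-12)
  }
})

test_that("MI decomposes by the chain rule on exhaustive small tables", {
  # MI(X, {A, B}) = MI(X, A) + MI(X, B | A), checked to 1e-10 by
  # enumerating every joint count assignment of a 2x2x2 table with small
  # totals (zero-inclusive)
  vals <- 0:2
  grid <- expand.grid(rep(list(vals), 8))
  set.seed(31)
  grid <- grid[sample(nrow(grid), 400), ]
  for (r in seq_len(nrow(grid))) {
    cnt <- array(as.numeric(grid[r, ]), c(2, 2, 2))  # [x, a, b]
    if (sum(cnt) == 0) next
    joint <- matrix(aperm(cnt, c(1, 2, 3)), nrow = 2)  # X vs (A,B) joint
    mi_joint <- mutual_information(joint)
    mi_a <- mutual_information(apply(cnt, c(1, 2), sum))
    cmi_b_given_a <- conditional_mi(aperm(cnt, c(1, 3, 2)))  # (X, B | A)
    expect_equal(mi_joint, mi_a + cmi_b_given_a, tolerance = 1e-10)
  }
})

test_that("2N * MI in nats equals the likelihood-ratio G-statistic", {
  set.seed(41)
  for (rep in 1:10) {
    counts <- matrix(rpois(9, 8) + 1, 3, 3)
    n <- sum(counts)
    expected <- outer(rowSums(counts), colSums(counts)) / n
    g_stat <- 2 * sum(counts * log(counts / expected))
    expect_equal(2 * n * mutual_information(counts), g_stat,
                 tolerance = 1e-9)
  }
})

test_that("degrees of freedom follow the ordered product rule", {
  expect_identical(degrees_of_freedom(3, 3, 1), 4L)
  expect_identical(degrees_of_freedom(3, c(3, 3), 2), 12L)
  expect_identical(degrees_of_freedom(3, c(3, 3, 3), 3), 36L)
  expect_identical(degrees_of_freedom(2, 2, 1), 1L)
  # mixed arities: sorting is internal, so listing order is irrelevant
  expect_identical(degrees_of_freedom(3, c(2, 4), 2),
                   degrees_of_freedom(3, c(4, 2), 2))
  expect_identical(degrees_of_freedom(3, c(4, 2), 1), (3L - 1L) * (4L - 1L))
  expect_identical(degrees_of_freedom(3, c(4, 2), 2), 2L * 1L * 4L)
  expect_error(degrees_of_freedom(3, c(3, 3), 3), "j must be")
})

test_that("descending-arity ordering maximizes the summed penalty", {
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  penalty_in_order <- function(ri, arities, alpha) {
    sum(vapply(seq_along(arities), function(j) {
      base <- (ri - 1) * (arities[j] - 1)
      df <- if (j == 1) base else base * prod(arities[seq_len(j - 1)])
      qchisq(alpha, df)
    }, 0))
  }
  set.seed(53)
  for (rep in 1:15) {
    ri <- sample(2:4, 1)
    arities <- sample(2:4, sample(2:4, 1), replace = TRUE)
    alpha <- runif(1, 0.5, 0.99)
    all_vals <- vapply(perms(arities),
                       function(p) penalty_in_order(ri, p, alpha), 0)
    expect_equal(order_penalty(ri, arities, alpha), max(all_vals),
                 tolerance = 1e-9)
  }
  # the worked mixed-arity case: descending [3,2] gives df (4,6), beating
  # ascending [2,3] with df (2,8)
  expect_equal(order_penalty(3, c(3, 2), 0.9),
               qchisq(0.9, 4) + qchisq(0.9, 6))
  expect_gte(order_penalty(3, c(3, 2), 0.9),
             qchisq(0.9, 2) + qchisq(0.9, 8))
  expect_equal(order_penalty(2, 2, 0.77), qchisq(0.77, 1))
})

test_that("the worked 3-level example yields the printed penalty structure", {
  # child B with lag-0 parents {A, D} and lag-1 parent {C}, all 3-level:
  # per-order penalization gives 2 * chi(a,4) + chi(a,12); penalizing the
  # whole set as one class gives chi(a,4) + chi(a,12) + chi(a,36)
  net <- worked_network(arity = 3L)
  set.seed(2)
  m <- matrix(sample(0:2, 4 * 30, TRUE), 4, 30,
              dimnames = list(net$genes$names, NULL))
  ds <- ccit_dataset(m, net$genes, periodic = TRUE)

  alpha <- 0.9
  b_parents <- data.frame(parent = c("A", "D", "C"), lag = c(0, 0, 1))
  per <- ccitnet:::penalty_terms(net$genes, 2L,
           ccitnet:::canonical_parents(net$genes, b_parents),
           score_config(alpha = alpha, penalty_mode = "per_order"))
  expect_equal(sort(per$df), c(4L, 4L, 12L))
  expect_equal(sum(per$chi), 2 * qchisq(alpha, 4) + qchisq(alpha, 12))

  joint <- ccitnet:::penalty_terms(net$genes, 2L,
             ccitnet:::canonical_parents(net$genes, b_parents),
             score_config(alpha = alpha, penalty_mode = "joint"))
  expect_equal(sort(joint$df), c(4L, 12L, 36L))
  expect_equal(sum(joint$chi),
               qchisq(alpha, 4) + qchisq(alpha, 12) + qchisq(alpha, 36))

  # whole network: three chi(a,4) terms plus one chi(a,12)
  sc <- ccit_score(net, ds)
  expect_equal(sort(sc$penalties$df), c(4L, 4L, 4L, 12L))
  expect_equal(sum(sc$penalties$chi),
               3 * qchisq(alpha, 4) + qchisq(alpha, 12))
  # and the total is the joint-MI part minus that penalty
  mi_b <- joint_mi(ds, "B", b_parents)
  mi_a <- joint_mi(ds, "A", data.frame(parent = "D", lag = 1))
  expect_equal(sc$total,
               2 * 30 * (mi_b$mi + mi_a$mi) -
                 (3 * qchisq(alpha, 4) + qchisq(alpha, 12)),
               tolerance = 1e-9)
})

test_that("empty parent sets score zero and totals decompose", {
  ds <- noise_dataset(4, 40, seed = 77)
  expect_equal(ccit_local_score(ds, 1, NULL), 0)
  net <- ccit_network(ds$genes)                      # empty network
  expect_equal(ccit_score(net, ds)$total, 0)

  set.seed(78)
  net2 <- random_network(ds$genes, 5, d_max = 2)
  sc <- ccit_score(net2, ds)
  locals <- vapply(seq_len(4), function(i) {
    p <- net2$arcs[net2$arcs$to == i, c("from", "lag")]
    names(p) <- c("parent", "lag")
    ccit_local_score(ds, i, p)
  }, 0)
  expect_equal(sc$total, sum(locals), tolerance = 1e-9)
  expect_equal(sc$total, sum(sc$per_node$local), tolerance = 1e-9)
})

test_that("joint MI behaves like a consistent dependence measure", {
  # independence: near zero at large N
  set.seed(91)
  N <- 2000
  m <- matrix(sample(0:1, 3 * N, TRUE), 3, N,
              dimnames = list(c("x", "a", "b"), NULL))
  ds <- ccit_dataset(m, gene_table(c("x", "a", "b"), 2L))
  jm <- joint_mi(ds, "x", data.frame(parent = c("a", "b"), lag = c(0, 0)))
  expect_lt(jm$mi, 0.01)
  # deterministic XOR of two balanced lag-0 parents: exactly log 2 (the
  # child entropy, since the child is a function of the joint state)
  a_bal <- rep(c(0L, 1L), each = 50)
  b_bal <- rep(c(0L, 1L), times = 50)
  x <- as.integer(xor(a_bal, b_bal))
  m2 <- rbind(x = x, a = a_bal, b = b_bal)
  ds2 <- ccit_dataset(m2, gene_table(c("x", "a", "b"), 2L))
  jm2 <- joint_mi(ds2, "x", data.frame(parent = c("a", "b"), lag = c(0, 0)))
  expect_equal(jm2$mi, log(2), tolerance = 1e-12)
  # while each single parent alone carries exactly none
  expect_equal(joint_mi(ds2, "x", data.frame(parent = "a", lag = 0))$mi, 0,
               tolerance = 1e-12)
})

test_that("score is invariant to parent listing order and gene relabeling", {
  ds <- noise_dataset(4, 60, seed = 13, arity = 3)
  p1 <- data.frame(parent = c(2, 3, 4), lag = c(0, 1, 2))
  p2 <- p1[c(3, 1, 2), ]
  expect_equal(ccit_local_score(ds, 1, p1), ccit_local_score(ds, 1, p2))

  # relabeling: permute genes in data and network together
  set.seed(14)
  net <- random_network(ds$genes, 4, d_max = 2)
  perm <- sample(4)
  m <- ds$series[[1]][perm, ]
  rownames(m) <- paste0("G", 1:4)
  ds_p <- ccit_dataset(m, gene_table(rownames(m), 3L))
  arcs_p <- data.frame(from = match(net$arcs$from, perm),
                       to = match(net$arcs$to, perm), lag = net$arcs$lag)
  net_p <- ccit_network(ds_p$genes, arcs_p, d_max = 2)
  expect_equal(ccit_score(net_p, ds_p)$total, ccit_score(net, ds)$total,
               tolerance = 1e-9)
})

test_that("per-order penalties never exceed joint penalties", {
  # with more than one populated lag class, penalizing per class is at most
  # the single-class penalization of the identical parent set
  set.seed(19)
  for (rep in 1:25) {
    n_par <- sample(2:5, 1)
    arities <- sample(2:4, n_par + 1, replace = TRUE)
    g <- gene_table(paste0("G", seq_len(n_par + 1)), arities)
    parents <- data.frame(parent = 1 + seq_len(n_par),
                          lag = sample(0:3, n_par, replace = TRUE))
    per <- ccitnet:::penalty_terms(g, 1L, parents,
                                   score_config(penalty_mode = "per_order"))
    joint <- ccitnet:::penalty_terms(g, 1L, parents,
                                     score_config(penalty_mode = "joint"))
    if (length(unique(parents$lag)) > 1L) {
      expect_lt(sum(per$chi), sum(joint$chi))
    } else {
      expect_equal(sum(per$chi), sum(joint$chi))
    }
  }
})

test_that("baselines collapse correctly on single-plane networks", {
  ds <- noise_dataset(4, 50, seed = 55)
  g <- ds$genes
  only0 <- ccit_network(g, data.frame(from = c(1, 2), to = c(2, 3),
                                      lag = c(0, 0)))
  s0 <- mit_scores(only0, ds)
  expect_equal(s0$mit1, 0)
  expect_equal(s0$mit01, s0$mit0)
  only1 <- ccit_network(g, data.frame(from = c(1, 2), to = c(2, 3),
                                      lag = c(1, 2)))
  s1 <- mit_scores(only1, ds)
  expect_equal(s1$mit0, 0)
  expect_equal(s1$mit01, s1$mit1)
})

test_that("concurrent scoring differs from the naive split exactly when the
           delayed parent matters", {
  # data generated from the worked structure with a B that genuinely
  # depends on C at lag 1
  truth <- worked_truth()
  ds <- sample_timeseries(truth, N = 300, seed = 123)
  ds$periodic <- TRUE  # all nodes then share the same effective N
  net <- truth$network
  cc <- ccit_score(net, ds)$total
  ms <- mit_scores(net, ds)
  expect_gt(abs(cc - ms$mit01), 1e-6)

  # removing C's arc makes the two scorings coincide
  arcs2 <- net$arcs[!(net$arcs$from == 3L & net$arcs$to == 2L), ]
  net2 <- ccit_network(net$genes, arcs2, d_max = 1)
  expect_equal(ccit_score(net2, ds)$total, mit_scores(net2, ds)$mit01,
               tolerance = 1e-9)
})
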