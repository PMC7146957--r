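# Markov Clustering core: matrix construction, expansion, inflation,
# cluster extraction, and agreement with an independent dense iteration.

test_that("build_matrix yields a column-stochastic matrix", {
  n1 <- make_network("A")
  expect_equal(build_matrix(n1, self_loop = 1),
               matrix(1, 1, 1, dimnames = list("A", "A")))

  n2 <- make_network(c("A", "B"),
                     data.frame(from = "A", to = "B", weight = 1))
  M2 <- build_matrix(n2, self_loop = 1)
  expect_equal(unname(M2), matrix(0.5, 2, 2))

  n3 <- make_network(c("A", "B", "C"),
                     data.frame(from = c("A", "B"), to = c("B", "C"),
                                weight = c(1, 1)))
  expect_equal(colSums(build_matrix(n3)), c(A = 1, B = 1, C = 1))
})

test_that("expansion equals a naive triple-loop product", {
  I4 <- diag(4)
  expect_equal(mcl_expand(I4), I4)
  P <- matrix(0.5, 2, 2)
  expect_equal(mcl_expand(P), P)

  set.seed(3)
  M <- matrix(runif(16), 4, 4)
  M <- sweep(M, 2, colSums(M), "/")
  naive <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4)
    for (k in 1:4) naive[i, j] <- naive[i, j] + M[i, k] * M[k, j]
  expect_equal(mcl_expand(M), naive, tolerance = 1e-12)
})

test_that("inflation raises entries to r and renormalizes columns", {
  det_col <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(mcl_inflate(det_col, 2), det_col)
  expect_equal(mcl_inflate(matrix(0.5, 2, 2), 2), matrix(0.5, 2, 2))
  # hand-derived: 0.8^2 / (0.8^2 + 0.2^2) = 0.64 / 0.68
  M <- matrix(c(0.8, 0.2), 2, 1)
  expect_equal(mcl_inflate(M, 2), matrix(c(0.64, 0.04) / 0.68, 2, 1),
               tolerance = 1e-12)
  expect_error(mcl_inflate(M, 1), "inflation")
})

test_that("disconnected cliques can never merge", {
  cl <- function(nodes) {
    p <- t(combn(nodes, 2))
    data.frame(from = p[, 1], to = p[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }
  net <- make_network(sprintf("N%d", 1:6),
                      rbind(cl(sprintf("N%d", 1:3)),
                            cl(sprintf("N%d", 4:6))))
  part <- mcl(net, inflation = 1.5)
  expect_identical(canon_partition(part),
                   canon_partition(list(c("N1", "N2", "N3"),
                                        c("N4", "N5", "N6"))))
})

test_that("a single node and isolated nodes become singletons", {
  expect_identical(canon_partition(mcl(make_network("A"))),
                   list("A"))
  net <- make_network(c("A", "B", "C"),
                      data.frame(from = "A", to = "B", weight = 1))
  part <- mcl(net, inflation = 1.5)
  expect_true(any(vapply(part, identical, logical(1), "C")))
})

test_that("a weak bridge between cliques splits at high inflation", {
  cl <- function(nodes) {
    p <- t(combn(nodes, 2))
    data.frame(from = p[, 1], to = p[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(cl(sprintf("N%d", 1:3)), cl(sprintf("N%d", 4:6)),
                 data.frame(from = "N3", to = "N4", weight = 0.1))
  net <- make_network(sprintf("N%d", 1:6), edges)
  part <- mcl(net, inflation = 2.0)
  expect_identical(canon_partition(part),
                   canon_partition(list(sprintf("N%d", 1:3),
                                        sprintf("N%d", 4:6))))
  # independent oracle agrees
  W <- gomclust:::network_matrix(net)
  expect_identical(canon_partition(part),
                   canon_partition(lapply(oracle_mcl(W, 2.0),
                                          function(ix) rownames(W)[ix])))
})

test_that("extract_clusters reads attractors deterministically", {
  # identity limit: every node its own attractor
  I3 <- diag(3)
  dimnames(I3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_identical(canon_partition(extract_clusters(I3)),
                   list("A", "B", "C"))

  # block limit: all mass of each column on the block attractor row
  M <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  M["a", c("a", "b")] <- 1
  M["c", c("c", "d")] <- 1
  expect_identical(canon_partition(extract_clusters(M)),
                   canon_partition(list(c("a", "b"), c("c", "d"))))

  # node claimed by two attractors goes to the larger entry
  M2 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  M2["a", "a"] <- 1; M2["c", "c"] <- 1
  M2["a", "b"] <- 0.7; M2["c", "b"] <- 0.3
  expect_identical(canon_partition(extract_clusters(M2)),
                   canon_partition(list(c("a", "b"), "c")))
})

test_that("mcl is deterministic and always returns a strict partition", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    nodes <- sprintf("N%02d", seq_len(n))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.4
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                        weight = sample(c(0.5, 1), sum(keep), TRUE),
                        stringsAsFactors = FALSE)
    net <- make_network(nodes, edges)
    p1 <- mcl(net, inflation = 1.5)
    p2 <- mcl(net, inflation = 1.5)
    expect_identical(p1, p2)
    members <- unlist(p1)
    expect_identical(sort(members), sort(nodes))
    expect_false(anyDuplicated(members) > 0)
    # every cluster sits inside one connected component
    g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                       vertices = nodes)
    comp <- igraph::components(g)$membership
    for (cl in p1)
      expect_identical(length(unique(comp[cl])), 1L)
  }
})

test_that("partitions agree with the independent oracle on small graphs", {
  # exhaustive over all weightings {0, 0.5, 1} of the 3 pairs at n = 3
  nodes <- c("N1", "N2", "N3")
  pairs <- t(combn(nodes, 2))
  for (code in 0:(3^3 - 1)) {
    w <- c(0, 0.5, 1)[(code %/% 3^(0:2)) %% 3 + 1]
    keep <- w > 0
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                        weight = w[keep], stringsAsFactors = FALSE)
    net <- make_network(nodes, edges)
    for (infl in c(1.5, 2)) {
      got <- canon_partition(mcl(net, inflation = infl))
      W <- gomclust:::network_matrix(net)
      want <- canon_partition(lapply(oracle_mcl(W, infl),
                                     function(ix) rownames(W)[ix]))
      expect_identical(got, want,
                       info = sprintf("code=%d inflation=%.1f", code, infl))
    }
  }
})
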