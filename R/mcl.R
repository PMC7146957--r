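# Markov Clustering (MCL) of the weighted similarity network.
#
# The algorithm simulates flow on the graph: the column-stochastic
# transition matrix is alternately squared ("expansion", spreading flow
# along paths) and taken to an entrywise power with column renormalization
# ("inflation", favouring strong currents). The iteration converges to a
# near-idempotent limit whose attractors (nodes retaining mass on their own
# diagonal) define the clusters. Inflation is the granularity knob: larger
# values give more, smaller clusters.

#' Build the MCL transition matrix from a similarity network
#'
#' Edge weights form the adjacency; a self-loop of weight `self_loop` is
#' added to every node (guaranteeing aperiodicity of the walk) and columns
#' are normalized to sum to one.
#'
#' @param net A `similarity_network`.
#' @param self_loop Non-negative self-loop weight added to the diagonal
#'   before normalization; default 1.
#' @return A column-stochastic matrix with node accessions as dimnames.
#' @export
build_matrix <- function(net, self_loop = 1) {
  if (!length(net$nodes)) stop("network has no nodes")
  W <- network_matrix(net)
  diag(W) <- diag(W) + self_loop
  sweep(W, 2, colSums(W), "/")
}

#' MCL expansion: square the transition matrix
#'
#' @param M A column-stochastic matrix.
#' @return `M %*% M`.
#' @export
mcl_expand <- function(M) M %*% M

#' MCL inflation: entrywise power and column renormalization
#'
#' Each entry is raised to the power `r`; entries falling below the pruning
#' floor are zeroed; columns are renormalized to sum to one.
#'
#' @param M A column-stochastic matrix.
#' @param r Inflation exponent, must exceed 1.
#' @param prune Entries below this value are set to zero before
#'   renormalization (keeps the limit sparse and the iteration stable);
#'   default `1e-5`.
#' @return The inflated column-stochastic matrix.
#' @export
mcl_inflate <- function(M, r, prune = 1e-5) {
  if (r <= 1) stop("inflation must be > 1 (got ", r, ")")
  M <- M^r
  M[M < prune] <- 0
  cs <- colSums(M)
  cs[cs == 0] <- 1  # fully pruned column: leave as zero (cannot happen with self-loops)
  sweep(M, 2, cs, "/")
}

#' Cluster a similarity network with Markov Clustering
#'
#' Runs the expansion/inflation iteration from [build_matrix()] until the
#' largest absolute entry change drops below `tol` or `max_iter` rounds
#' have run, then extracts the partition from the limit matrix with
#' [extract_clusters()]. The whole procedure is deterministic.
#'
#' @param net A `similarity_network`.
#' @param inflation Granularity; default 1.5.
#' @param self_loop Self-loop weight, see [build_matrix()].
#' @param max_iter Maximum iterations; default 100. Non-convergence raises
#'   a warning and clusters are read from the last iterate.
#' @param tol Convergence tolerance on the max entry change; default 1e-6.
#' @param prune Pruning floor, see [mcl_inflate()].
#' @param verbose Log the per-iteration max change.
#' @return A `cluster_partition`: list of character vectors of node
#'   accessions, pairwise disjoint and jointly covering the node set.
#' @export
mcl <- function(net, inflation = 1.5, self_loop = 1, max_iter = 100,
                tol = 1e-6, prune = 1e-5, verbose = FALSE) {
  M <- build_matrix(net, self_loop = self_loop)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M_new <- mcl_inflate(mcl_expand(M), inflation, prune = prune)
    delta <- max(abs(M_new - M))
    if (verbose) vlog(sprintf("mcl iter %3d  max change %.3e", it, delta))
    M <- M_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; extracting clusters from the last iterate")
  gene_w <- NULL
  if (!is.null(net$terms) && !is.null(net$terms$x))
    gene_w <- setNames(net$terms$x, net$terms$go_id)[colnames(M)]
  extract_clusters(M, gene_weights = gene_w)
}

#' Extract the node partition from a converged MCL matrix
#'
#' Attractors are nodes with positive diagonal mass; attractors that carry
#' mass on each other belong to one attractor system, and each system's
#' cluster is the set of nodes with positive entries in its attractor
#' rows. A node claimed by several systems is assigned to the system with
#' the largest entry; exact ties go to the system whose cluster carries
#' more total test-set genes, then to the lexicographically smallest
#' attractor accession — so the result is always a strict partition.
#'
#' @param M A converged (near-idempotent) MCL iterate with dimnames.
#' @param gene_weights Optional named vector of per-node test-set gene
#'   counts used in tie-breaking.
#' @param eps Positivity threshold; default 1e-9.
#' @param tie_tol Entries within this distance of the best claim are
#'   treated as exactly tied (the iterate is only converged to a finite
#'   tolerance, so sub-tolerance differences are numerical noise);
#'   default 1e-5.
#' @return A `cluster_partition`.
#' @export
extract_clusters <- function(M, gene_weights = NULL, eps = 1e-9,
                             tie_tol = 1e-5) {
  nodes <- colnames(M)
  if (is.null(nodes)) nodes <- as.character(seq_len(ncol(M)))
  m <- ncol(M)

  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- seq_len(m)  # degenerate safeguard

  # union attractor systems: i ~ j when either row holds mass on the other
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in attractors) for (j in attractors)
    if (i < j && (M[i, j] > eps || M[j, i] > eps)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  sys_of <- vapply(attractors, find, integer(1))
  systems <- split(attractors, sys_of)

  # candidate membership and per-system score for every node
  score <- matrix(0, length(systems), m)
  for (s in seq_along(systems)) {
    rows <- M[systems[[s]], , drop = FALSE]
    score[s, ] <- apply(rows, 2, max)
  }
  claimed <- score > eps

  sys_genes <- vapply(seq_along(systems), function(s) {
    mem <- nodes[claimed[s, ]]
    if (is.null(gene_weights)) 0 else sum(gene_weights[mem], na.rm = TRUE)
  }, numeric(1))
  sys_anchor <- vapply(systems, function(rows) min(nodes[rows]), character(1))

  assign <- integer(m)
  for (v in seq_len(m)) {
    cand <- which(claimed[, v])
    if (!length(cand)) { assign[v] <- 0L; next }  # resolved below
    best <- cand[score[cand, v] >= max(score[cand, v]) - tie_tol]
    if (length(best) > 1) {
      best <- best[sys_genes[best] == max(sys_genes[best])]
      if (length(best) > 1) best <- best[order(sys_anchor[best])][1]
    }
    assign[v] <- best[1]
  }
  # nodes claimed by no attractor row (numerically starved): follow the
  # column's dominant row, inheriting its assignment; give up after m hops
  for (v in which(assign == 0L)) {
    cur <- v
    for (hop in seq_len(m)) {
      cur <- which.max(M[, cur])
      if (assign[cur] != 0L) { assign[v] <- assign[cur]; break }
    }
    if (assign[v] == 0L) assign[v] <- 1L
  }

  clusters <- lapply(split(seq_len(m), assign), function(ix) sort(nodes[ix]))
  clusters <- unname(clusters[order(vapply(clusters, `[`, character(1), 1))])
  structure(clusters, class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("Cluster partition:", length(x), "clusters over", sum(lengths(x)),
      "nodes; sizes:", paste(sort(lengths(x), decreasing = TRUE),
                             collapse = ", "), "\n")
  invisible(x)
}

# strict-partition sanity check used by the pipeline and tests
validate_partition <- function(partition, nodes) {
  members <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(members))
    stop("partition is not disjoint: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  if (!setequal(members, nodes))
    stop("partition does not cover the node set")
  invisible(TRUE)
}
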