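# End-to-end orchestration: trim -> similarity network -> MCL -> ordered,
# labeled clusters with representative terms; plus sub-clustering of
# selected clusters with tighter parameters.

#' Cluster an enriched GO term list
#'
#' Runs the full procedure: resolve accessions against the ontology
#' (alternate ids mapped, unknown/obsolete terms dropped with a warning),
#' trim overly broad terms (`n > max_size`), optionally restrict
#' namespaces, build the similarity network at the chosen metric and
#' cutoff, partition it with Markov Clustering, order clusters by the size
#' of their gene unions, and pick representative terms per cluster. The
#' run is deterministic end to end.
#'
#' @param x An `enrichment_list` from [read_enrichment()].
#' @param graph An `ontology_graph` from [read_obo()].
#' @param metric `"OC"` (default) or `"JC"`.
#' @param cutoff Similarity cutoff for network edges; default 0.5.
#' @param inflation MCL granularity; default 1.5.
#' @param max_size Largest reference annotation size retained; default 3500.
#' @param namespaces Optional namespace subset (see [filter_namespaces()]);
#'   `NULL` keeps all.
#' @param self_loop,prune,tol,max_iter MCL numerical controls, see [mcl()].
#' @return A `gomcl_result`: list with `clusters` (ordered list of
#'   `go_cluster` records: `label`, `members` data frame, `gene_union`,
#'   `representatives`), `network`, `terms` (post-trim term table with
#'   `cluster` and `depth` columns), `parameters`, `dropped`.
#' @export
run_gomcl <- function(x, graph, metric = c("OC", "JC"), cutoff = 0.5,
                      inflation = 1.5, max_size = 3500, namespaces = NULL,
                      self_loop = 1, prune = 1e-5, tol = 1e-6,
                      max_iter = 100) {
  metric <- match.arg(metric)
  stopifnot(cutoff >= 0, cutoff <= 1, inflation > 1)

  res <- resolve_enrichment_ids(x, graph)
  lst <- res$list
  lst <- trim_terms(lst, max_size, graph = graph, keep = namespaces)
  if (!nrow(lst))
    stop("no terms left after trimming at max_size = ", max_size,
         "; consider a larger max_size")
  # refresh namespaces from the ontology even when no filter was requested
  lst$namespace <- vapply(lst$go_id, function(a) graph$terms[[a]]$namespace,
                          character(1), USE.NAMES = FALSE)

  net <- build_network(lst, metric = metric, cutoff = cutoff)
  partition <- mcl(net, inflation = inflation, self_loop = self_loop,
                   max_iter = max_iter, tol = tol, prune = prune)
  validate_partition(partition, net$nodes)

  clusters <- order_clusters(partition, lst)
  clusters <- lapply(clusters, function(cl) {
    cl$representatives <- select_representatives(cl, net)
    cl
  })

  depth <- term_depth_table(graph)
  terms <- as.data.frame(lst)
  terms$depth <- unname(depth[terms$go_id])
  lab <- setNames(rep(vapply(clusters, `[[`, character(1), "label"),
                      vapply(clusters, function(cl) nrow(cl$members),
                             integer(1))),
                  unlist(lapply(clusters, function(cl) cl$members$go_id)))
  terms$cluster <- unname(lab[terms$go_id])

  structure(list(
    clusters = clusters, network = net, terms = terms,
    parameters = list(metric = metric, cutoff = cutoff,
                      inflation = inflation, max_size = max_size,
                      namespaces = namespaces %||% GO_NAMESPACES,
                      self_loop = self_loop, prune = prune, tol = tol,
                      max_iter = max_iter,
                      obo_data_version = graph$data_version,
                      tool_version = as.character(
                        utils::packageVersion("gomclust"))),
    dropped = res$dropped), class = "gomcl_result")
}

#' @export
print.gomcl_result <- function(x, ...) {
  p <- x$parameters
  cat("GO term clustering:", nrow(x$terms), "terms ->", length(x$clusters),
      "clusters [", p$metric, ">=", p$cutoff, ", inflation", p$inflation,
      ", max term size", p$max_size, "]\n")
  for (cl in utils::head(x$clusters, 10))
    cat(sprintf("  %-6s %3d terms, %4d genes; rep: %s\n", cl$label,
                nrow(cl$members), length(cl$gene_union),
                cl$representatives$go_id[
                  cl$representatives$tag == "most_genes"][1]))
  if (length(x$clusters) > 10)
    cat("  ...", length(x$clusters) - 10, "more clusters\n")
  invisible(x)
}

#' Order a partition into labeled clusters
#'
#' Clusters are sorted by the size of the union of their members' test-set
#' gene sets, descending; ties by member count (descending), then by the
#' smallest member accession. Labels `C1`, `C2`, ... are assigned in
#' sorted order.
#'
#' @param partition A `cluster_partition`.
#' @param x The `enrichment_list` backing the partition's nodes.
#' @param label_prefix Prefix for labels; default `"C"`. Sub-clustering
#'   passes e.g. `"C1-"`.
#' @return List of `go_cluster` records.
#' @export
order_clusters <- function(partition, x, label_prefix = "C") {
  idx <- match(unlist(partition, use.names = FALSE), x$go_id)
  if (anyNA(idx)) stop("partition node absent from term list")
  info <- lapply(partition, function(mem) {
    rows <- x[match(mem, x$go_id), , drop = FALSE]
    list(members = as.data.frame(rows),
         gene_union = sort(unique(unlist(rows$genes))))
  })
  union_size <- vapply(info, function(i) length(i$gene_union), integer(1))
  n_members <- vapply(info, function(i) nrow(i$members), integer(1))
  first_acc <- vapply(info, function(i) min(i$members$go_id), character(1))
  ord <- order(-union_size, -n_members, first_acc)
  out <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    out[[k]] <- structure(list(label = paste0(label_prefix, k),
                               members = info[[i]]$members,
                               gene_union = info[[i]]$gene_union,
                               representatives = NULL),
                          class = "go_cluster")
  }
  out
}

#' Representative GO terms of a cluster
#'
#' Offers up to three candidate representatives: the member annotating the
#' most test-set genes (`most_genes`), the member with the smallest
#' enrichment p-value (`smallest_p`), and the member connected to most
#' other members in the similarity network (`highest_degree`). One term
#' may carry several tags. Ties resolve by smaller p-value, then smaller
#' accession.
#'
#' @param cluster A `go_cluster`.
#' @param net The run's `similarity_network`.
#' @return Data frame with columns `tag`, `go_id`, `description`.
#' @export
select_representatives <- function(cluster, net) {
  mem <- cluster$members
  pick <- function(score) {
    best <- which(score == max(score))
    if (length(best) > 1)
      best <- best[order(mem$p_value[best], mem$go_id[best])]
    best[1]
  }
  deg <- vapply(mem$go_id, function(a) {
    sum((net$edges$from == a & net$edges$to %in% mem$go_id) |
        (net$edges$to == a & net$edges$from %in% mem$go_id))
  }, integer(1))
  i_genes <- pick(mem$x)
  i_p <- pick(-mem$p_value)
  i_deg <- pick(deg)
  data.frame(tag = c("most_genes", "smallest_p", "highest_degree"),
             go_id = mem$go_id[c(i_genes, i_p, i_deg)],
             description = mem$description[c(i_genes, i_p, i_deg)],
             stringsAsFactors = FALSE)
}

#' Sub-cluster selected clusters with tighter parameters
#'
#' Re-runs trimming, network construction and Markov Clustering on the
#' member terms of each selected cluster only — typically with a smaller
#' `max_size` and a larger inflation to expose sub-structure. Members
#' removed by the tighter trim are reported separately as "not passed"
#' rather than silently lost. Sub-groups are labeled `C<k>-1`, `C<k>-2`,
#' ... ordered by gene union, mirroring the parent labeling.
#'
#' @param result A `gomcl_result` from [run_gomcl()].
#' @param clusters Character vector of cluster labels to sub-cluster.
#' @param max_size,cutoff,inflation,metric Overrides; default to the
#'   parent run's values (the usual move is to lower `max_size` and raise
#'   `inflation`).
#' @return A `gomcl_sub_result`: named list (by parent label) of lists
#'   with `clusters` (ordered `go_cluster` records with sub-labels),
#'   `network`, `terms`, `not_passed` (data frame of trimmed-out members),
#'   plus `parameters`.
#' @export
run_gomcl_sub <- function(result, clusters, max_size = NULL, cutoff = NULL,
                          inflation = NULL, metric = NULL) {
  stopifnot(inherits(result, "gomcl_result"))
  p <- result$parameters
  max_size <- max_size %||% p$max_size
  cutoff <- cutoff %||% p$cutoff
  inflation <- inflation %||% p$inflation
  metric <- metric %||% p$metric
  labels <- vapply(result$clusters, `[[`, character(1), "label")
  unknown <- setdiff(clusters, labels)
  if (length(unknown))
    stop("unknown cluster label(s): ", paste(unknown, collapse = ", "))

  subs <- list()
  for (lab in clusters) {
    cl <- result$clusters[[match(lab, labels)]]
    mem <- new_enrichment_list(cl$members, "generic", NA_character_)
    passed <- trim_terms(mem, max_size)
    not_passed <- as.data.frame(
      mem[!(mem$go_id %in% passed$go_id), , drop = FALSE])
    if (!nrow(passed)) {
      subs[[lab]] <- list(clusters = list(), network = NULL,
                          terms = NULL, not_passed = not_passed)
      next
    }
    net <- build_network(passed, metric = metric, cutoff = cutoff)
    partition <- mcl(net, inflation = inflation, self_loop = p$self_loop,
                     max_iter = p$max_iter, tol = p$tol, prune = p$prune)
    validate_partition(partition, net$nodes)
    sub_clusters <- order_clusters(partition, passed,
                                   label_prefix = paste0(lab, "-"))
    sub_clusters <- lapply(sub_clusters, function(sc) {
      sc$representatives <- select_representatives(sc, net)
      sc
    })
    terms <- as.data.frame(passed)
    slab <- setNames(
      rep(vapply(sub_clusters, `[[`, character(1), "label"),
          vapply(sub_clusters, function(sc) nrow(sc$members), integer(1))),
      unlist(lapply(sub_clusters, function(sc) sc$members$go_id)))
    terms$cluster <- unname(slab[terms$go_id])
    subs[[lab]] <- list(clusters = sub_clusters, network = net,
                        terms = terms, not_passed = not_passed)
  }
  structure(list(sub = subs,
                 parameters = utils::modifyList(
                   p, list(max_size = max_size, cutoff = cutoff,
                           inflation = inflation, metric = metric))),
            class = "gomcl_sub_result")
}

#' @export
print.gomcl_sub_result <- function(x, ...) {
  for (lab in names(x$sub)) {
    s <- x$sub[[lab]]
    cat(lab, ":", length(s$clusters), "sub-groups (",
        sum(vapply(s$clusters, function(c) nrow(c$members), integer(1))),
        "terms passed,", nrow(s$not_passed), "not passed )\n")
    for (sc in s$clusters)
      cat(sprintf("  %-8s %3d terms, %4d genes\n", sc$label,
                  nrow(sc$members), length(sc$gene_union)))
  }
  invisible(x)
}
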