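# Reconstruction of the GO hierarchy restricted to one cluster's members:
# which members are ancestors of which, with edges implied by other
# members removed, and the remaining edges tagged direct (immediate
# parent) or transitive (the connecting path runs through non-members).

#' GO hierarchy among a cluster's members
#'
#' Computes ancestor reachability in the full ontology, restricts it to
#' pairs of cluster members, deletes every pair that has a member-internal
#' intermediate (transitive reduction over the members), and tags each
#' remaining edge `direct` when the parent is an immediate parent of the
#' child in the ontology, or `transitive` when the connection runs only
#' through terms outside the cluster. Members from several ontology
#' branches yield a forest; no artificial root is added.
#'
#' @param graph An `ontology_graph`.
#' @param cluster A `go_cluster`, or a character vector of accessions.
#' @param relations Relations to traverse; default `"is_a"` (add
#'   `"part_of"` to include part-of links).
#' @return A `cluster_hierarchy`: list with `nodes` (member accessions
#'   found in the ontology) and `edges` (data frame `parent`, `child`,
#'   `tag`).
#' @export
cluster_hierarchy <- function(graph, cluster, relations = "is_a") {
  members <- if (inherits(cluster, "go_cluster")) cluster$members$go_id
             else as.character(cluster)
  ok <- vapply(members, function(a) {
    !is.na(tryCatch(resolve_id(graph, a), error = function(e) NA_character_))
  }, logical(1))
  if (any(!ok))
    warning("member(s) absent from ontology, excluded from hierarchy: ",
            paste(members[!ok], collapse = ", "), call. = FALSE)
  members <- vapply(members[ok], function(a) resolve_id(graph, a),
                    character(1), USE.NAMES = FALSE)
  members <- sort(unique(members))

  anc <- lapply(members, function(a) term_ancestors(graph, a, relations))
  names(anc) <- members

  parent <- character(0); child <- character(0)
  for (c_acc in members) {
    ps <- intersect(anc[[c_acc]], members)
    for (p_acc in ps) {
      # implied if some other member sits between p and c
      mids <- setdiff(intersect(anc[[c_acc]], members), c(p_acc, c_acc))
      implied <- any(vapply(mids, function(m_acc)
        p_acc %in% anc[[m_acc]], logical(1)))
      if (!implied) { parent <- c(parent, p_acc); child <- c(child, c_acc) }
    }
  }
  direct_parents <- function(a) {
    t <- graph$terms[[a]]
    p <- character(0)
    if ("is_a" %in% relations) p <- c(p, t$parents_is_a)
    if ("part_of" %in% relations) p <- c(p, t$parents_part_of)
    unique(p)
  }
  tag <- character(length(parent))
  for (k in seq_along(parent))
    tag[k] <- if (parent[k] %in% direct_parents(child[k])) "direct"
              else "transitive"
  ord <- order(parent, child)
  structure(list(nodes = members,
                 edges = data.frame(parent = parent[ord], child = child[ord],
                                    tag = tag[ord],
                                    stringsAsFactors = FALSE)),
            class = "cluster_hierarchy")
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  cat("Cluster hierarchy:", length(x$nodes), "terms,",
      sum(x$edges$tag == "direct"), "direct +",
      sum(x$edges$tag == "transitive"), "transitive edges\n")
  invisible(x)
}

#' Write a cluster hierarchy as a TAB table
#'
#' Columns: `parent`, `child`, `tag`, `parent_depth`, `child_depth`.
#'
#' @param hier A `cluster_hierarchy`.
#' @param graph The `ontology_graph` (for depths).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy_table <- function(hier, graph, path) {
  depth <- term_depth_table(graph)
  df <- data.frame(parent = hier$edges$parent, child = hier$edges$child,
                   tag = hier$edges$tag,
                   parent_depth = unname(depth[hier$edges$parent]),
                   child_depth = unname(depth[hier$edges$child]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
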