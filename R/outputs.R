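# Serialization of clustering results: cluster/summary tables, Cytoscape
# SIF exports with node/edge attribute tables, and figures (heatmap,
# network, cohesion curves, hierarchy). Every figure writes a
# machine-readable companion table next to it; tests and downstream tools
# read the companions, never the pixels.

provenance_header <- function(params) {
  c(paste0("# gomclust v", params$tool_version),
    paste0("# metric=", params$metric, " cutoff=", params$cutoff,
           " inflation=", params$inflation, " max_size=", params$max_size),
    paste0("# namespaces=", paste(params$namespaces, collapse = ",")),
    paste0("# obo_data_version=", params$obo_data_version %||% NA))
}

write_tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

companion_path <- function(path, suffix = "") {
  paste0(tools::file_path_sans_ext(path), suffix, ".tsv")
}

#' Write the per-term cluster table
#'
#' One TAB-separated row per post-trim GO term: accession, description,
#' namespace, ontology depth, p-value, `x`, `n`, cluster label and any
#' representative tags, preceded by `#`-prefixed provenance lines. Rows
#' are ordered by cluster label, then p-value ascending.
#'
#' @param result A `gomcl_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(result, path) {
  terms <- result$terms
  rep_tags <- list()
  for (cl in result$clusters)
    for (k in seq_len(nrow(cl$representatives))) {
      acc <- cl$representatives$go_id[k]
      rep_tags[[acc]] <- c(rep_tags[[acc]], cl$representatives$tag[k])
    }
  df <- data.frame(
    go_id = terms$go_id, description = terms$description,
    namespace = terms$namespace, depth = terms$depth,
    p_value = format(terms$p_value, digits = 10), x = terms$x, n = terms$n,
    cluster = terms$cluster,
    representative = vapply(terms$go_id, function(a)
      paste(rep_tags[[a]] %||% character(0), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  ord <- label_sort_key(df$cluster)
  df <- df[ord, , drop = FALSE]
  df <- df[order(match(df$cluster, unique(df$cluster)),
                 as.numeric(df$p_value)), , drop = FALSE]
  write_tsv_with_header(df, path, provenance_header(result$parameters))
}

#' Write the cluster summary table
#'
#' One TAB-separated row per cluster: label, member count, size of the
#' gene union, and the representative terms with description, `x`, `n`
#' and p-value.
#'
#' @inheritParams write_cluster_table
#' @return `path`, invisibly.
#' @export
write_summary <- function(result, path) {
  rows <- lapply(result$clusters, function(cl) {
    rep_row <- function(tag) {
      r <- cl$representatives[cl$representatives$tag == tag, , drop = FALSE]
      i <- match(r$go_id[1], cl$members$go_id)
      sprintf("%s (%s; x=%d, n=%s, p=%s)", r$go_id[1],
              cl$members$description[i], cl$members$x[i],
              ifelse(is.na(cl$members$n[i]), "NA", cl$members$n[i]),
              format(cl$members$p_value[i], digits = 4))
    }
    data.frame(cluster = cl$label, n_terms = nrow(cl$members),
               n_genes = length(cl$gene_union),
               rep_most_genes = rep_row("most_genes"),
               rep_smallest_p = rep_row("smallest_p"),
               rep_highest_degree = rep_row("highest_degree"),
               stringsAsFactors = FALSE)
  })
  write_tsv_with_header(do.call(rbind, rows), path,
                        provenance_header(result$parameters))
}

#' Export a network or hierarchy in Cytoscape SIF format
#'
#' SIF lines are `source<TAB>interaction<TAB>target`. A similarity network
#' uses interaction `sim` and writes a companion edge-attribute table with
#' the weights; a hierarchy uses `isa_direct` / `isa_indirect`. Nodes
#' without any edge are emitted as single-column lines, the SIF convention
#' for isolated nodes.
#'
#' @param x A `similarity_network` or `cluster_hierarchy`.
#' @param path Output `.sif` path. The edge-attribute companion (for
#'   networks) is written next to it with suffix `_edge_attributes.tsv`.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path) {
  if (inherits(x, "similarity_network")) {
    lines <- character(0)
    if (nrow(x$edges))
      lines <- sprintf("%s\tsim\t%s", x$edges$from, x$edges$to)
    isolated <- setdiff(x$nodes, c(x$edges$from, x$edges$to))
    writeLines(c(lines, isolated), path)
    eda <- data.frame(term_A = x$edges$from, term_B = x$edges$to,
                      interaction = rep("sim", nrow(x$edges)),
                      weight = format(x$edges$weight, digits = 10),
                      stringsAsFactors = FALSE)
    utils::write.table(eda, companion_path(path, "_edge_attributes"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "cluster_hierarchy")) {
    inter <- ifelse(x$edges$tag == "direct", "isa_direct", "isa_indirect")
    lines <- character(0)
    if (nrow(x$edges))
      lines <- sprintf("%s\t%s\t%s", x$edges$parent, inter, x$edges$child)
    isolated <- setdiff(x$nodes, c(x$edges$parent, x$edges$child))
    writeLines(c(lines, isolated), path)
  } else stop("write_sif expects a similarity_network or cluster_hierarchy")
  invisible(path)
}

#' Write the node attribute table for Cytoscape import
#'
#' Columns: `node`, `cluster`, `description`, `namespace`, `depth`,
#' `p_value`, `x`, `n`.
#'
#' @inheritParams write_cluster_table
#' @return `path`, invisibly.
#' @export
write_node_table <- function(result, path) {
  t <- result$terms
  df <- data.frame(node = t$go_id, cluster = t$cluster,
                   description = t$description, namespace = t$namespace,
                   depth = t$depth, p_value = format(t$p_value, digits = 10),
                   x = t$x, n = t$n, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# -log10(p), capped so extreme p-values do not saturate the colormap
p_shade <- function(p, cap = 10) pmin(-log10(p), cap)

# heatmap term order: cluster label order, then within-cluster network
# degree descending, then accession
heatmap_order <- function(result) {
  t <- result$terms
  deg <- setNames(rep(0L, nrow(t)), t$go_id)
  if (nrow(result$network$edges)) {
    tab <- table(c(result$network$edges$from, result$network$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  key <- label_sort_key(t$cluster)
  t <- t[key, , drop = FALSE]
  unlist(lapply(unique(t$cluster), function(lab) {
    mem <- t$go_id[t$cluster == lab]
    mem[order(-deg[mem], mem)]
  }), use.names = FALSE)
}

#' Similarity heatmap of a clustering result
#'
#' All-pairs similarity matrix (cutoff ignored, so between-cluster cells
#' are visible) with terms ordered so cluster blocks are contiguous, and
#' cluster boundaries delineated. The exact cell values are written to a
#' companion matrix TSV.
#'
#' @param result A `gomcl_result`.
#' @param path Output figure path (`.pdf` or any device `ggplot2::ggsave`
#'   understands). Companion written with suffix `_matrix.tsv`.
#' @return `path`, invisibly.
#' @export
plot_heatmap <- function(result, path) {
  ord <- heatmap_order(result)
  S <- similarity_matrix(result$terms, result$parameters$metric)[ord, ord,
                                                                 drop = FALSE]
  mat_path <- companion_path(path, "_matrix")
  utils::write.table(
    data.frame(go_id = rownames(S), format(S, digits = 10),
               check.names = FALSE),
    mat_path, sep = "\t", quote = FALSE, row.names = FALSE)

  df <- expand.grid(row = seq_along(ord), col = seq_along(ord))
  df$sim <- as.vector(S)
  bounds <- cumsum(table(factor(result$terms$cluster,
                                levels = unique(result$terms$cluster[
                                  label_sort_key(result$terms$cluster)]))))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                         fill = .data$sim)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = result$parameters$metric) +
    ggplot2::scale_y_reverse() +
    ggplot2::geom_hline(yintercept = utils::head(bounds, -1) + 0.5,
                        colour = "white", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = utils::head(bounds, -1) + 0.5,
                        colour = "white", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Within/between-cluster gene-set similarity") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, gg, width = 7, height = 6)
  invisible(path)
}

#' Network figure of a clustering result
#'
#' Force-directed layout (fixed seed, so the figure is reproducible).
#' Node size grows with the test-set gene count `x`, node shade with
#' `-log10(p)` (darker = smaller p-value, capped at 10), node colour by
#' cluster, edge width by similarity weight. A companion node table
#' (`node`, `x`, `cluster`, `p_value`, `shade`, `size`, `color`) and edge
#' table are written next to the figure.
#'
#' @param result A `gomcl_result`.
#' @param path Output figure path; companions written with suffixes
#'   `_nodes.tsv` and `_edges.tsv`.
#' @param layout_seed Seed for the layout; default 42.
#' @return `path`, invisibly.
#' @export
plot_network <- function(result, path, layout_seed = 42) {
  t <- result$terms
  g <- igraph::graph_from_data_frame(
    result$network$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = t$go_id))
  lay <- with_local_seed(layout_seed, igraph::layout_with_fr(g))
  size <- 2 + 6 * sqrt(t$x / max(t$x))
  shade <- p_shade(t$p_value)
  clusters <- unique(t$cluster[label_sort_key(t$cluster)])
  palette <- grDevices::hcl.colors(max(3, length(clusters)), "Dark 3")
  color <- palette[match(t$cluster, clusters)]

  nodes <- data.frame(node = t$go_id, x = t$x, cluster = t$cluster,
                      p_value = format(t$p_value, digits = 10),
                      shade = format(shade, digits = 10),
                      size = format(size, digits = 10), color = color,
                      lay_x = format(lay[, 1], digits = 10),
                      lay_y = format(lay[, 2], digits = 10),
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, companion_path(path, "_nodes"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(from = result$network$edges$from,
               to = result$network$edges$to,
               weight = format(result$network$edges$weight, digits = 10)),
    companion_path(path, "_edges"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  grDevices::pdf(path, width = 8, height = 7)
  on.exit(grDevices::dev.off())
  alpha <- 0.35 + 0.65 * shade / max(shade, 1)
  igraph::plot.igraph(
    g, layout = lay, vertex.size = size,
    vertex.color = grDevices::adjustcolor(color, alpha.f = 1),
    vertex.frame.color = grDevices::grey(1 - alpha),
    vertex.label.cex = 0.4,
    edge.width = 0.5 + 2.5 * result$network$edges$weight)
  graphics::legend("topleft", legend = clusters, pch = 19,
                   col = palette[seq_along(clusters)], cex = 0.8, bty = "n")
  invisible(path)
}

#' Cumulative within-cluster similarity curves
#'
#' One empirical-CDF curve per (non-singleton) cluster, a vertical line at
#' the threshold, and a legend reporting each cluster's `p_above`. The
#' curve points are written to a companion table.
#'
#' @param cohesions List of `cluster_cohesion` (see [result_cohesion()]).
#' @param path Output figure path; companion suffix `_curves.tsv`.
#' @return `path`, invisibly.
#' @export
plot_cohesion <- function(cohesions, path) {
  keep <- Filter(function(c) length(c$pairwise_sims) > 0, cohesions)
  if (!length(keep)) stop("no cluster with >= 2 members to plot")
  thr <- keep[[1]]$threshold
  curves <- do.call(rbind, lapply(keep, function(c) {
    cc <- cumulative_curve(c)
    cc$cluster <- c$label
    cc$p_above <- c$p_above
    cc
  }))
  utils::write.table(
    data.frame(cluster = curves$cluster,
               similarity = format(curves$similarity, digits = 10),
               cum_fraction = format(curves$cum_fraction, digits = 10),
               p_above = format(curves$p_above, digits = 10)),
    companion_path(path, "_curves"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  lab <- vapply(keep, function(c)
    sprintf("%s  P(>=%.2f)=%.2f", c$label, thr, c$p_above), character(1))
  curves$legend <- lab[match(curves$cluster,
                             vapply(keep, `[[`, character(1), "label"))]
  gg <- ggplot2::ggplot(curves,
                        ggplot2::aes(x = .data$similarity,
                                     y = .data$cum_fraction,
                                     colour = .data$legend)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "similarity index", y = "cumulative fraction of pairs",
                  colour = NULL,
                  title = "Within-cluster similarity distributions") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, gg, width = 7, height = 5)
  invisible(path)
}

#' Hierarchy figure for one cluster
#'
#' Layered top-down layout by ontology depth; direct parent/child edges
#' are solid black, connections running through non-member intermediates
#' are grey. Node size and shade encode `x` and p-value as in
#' [plot_network()]. Companion tables carry the node and edge data.
#'
#' @param hier A `cluster_hierarchy`.
#' @param result The `gomcl_result` providing `x` and p-values.
#' @param graph The `ontology_graph` (for depths).
#' @param path Output figure path; companions `_nodes.tsv`, `_edges.tsv`.
#' @return `path`, invisibly.
#' @export
plot_hierarchy <- function(hier, result, graph, path) {
  depth <- term_depth_table(graph)
  t <- result$terms[match(hier$nodes, result$terms$go_id), , drop = FALSE]
  d <- unname(depth[hier$nodes])
  # spread nodes horizontally within each depth layer
  xpos <- numeric(length(hier$nodes))
  for (dd in unique(d)) {
    ix <- which(d == dd)
    xpos[ix] <- seq_along(ix) - (length(ix) + 1) / 2
  }
  nodes <- data.frame(node = hier$nodes, depth = d, x = t$x,
                      p_value = format(t$p_value, digits = 10),
                      stringsAsFactors = FALSE)
  utils::write.table(nodes, companion_path(path, "_nodes"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(hier$edges, companion_path(path, "_edges"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  grDevices::pdf(path, width = 8, height = 6)
  on.exit(grDevices::dev.off())
  graphics::plot(NULL, xlim = range(xpos) + c(-1, 1),
                 ylim = -range(d)[2:1] + c(-0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "",
                 main = "GO hierarchy within cluster")
  if (nrow(hier$edges)) {
    i <- match(hier$edges$parent, hier$nodes)
    j <- match(hier$edges$child, hier$nodes)
    graphics::segments(xpos[i], -d[i], xpos[j], -d[j],
                       col = ifelse(hier$edges$tag == "direct", "black",
                                    "grey60"),
                       lwd = ifelse(hier$edges$tag == "direct", 1.5, 1))
  }
  shade <- p_shade(t$p_value)
  alpha <- 0.25 + 0.75 * shade / max(shade, 1)
  graphics::points(xpos, -d, pch = 21,
                   bg = grDevices::grey(1 - alpha),
                   cex = 1 + 2 * sqrt(t$x / max(t$x)))
  graphics::text(xpos, -d - 0.18, labels = hier$nodes, cex = 0.45)
  invisible(path)
}
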