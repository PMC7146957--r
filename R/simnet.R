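# Gene-set similarity coefficients, term-list trimming, and construction of
# the thresholded similarity network over enriched GO terms.

#' Jaccard coefficient between two gene sets
#'
#' `|A intersect B| / |A union B|`. Preferred when the two terms annotate
#' similarly many genes.
#'
#' @param a,b Character vectors of gene identifiers (treated as sets).
#' @return A number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) stop("Jaccard undefined for two empty sets")
  length(intersect(a, b)) / length(union(a, b))
}

#' Overlap coefficient between two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`. Saturates at 1 when one set contains
#' the other, which makes it the better choice for reducing redundancy
#' between disproportionately sized terms.
#'
#' @inheritParams jaccard
#' @return A number in `[0, 1]`.
#' @export
overlap_coeff <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b))
    stop("overlap coefficient undefined for an empty set")
  length(intersect(a, b)) / min(length(a), length(b))
}

sim_fun <- function(metric) {
  switch(match.arg(metric, c("OC", "JC")), OC = overlap_coeff, JC = jaccard)
}

#' Remove overly broad GO terms from an enrichment list
#'
#' Drops every term whose reference annotation size `n` is strictly
#' greater than `max_size` (a term with `n == max_size` is kept), then
#' optionally restricts to selected namespaces. Very broad terms
#' (thousands of annotated genes) rarely describe a meaningful specific
#' function and would otherwise glue unrelated clusters together. Terms
#' with unknown `n` (dialects that do not report it) are kept.
#'
#' @param x An `enrichment_list`.
#' @param max_size Positive integer; largest annotation size retained.
#' @param graph Optional `ontology_graph`, required when `keep` is given.
#' @param keep Optional namespace subset passed to [filter_namespaces()].
#' @return A filtered `enrichment_list`.
#' @export
trim_terms <- function(x, max_size, graph = NULL, keep = NULL) {
  stopifnot(is.numeric(max_size), max_size >= 1)
  drop <- !is.na(x$n) & x$n > max_size
  if (any(drop))
    vlog("trimming ", sum(drop), " term(s) with n > ", max_size, ": ",
         paste(sprintf("%s (n=%d)", x$go_id[drop], x$n[drop]),
               collapse = ", "))
  out <- new_enrichment_list(as.data.frame(x[!drop, , drop = FALSE]),
                             attr(x, "source_dialect"),
                             attr(x, "source_path"))
  if (!is.null(keep)) {
    if (is.null(graph)) stop("namespace filtering requires an ontology graph")
    out <- filter_namespaces(out, graph, keep)
  }
  out
}

#' Build the gene-set-overlap similarity network
#'
#' Scores every unordered pair of terms with the chosen coefficient over
#' their test-set gene members and stores an edge when the weight reaches
#' the cutoff (inclusive: `weight >= cutoff`). Terms with no retained edge
#' remain as isolated nodes.
#'
#' @param x An `enrichment_list` (typically after [trim_terms()]).
#' @param metric `"OC"` (overlap coefficient, default) or `"JC"` (Jaccard).
#' @param cutoff Minimum similarity for an edge, in `[0, 1]`; default 0.5.
#' @return A `similarity_network`: list with `nodes` (accessions), `terms`
#'   (the backing `enrichment_list`), `edges` (data frame `from`, `to`,
#'   `weight`), `metric`, `cutoff`.
#' @export
build_network <- function(x, metric = c("OC", "JC"), cutoff = 0.5) {
  metric <- match.arg(metric)
  stopifnot(cutoff >= 0, cutoff <= 1)
  f <- sim_fun(metric)
  nodes <- x$go_id
  m <- length(nodes)
  from <- character(0); to <- character(0); w <- numeric(0)
  if (m >= 2) {
    for (i in seq_len(m - 1)) {
      gi <- x$genes[[i]]
      for (j in (i + 1):m) {
        s <- f(gi, x$genes[[j]])
        if (s > 0 && s >= cutoff) {
          from <- c(from, nodes[i]); to <- c(to, nodes[j]); w <- c(w, s)
        }
      }
    }
  }
  structure(list(nodes = nodes, terms = x,
                 edges = data.frame(from = from, to = to, weight = w,
                                    stringsAsFactors = FALSE),
                 metric = metric, cutoff = cutoff),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("GO similarity network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges [", x$metric, ">=", x$cutoff, "]\n")
  invisible(x)
}

# dense symmetric weight matrix of a similarity network
network_matrix <- function(net) {
  m <- length(net$nodes)
  W <- matrix(0, m, m, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    W[cbind(i, j)] <- net$edges$weight
    W[cbind(j, i)] <- net$edges$weight
  }
  W
}

# all-pairs similarity matrix of an enrichment list (no cutoff applied);
# used by the heatmap and the cohesion statistics
similarity_matrix <- function(x, metric = c("OC", "JC")) {
  f <- sim_fun(match.arg(metric))
  m <- nrow(x)
  S <- diag(1, m)
  dimnames(S) <- list(x$go_id, x$go_id)
  if (m >= 2)
    for (i in seq_len(m - 1))
      for (j in (i + 1):m)
        S[i, j] <- S[j, i] <- f(x$genes[[i]], x$genes[[j]])
  S
}

#' Write the network edge table
#'
#' TAB-separated columns `term_A`, `term_B`, `weight`, `metric`.
#'
#' @param net A `similarity_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(net, path) {
  df <- data.frame(term_A = net$edges$from, term_B = net$edges$to,
                   weight = format(net$edges$weight, digits = 10),
                   metric = net$metric, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
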