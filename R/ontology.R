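# OBO 1.2 flat-file ontology: parsing, validation, depth and ancestry queries.

GO_NAMESPACES <- c("biological_process", "molecular_function",
                   "cellular_component")

#' Parse an OBO 1.2 flat file into a GO ontology graph
#'
#' Reads the stanza-based OBO flat format used by the Gene Ontology
#' Consortium. Every `[Term]` stanza becomes a term record carrying its
#' accession, name, namespace, `is_a` parents, `relationship: part_of`
#' parents, alternate accessions and obsolete flag. Obsolete terms are kept
#' in the graph but flagged; they are rejected by [term_depth()] and
#' [term_ancestors()]. Typedef stanzas other than `part_of` relationships
#' are ignored.
#'
#' The parsed graph is validated: accessions must match `GO:` followed by
#' seven digits, the `is_a` relation over non-obsolete terms must be
#' acyclic (a cycle aborts with one offending cycle listed), and every
#' `alt_id` must map to a parsed term. An `is_a` edge crossing namespaces
#' raises a warning but is kept.
#'
#' @param path Path to an OBO 1.2 flat file.
#' @return An object of class `ontology_graph`: a list with elements
#'   `terms` (named list of term records), `alt_index` (named character
#'   vector, alternate accession -> canonical accession) and `data_version`
#'   (the header `data-version:` string, or `NA`).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "name: root",
#'   "namespace: biological_process", "",
#'   "[Term]", "id: GO:0000002", "name: child",
#'   "namespace: biological_process", "is_a: GO:0000001 ! root"), obo)
#' g <- read_obo(obo)
#' term_depth(g, "GO:0000002")
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  stanza_at <- grepl("^\\[", lines)
  header_end <- if (any(stanza_at)) which(stanza_at)[1] - 1L else length(lines)
  data_version <- NA_character_
  dv <- grep("^data-version:", lines[seq_len(header_end)], value = TRUE)
  if (length(dv)) data_version <- trimws(sub("^data-version:", "", dv[1]))

  starts <- which(stanza_at)
  if (!length(starts) || !any(lines[starts] == "[Term]"))
    stop("no [Term] stanza found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))

  terms <- list()
  alt_index <- character(0)
  for (k in seq_along(starts)) {
    if (lines[starts[k]] != "[Term]") next
    body <- lines[(starts[k] + 1L):ends[k]]
    body <- body[nzchar(trimws(body))]
    term <- parse_term_stanza(body, line_no = starts[k])
    if (term$id %in% names(terms))
      stop("duplicate term stanza for ", term$id, " near line ", starts[k])
    terms[[term$id]] <- term
    if (length(term$alt_ids))
      alt_index[term$alt_ids] <- term$id
  }

  graph <- structure(
    list(terms = terms, alt_index = alt_index, data_version = data_version),
    class = "ontology_graph")
  validate_ontology(graph)
  graph
}

parse_term_stanza <- function(body, line_no) {
  field <- function(key) {
    hit <- grepl(paste0("^", key, ":"), body)
    trimws(sub(paste0("^", key, ":"), "", body[hit]))
  }
  strip_comment <- function(x) trimws(sub("!.*$", "", x))

  id <- field("id")
  if (length(id) != 1L)
    stop("malformed [Term] stanza (missing or repeated id) near line ", line_no)
  if (!is_go_accession(id))
    stop("malformed GO accession '", id, "' near line ", line_no)

  name <- field("name")
  namespace <- field("namespace")
  obsolete <- any(tolower(strip_comment(field("is_obsolete"))) == "true")

  is_a <- strip_comment(field("is_a"))
  rels <- strip_comment(field("relationship"))
  part_of <- sub("^part_of\\s+", "", rels[grepl("^part_of\\s", rels)])
  alt_ids <- strip_comment(field("alt_id"))

  for (acc in c(is_a, part_of, alt_ids))
    if (!is_go_accession(acc))
      stop("malformed GO accession '", acc, "' near line ", line_no)
  if (obsolete && (length(is_a) || length(part_of)))
    stop("obsolete term ", id, " declares parents near line ", line_no)

  list(id = id,
       name = if (length(name)) name[1] else "",
       namespace = if (length(namespace)) namespace[1] else NA_character_,
       parents_is_a = unique(is_a),
       parents_part_of = unique(part_of),
       alt_ids = unique(alt_ids),
       obsolete = obsolete)
}

validate_ontology <- function(graph) {
  terms <- graph$terms
  bad_alt <- setdiff(graph$alt_index, names(terms))
  if (length(bad_alt))
    stop("alt_id maps to unknown term(s): ", paste(bad_alt, collapse = ", "))

  # cycle check on is_a restricted to non-obsolete terms (iterative DFS)
  active <- names(terms)[!vapply(terms, `[[`, TRUE, "obsolete")]
  color <- setNames(rep(0L, length(active)), active)  # 0 white 1 grey 2 black
  for (root in active) {
    if (color[root] != 0L) next
    stack <- list(list(node = root, i = 0L))
    path <- character(0)
    while (length(stack)) {
      top <- stack[[length(stack)]]
      node <- top$node
      if (top$i == 0L) { color[node] <- 1L; path <- c(path, node) }
      kids <- intersect(terms[[node]]$parents_is_a, active)
      if (top$i < length(kids)) {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- kids[top$i + 1L]
        if (color[nxt] == 1L) {
          cyc <- c(path[which(path == nxt):length(path)], nxt)
          stop("cyclic is_a relation: ", paste(cyc, collapse = " -> "))
        }
        if (color[nxt] == 0L)
          stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
      } else {
        color[node] <- 2L
        path <- path[-length(path)]
        stack[[length(stack)]] <- NULL
      }
    }
  }

  for (t in terms)
    if (!t$obsolete)
      for (p in t$parents_is_a)
        if (p %in% names(terms) && !identical(terms[[p]]$namespace, t$namespace))
          warning("is_a edge crosses namespaces: ", t$id, " -> ", p,
                  call. = FALSE)
  invisible(graph)
}

#' @export
print.ontology_graph <- function(x, ...) {
  obs <- sum(vapply(x$terms, `[[`, TRUE, "obsolete"))
  cat("GO ontology graph:", length(x$terms), "terms (", obs, "obsolete ),",
      length(x$alt_index), "alt ids; data-version:",
      x$data_version %||% NA, "\n")
  invisible(x)
}

#' Resolve a GO accession to its canonical form
#'
#' Alternate accessions (`alt_id` lines in the OBO file) are mapped to the
#' canonical term accession; canonical accessions are returned unchanged.
#'
#' @param graph An `ontology_graph` from [read_obo()].
#' @param acc A GO accession string.
#' @return The canonical accession.
#' @export
resolve_id <- function(graph, acc) {
  if (acc %in% names(graph$terms)) return(acc)
  if (acc %in% names(graph$alt_index)) return(unname(graph$alt_index[[acc]]))
  stop("unknown GO accession: ", acc)
}

# Depths of all non-obsolete terms: shortest is_a path from a namespace root
# (terms with no is_a parents have depth 0). Memoless dynamic program over a
# topological order of the DAG.
term_depth_table <- function(graph) {
  terms <- graph$terms
  active <- names(terms)[!vapply(terms, `[[`, TRUE, "obsolete")]
  parents <- lapply(terms[active], function(t) intersect(t$parents_is_a, active))
  depth <- setNames(rep(NA_integer_, length(active)), active)
  remaining <- active
  repeat {
    ready <- remaining[vapply(remaining, function(a) {
      p <- parents[[a]]
      !length(p) || !anyNA(depth[p])
    }, logical(1))]
    if (!length(ready)) break
    for (a in ready) {
      p <- parents[[a]]
      depth[a] <- if (!length(p)) 0L else 1L + min(depth[p])
    }
    remaining <- setdiff(remaining, ready)
  }
  depth
}

#' Depth of a GO term in its namespace
#'
#' Depth is the length of the shortest directed `is_a` path from the term's
#' namespace root down to the term; a namespace root has depth 0. `part_of`
#' edges are not traversed. Obsolete terms have no defined depth and raise
#' an error.
#'
#' @inheritParams resolve_id
#' @return A non-negative integer depth.
#' @export
term_depth <- function(graph, acc) {
  acc <- resolve_id(graph, acc)
  if (graph$terms[[acc]]$obsolete)
    stop("depth undefined for obsolete term ", acc)
  unname(term_depth_table(graph)[acc])
}

#' Ancestors of a GO term
#'
#' Transitive closure of the parent relation over the selected relation
#' types; the term itself is not included. Defaults to `is_a` only, the
#' relation used for depth; add `"part_of"` to traverse part-of edges too.
#'
#' @inheritParams resolve_id
#' @param relations Character subset of `c("is_a", "part_of")`.
#' @return Character vector of ancestor accessions (sorted).
#' @export
term_ancestors <- function(graph, acc, relations = "is_a") {
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  acc <- resolve_id(graph, acc)
  if (graph$terms[[acc]]$obsolete)
    stop("ancestors undefined for obsolete term ", acc)
  parents_of <- function(a) {
    t <- graph$terms[[a]]
    p <- character(0)
    if ("is_a" %in% relations) p <- c(p, t$parents_is_a)
    if ("part_of" %in% relations) p <- c(p, t$parents_part_of)
    intersect(unique(p), names(graph$terms))
  }
  seen <- character(0)
  frontier <- parents_of(acc)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(lapply(frontier, parents_of))), seen)
  }
  sort(seen)
}

#' Write an ontology graph back to OBO 1.2 text
#'
#' Serializes a parsed graph so that re-parsing yields an identical term
#' set, edge set and flags (round-trip stability).
#'
#' @inheritParams resolve_id
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  out <- c("format-version: 1.2")
  if (!is.na(graph$data_version))
    out <- c(out, paste0("data-version: ", graph$data_version))
  for (id in names(graph$terms)) {
    t <- graph$terms[[id]]
    out <- c(out, "", "[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    if (!is.na(t$namespace)) out <- c(out, paste0("namespace: ", t$namespace))
    for (a in t$alt_ids) out <- c(out, paste0("alt_id: ", a))
    for (p in t$parents_is_a) out <- c(out, paste0("is_a: ", p))
    for (p in t$parents_part_of)
      out <- c(out, paste0("relationship: part_of ", p))
    if (t$obsolete) out <- c(out, "is_obsolete: true")
  }
  writeLines(out, path)
  invisible(path)
}
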