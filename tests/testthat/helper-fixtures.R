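# Shared test builders and independent oracles.

# --- miniature OBO construction -------------------------------------------

# terms: list of lists with fields id, name, ns, is_a, part_of, alt, obsolete
obo_lines <- function(terms, data_version = "test/1") {
  out <- c("format-version: 1.2", paste0("data-version: ", data_version))
  for (t in terms) {
    out <- c(out, "", "[Term]", paste0("id: ", t$id),
             paste0("name: ", t$name %||% "unnamed"),
             paste0("namespace: ", t$ns %||% "biological_process"))
    for (a in t$alt %||% character(0)) out <- c(out, paste0("alt_id: ", a))
    for (p in t$is_a %||% character(0)) out <- c(out, paste0("is_a: ", p))
    for (p in t$part_of %||% character(0))
      out <- c(out, paste0("relationship: part_of ", p))
    if (isTRUE(t$obsolete)) out <- c(out, "is_obsolete: true")
  }
  out
}

write_obo_fixture <- function(terms, ...) {
  path <- tempfile(fileext = ".obo")
  writeLines(obo_lines(terms, ...), path)
  path
}

go_acc <- function(i) sprintf("GO:%07d", i)

# --- enrichment-list construction -----------------------------------------

# rows: list of lists with go_id, genes, p, n, ns, desc
make_enrichment <- function(rows) {
  df <- data.frame(
    go_id = vapply(rows, `[[`, character(1), "go_id"),
    description = vapply(rows, function(r) r$desc %||% "term", character(1)),
    namespace = vapply(rows, function(r) r$ns %||% "biological_process",
                       character(1)),
    p_value = vapply(rows, function(r) r$p %||% 0.01, numeric(1)),
    x = vapply(rows, function(r) length(unique(toupper(r$genes))),
               integer(1)),
    n = vapply(rows, function(r) as.integer(r$n %||% 100L), integer(1)),
    stringsAsFactors = FALSE)
  df$genes <- lapply(rows, function(r) sort(unique(toupper(r$genes))))
  structure(df, class = c("enrichment_list", "data.frame"),
            source_dialect = "generic", source_path = NA_character_)
}

write_generic_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  x <- make_enrichment(rows)
  gomclust::write_enrichment(x, path)
  path
}

# --- direct similarity-network construction (for MCL unit tests) ----------

# edges: data.frame(from, to, weight)
make_network <- function(nodes, edges = NULL, metric = "OC", cutoff = 0) {
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, terms = NULL, edges = edges,
                 metric = metric, cutoff = cutoff),
            class = "similarity_network")
}

# --- independent MCL oracle -----------------------------------------------
# Unoptimized dense iteration written without reusing any package code:
# explicit triple-loop matrix product, per-column inflation, and a separate
# attractor-reading routine.

oracle_mcl <- function(W, inflation, self_loop = 1, prune = 1e-5,
                       tol = 1e-6, max_iter = 100) {
  n <- nrow(W)
  M <- W
  for (i in seq_len(n)) M[i, i] <- M[i, i] + self_loop
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(n)) s <- s + M[i, j]
    for (i in seq_len(n)) M[i, j] <- M[i, j] / s
  }
  for (iter in seq_len(max_iter)) {
    P <- matrix(0, n, n)
    for (i in seq_len(n))
      for (j in seq_len(n)) {
        acc <- 0
        for (k in seq_len(n)) acc <- acc + M[i, k] * M[k, j]
        P[i, j] <- acc
      }
    for (j in seq_len(n)) {
      s <- 0
      for (i in seq_len(n)) {
        P[i, j] <- P[i, j]^inflation
        if (P[i, j] < prune) P[i, j] <- 0
        s <- s + P[i, j]
      }
      if (s > 0) for (i in seq_len(n)) P[i, j] <- P[i, j] / s
    }
    delta <- 0
    for (i in seq_len(n))
      for (j in seq_len(n))
        delta <- max(delta, abs(P[i, j] - M[i, j]))
    M <- P
    if (delta < tol) break
  }
  oracle_read_attractors(M, eps = 1e-9)
}

oracle_read_attractors <- function(M, eps = 1e-9, tie_tol = 1e-5) {
  n <- nrow(M)
  att <- which(diag(M) > eps)
  if (!length(att)) att <- seq_len(n)
  # merge attractor systems by repeated scanning until stable
  sys_id <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in att) for (j in att)
      if ((M[i, j] > eps || M[j, i] > eps) && sys_id[i] != sys_id[j]) {
        new <- min(sys_id[i], sys_id[j])
        old <- max(sys_id[i], sys_id[j])
        sys_id[sys_id == old] <- new
        changed <- TRUE
      }
    if (!changed) break
  }
  systems <- unique(sys_id[att])
  assign <- integer(n)
  for (v in seq_len(n)) {
    best_sys <- NA_integer_; best_score <- 0
    for (s in systems) {
      sc <- 0
      for (i in att[sys_id[att] == s]) sc <- max(sc, M[i, v])
      if (sc > best_score + tie_tol ||
          (abs(sc - best_score) <= tie_tol && !is.na(best_sys) &&
           s < best_sys && sc > eps)) {
        best_score <- sc; best_sys <- s
      }
    }
    assign[v] <- if (!is.na(best_sys) && best_score > eps) best_sys else 0L
  }
  for (v in which(assign == 0L)) {
    cur <- v
    for (hop in seq_len(n)) {
      cur <- which.max(M[, cur])
      if (assign[cur] != 0L) { assign[v] <- assign[cur]; break }
    }
    if (assign[v] == 0L) assign[v] <- systems[1]
  }
  unname(split(seq_len(n), assign))
}

# canonical form of a partition for comparison
canon_partition <- function(p) {
  p <- lapply(p, function(x) sort(as.character(x)))
  p[order(vapply(p, `[`, character(1), 1))]
}

# --- brute-force hierarchy oracle -----------------------------------------
# reachability by naive repeated expansion, then deletion of pairs with a
# member-internal intermediate

oracle_hierarchy <- function(graph, members, relations = "is_a") {
  reach <- function(a) {
    seen <- character(0)
    frontier <- a
    repeat {
      nxt <- character(0)
      for (f in frontier) {
        t <- graph$terms[[f]]
        p <- character(0)
        if ("is_a" %in% relations) p <- c(p, t$parents_is_a)
        if ("part_of" %in% relations) p <- c(p, t$parents_part_of)
        nxt <- c(nxt, setdiff(p, seen))
      }
      nxt <- intersect(unique(nxt), names(graph$terms))
      if (!length(nxt)) break
      seen <- union(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  anc <- lapply(members, reach)
  names(anc) <- members
  edges <- list()
  for (c_acc in members) for (p_acc in intersect(anc[[c_acc]], members)) {
    implied <- FALSE
    for (m_acc in setdiff(members, c(p_acc, c_acc)))
      if (m_acc %in% anc[[c_acc]] && p_acc %in% anc[[m_acc]]) {
        implied <- TRUE; break
      }
    if (!implied) edges[[length(edges) + 1]] <- c(p_acc, c_acc)
  }
  if (!length(edges))
    return(data.frame(parent = character(0), child = character(0)))
  df <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  names(df) <- c("parent", "child")
  df[order(df$parent, df$child), , drop = FALSE]
}

# read a TSV written with "#" provenance lines
read_out_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
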