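# Readers for GO enrichment result files in several tool dialects, and the
# normalized EnrichedTerm record they all map onto.

DIALECTS <- c("bingo", "gprofiler", "agrigo", "gorilla", "generic")

# per-dialect delimiter inside the gene-member column
GENE_DELIMS <- c(bingo = "|", gprofiler = ",", agrigo = ",", gorilla = ",",
                 generic = ",")

new_enrichment_list <- function(df, dialect, path) {
  stopifnot(is.data.frame(df))
  rownames(df) <- NULL
  structure(df, class = c("enrichment_list", "data.frame"),
            source_dialect = dialect, source_path = path)
}

#' @export
print.enrichment_list <- function(x, ...) {
  cat("Enrichment list:", nrow(x), "GO terms [dialect:",
      attr(x, "source_dialect"), "]\n")
  if (nrow(x)) {
    show <- utils::head(data.frame(
      go_id = x$go_id, p_value = signif(x$p_value, 3), x = x$x, n = x$n,
      description = substr(x$description, 1, 40)), 10)
    print(show, row.names = FALSE)
    if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  }
  invisible(x)
}

#' Detect the dialect of an enrichment result file
#'
#' Inspects header lines and returns the best-matching source tool:
#' `"bingo"` (BiNGO `.bgo`, `!`-prefixed preamble then a header starting
#' `GO-ID`), `"gprofiler"` (GEM export), `"agrigo"` (tabular export),
#' `"gorilla"` (tabular export) or `"generic"` (the documented
#' TAB-separated layout with columns `GO_ID`, `Description`, `P_value`,
#' `n`, `Genes`).
#'
#' @param path Path to an enrichment result file.
#' @return One of `c("bingo", "gprofiler", "agrigo", "gorilla", "generic")`.
#' @export
detect_dialect <- function(path) {
  head_lines <- readLines(path, n = 100L, warn = FALSE)
  if (!length(head_lines)) stop("empty enrichment file: ", path)
  for (ln in head_lines) {
    cols <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (!length(cols)) next
    if (cols[1] == "GO-ID" && any(grepl("corr p-value", cols)) &&
        any(grepl("Genes in test set", cols))) return("bingo")
    if (all(c("GO.ID", "Description", "p.Val", "FDR", "Genes") %in% cols))
      return("gprofiler")
    if (all(c("GO_acc", "term_type", "queryitem", "bgitem", "entries")
            %in% cols)) return("agrigo")
    if (any(grepl("^GO [Tt]erm$", cols)) &&
        any(grepl("FDR q-value", cols))) return("gorilla")
    if (all(c("GO_ID", "Description", "P_value", "n", "Genes") %in% cols))
      return("generic")
  }
  hdr <- strsplit(head_lines[nzchar(head_lines)][1], "\t", fixed = TRUE)[[1]]
  stop("unrecognized enrichment file layout in ", path,
       "\n  headers seen: ", paste(hdr, collapse = " | "),
       "\n  expected one of: BiNGO ('GO-ID' ... 'corr p-value' ...),",
       " g:Profiler GEM ('GO.ID', 'p.Val', 'FDR', 'Genes'),",
       " agriGO ('GO_acc', 'queryitem', 'bgitem', 'entries'),",
       " GOrilla ('GO term', 'FDR q-value'),",
       " generic ('GO_ID', 'Description', 'P_value', 'n', 'Genes')")
}

#' Read a GO enrichment result file
#'
#' Parses an enrichment file into the normalized record used throughout the
#' package: one row per GO term with accession (`go_id`), description,
#' namespace (when the file carries one; the ontology overrides it later),
#' `p_value` (the corrected/FDR value where the tool reports one), `x`
#' (test-set gene count, recomputed from the gene members), `n` (reference
#' annotation size; `NA` for dialects that do not report it) and `genes`
#' (list column of deduplicated, upper-cased gene identifiers).
#'
#' Bare numeric GO ids (as printed by BiNGO) are zero-padded to
#' `GO:NNNNNNN`. Duplicate accessions within one file are collapsed to the
#' row with the smallest p-value. Rows with an empty gene list are an
#' error: similarity between terms is computed from test-set members, so a
#' memberless row cannot participate.
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"` (default; see [detect_dialect()]),
#'   `"bingo"`, `"gprofiler"`, `"agrigo"`, `"gorilla"`, `"generic"`.
#' @return An `enrichment_list`: a data frame with columns `go_id`,
#'   `description`, `namespace`, `p_value`, `x`, `n` and list column
#'   `genes`, plus attributes `source_dialect` and `source_path`.
#' @export
read_enrichment <- function(path, dialect = "auto") {
  dialect <- match.arg(dialect, c("auto", DIALECTS))
  if (dialect == "auto") dialect <- detect_dialect(path)
  raw <- switch(dialect,
    bingo = read_bingo(path),
    gprofiler = read_gprofiler(path),
    agrigo = read_agrigo(path),
    gorilla = read_gorilla(path),
    generic = read_generic(path))
  if (!nrow(raw)) stop("no data rows in enrichment file: ", path)
  df <- normalize_enrichment(raw, GENE_DELIMS[[dialect]], path)
  new_enrichment_list(df, dialect, path)
}

normalize_enrichment <- function(raw, delim, path) {
  genes <- lapply(seq_len(nrow(raw)), function(i) {
    g <- strsplit(raw$genes_raw[i], delim, fixed = TRUE)[[1]]
    g <- toupper(trimws(g))
    sort(unique(g[nzchar(g)]))
  })
  for (i in seq_len(nrow(raw))) {
    row_no <- raw$row_no[i]
    if (!length(genes[[i]]))
      stop("row ", row_no, " of ", path, ": empty gene member list")
    p <- raw$p_value[i]
    if (is.na(p) || p <= 0 || p > 1)
      stop("row ", row_no, " of ", path, ": p-value '", p,
           "' not in (0, 1]")
    if (!is_go_accession(raw$go_id[i]))
      stop("row ", row_no, " of ", path, ": malformed GO id '",
           raw$go_id[i], "'")
  }
  df <- data.frame(go_id = raw$go_id, description = raw$description,
                   namespace = raw$namespace, p_value = raw$p_value,
                   x = lengths(genes), n = raw$n,
                   stringsAsFactors = FALSE)
  df$genes <- genes
  ok <- !is.na(df$n) & df$x > df$n
  if (any(ok))
    stop("row(s) ", paste(raw$row_no[ok], collapse = ", "), " of ", path,
         ": test-set count x exceeds annotation size n")
  # collapse duplicate accessions to the smallest p-value
  if (anyDuplicated(df$go_id)) {
    dup <- unique(df$go_id[duplicated(df$go_id)])
    vlog("collapsing ", length(dup), " duplicated GO id(s) in ", path,
         " (keeping smallest p-value): ", paste(dup, collapse = ", "))
    df <- df[order(df$p_value), , drop = FALSE]
    df <- df[!duplicated(df$go_id), , drop = FALSE]
  }
  df[order(match(df$go_id, raw$go_id)), , drop = FALSE]
}

pad_go_id <- function(x) {
  x <- trimws(x)
  bare <- grepl("^[0-9]+$", x)
  x[bare] <- sprintf("GO:%07d", as.integer(x[bare]))
  x
}

read_table_body <- function(path, header_pattern, skip_prefix = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!is.null(skip_prefix))
    lines <- lines[!startsWith(lines, skip_prefix)]
  hdr_at <- grep(header_pattern, lines)
  if (!length(hdr_at)) stop("header line not found in ", path)
  hdr_at <- hdr_at[1]
  header <- trimws(strsplit(lines[hdr_at], "\t", fixed = TRUE)[[1]])
  body_idx <- which(seq_along(lines) > hdr_at & nzchar(trimws(lines)))
  rows <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  list(header = header, rows = rows, row_no = body_idx)
}

col_of <- function(tab, name, path) {
  j <- which(tab$header == name)
  if (!length(j)) stop("column '", name, "' not found in ", path)
  vapply(tab$rows, function(r) if (length(r) >= j[1]) trimws(r[j[1]]) else "",
         character(1))
}

read_bingo <- function(path) {
  tab <- read_table_body(path, "^GO-ID\t", skip_prefix = "!")
  data.frame(go_id = pad_go_id(col_of(tab, "GO-ID", path)),
             description = col_of(tab, "Description", path),
             namespace = NA_character_,
             p_value = as.numeric(col_of(tab, "corr p-value", path)),
             n = as.integer(col_of(tab, "n", path)),
             genes_raw = col_of(tab, "Genes in test set", path),
             row_no = tab$row_no, stringsAsFactors = FALSE)
}

read_gprofiler <- function(path) {
  tab <- read_table_body(path, "^GO\\.ID\t")
  data.frame(go_id = pad_go_id(col_of(tab, "GO.ID", path)),
             description = col_of(tab, "Description", path),
             namespace = NA_character_,
             p_value = as.numeric(col_of(tab, "FDR", path)),
             n = NA_integer_,   # GEM exports carry no annotation size
             genes_raw = col_of(tab, "Genes", path),
             row_no = tab$row_no, stringsAsFactors = FALSE)
}

AGRIGO_NS <- c(P = "biological_process", F = "molecular_function",
               C = "cellular_component")

read_agrigo <- function(path) {
  tab <- read_table_body(path, "^GO_acc\t")
  ns <- AGRIGO_NS[col_of(tab, "term_type", path)]
  # agriGO separates genes with "//" in some exports and "," in others
  genes_raw <- gsub("//", ",", col_of(tab, "entries", path), fixed = TRUE)
  data.frame(go_id = pad_go_id(col_of(tab, "GO_acc", path)),
             description = col_of(tab, "Term", path),
             namespace = unname(ns),
             p_value = as.numeric(col_of(tab, "FDR", path)),
             n = as.integer(col_of(tab, "bgitem", path)),
             genes_raw = genes_raw,
             row_no = tab$row_no, stringsAsFactors = FALSE)
}

read_gorilla <- function(path) {
  tab <- read_table_body(path, "^GO [Tt]erm\t")
  go_col <- if ("GO term" %in% tab$header) "GO term" else "GO Term"
  # "[GENE - description], [GENE2 - ...]": strip brackets, keep the symbol
  genes_raw <- vapply(col_of(tab, "Genes", path), function(g) {
    parts <- strsplit(g, ",", fixed = TRUE)[[1]]
    parts <- gsub("\\[|\\]", "", trimws(parts))
    paste(vapply(strsplit(trimws(parts), "\\s+"),
                 function(p) p[1] %||% "", character(1)),
          collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  data.frame(go_id = pad_go_id(col_of(tab, go_col, path)),
             description = col_of(tab, "Description", path),
             namespace = NA_character_,
             p_value = as.numeric(col_of(tab, "FDR q-value", path)),
             n = as.integer(col_of(tab, "B", path)),
             genes_raw = genes_raw,
             row_no = tab$row_no, stringsAsFactors = FALSE)
}

read_generic <- function(path) {
  tab <- read_table_body(path, "^GO_ID\t", skip_prefix = "#")
  ns <- if ("Namespace" %in% tab$header) col_of(tab, "Namespace", path)
        else NA_character_
  n_col <- suppressWarnings(as.integer(col_of(tab, "n", path)))
  data.frame(go_id = pad_go_id(col_of(tab, "GO_ID", path)),
             description = col_of(tab, "Description", path),
             namespace = ns,
             p_value = as.numeric(col_of(tab, "P_value", path)),
             n = n_col,
             genes_raw = col_of(tab, "Genes", path),
             row_no = tab$row_no, stringsAsFactors = FALSE)
}

#' Write an enrichment list in the generic dialect
#'
#' The generic dialect is TAB-separated with a header row and columns
#' `GO_ID`, `Description`, `Namespace`, `P_value`, `x`, `n`, `Genes`
#' (comma-separated members). Re-reading the written file reproduces the
#' list exactly.
#'
#' @param x An `enrichment_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  df <- data.frame(GO_ID = x$go_id, Description = x$description,
                   Namespace = x$namespace, P_value = format(x$p_value),
                   x = x$x, n = x$n,
                   Genes = vapply(x$genes, paste, character(1),
                                  collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Restrict an enrichment list to selected GO namespaces
#'
#' The namespace of each term is taken from the ontology (after alt-id
#' resolution), overriding any namespace column in the input file. Terms
#' absent from the ontology are dropped with a warning.
#'
#' @param x An `enrichment_list`.
#' @param graph An `ontology_graph`.
#' @param keep Character subset of
#'   `c("biological_process", "molecular_function", "cellular_component")`.
#' @return A filtered `enrichment_list`.
#' @export
filter_namespaces <- function(x, graph, keep = GO_NAMESPACES) {
  keep <- match.arg(keep, GO_NAMESPACES, several.ok = TRUE)
  res <- resolve_enrichment_ids(x, graph)
  x <- res$list
  ns <- vapply(x$go_id, function(a) graph$terms[[a]]$namespace, character(1))
  x$namespace <- unname(ns)
  out <- x[x$namespace %in% keep, , drop = FALSE]
  new_enrichment_list(as.data.frame(out), attr(x, "source_dialect"),
                      attr(x, "source_path"))
}

# Resolve accessions against the ontology: map alt ids to canonical, drop
# (with a warning) terms that are unknown or obsolete. Returns the cleaned
# list plus the dropped accessions.
resolve_enrichment_ids <- function(x, graph) {
  canon <- vapply(x$go_id, function(a) {
    tryCatch(resolve_id(graph, a), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  unknown <- x$go_id[is.na(canon)]
  obs <- !is.na(canon) &
    vapply(canon, function(a) !is.na(a) && graph$terms[[a]]$obsolete,
           logical(1))
  dropped <- c(unknown, x$go_id[obs])
  if (length(dropped))
    warning(length(dropped), " enrichment term(s) absent from or obsolete",
            " in the ontology, dropped: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) " ..." else "", call. = FALSE)
  keep <- !is.na(canon) & !obs
  out <- x[keep, , drop = FALSE]
  out$go_id <- canon[keep]
  if (anyDuplicated(out$go_id)) {  # alt ids can collapse onto one canonical
    out <- out[order(out$p_value), , drop = FALSE]
    out <- out[!duplicated(out$go_id), , drop = FALSE]
  }
  list(list = new_enrichment_list(as.data.frame(out),
                                  attr(x, "source_dialect"),
                                  attr(x, "source_path")),
       dropped = dropped)
}
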