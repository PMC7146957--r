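# Synthetic fixture generator: miniature ontologies and enrichment tables
# with planted gene-sharing block structure, so every stage of the
# pipeline can be exercised (and its recovery scored against known truth)
# without any real enrichment-tool output.
#
# Design of the planted structure:
#   * each block owns a disjoint pool of gene identifiers (when
#     between_block_shared_fraction = 0); every term in a block carries the
#     block's shared core (within_block_shared_fraction of its genes) plus
#     term-private genes, so within-block overlap coefficients are at
#     least the shared fraction and between-block coefficients are 0.
#   * a two-level design (levels = 2) splits each block into two
#     sub-blocks with disjoint cores, and adds one broad "bridge" term per
#     block spanning all the block's genes. The bridge welds the
#     sub-blocks into one cluster in a default run; its reference
#     annotation size n is drawn large (bridge_n), so a tighter trim (the
#     usual sub-clustering move) removes it and the sub-blocks separate.
#   * the companion ontology mirrors the blocks: one namespace root, one
#     branch term per block, one sub-branch per sub-block, each enriched
#     term a leaf under its (sub-)branch; bridges hang under the block
#     branch.

#' Describe a planted-block fixture design
#'
#' @param n_blocks Number of planted blocks (clusters); default 2.
#' @param terms_per_block Enriched terms per block (per sub-block pair in
#'   two-level designs, excluding the bridge term); default 5.
#' @param genes_per_term Gene identifiers per term; default 20.
#' @param within_block_shared_fraction Fraction of each term's genes drawn
#'   from its block's shared core, in (0, 1]; default 0.8.
#' @param between_block_shared_fraction Fraction drawn from a pool shared
#'   across all blocks, in `[0, 1)`; default 0.
#' @param n_value_range Interval for the reference annotation size `n` of
#'   ordinary terms; default `c(200, 1500)`.
#' @param p_value_range Interval for enrichment p-values; default
#'   `c(1e-10, 0.05)`.
#' @param levels 1 (flat blocks) or 2 (sub-blocks + bridge terms);
#'   default 1.
#' @param bridge_n Annotation size assigned to bridge terms in two-level
#'   designs; default 3000 (kept by a 3500 trim, removed by 2000).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `planted_design` list.
#' @export
planted_design <- function(n_blocks = 2, terms_per_block = 5,
                           genes_per_term = 20,
                           within_block_shared_fraction = 0.8,
                           between_block_shared_fraction = 0,
                           n_value_range = c(200, 1500),
                           p_value_range = c(1e-10, 0.05),
                           levels = 1, bridge_n = 3000, seed = 1) {
  stopifnot(n_blocks >= 1, terms_per_block >= 1, genes_per_term >= 2,
            within_block_shared_fraction > 0,
            within_block_shared_fraction <= 1,
            between_block_shared_fraction >= 0,
            between_block_shared_fraction < 1,
            levels %in% c(1, 2))
  n_core <- round(within_block_shared_fraction * genes_per_term)
  n_between <- round(between_block_shared_fraction * genes_per_term)
  if (n_core < 1)
    stop("within_block_shared_fraction too small for genes_per_term ",
         genes_per_term, " (shared core would be empty)")
  if (n_core + n_between > genes_per_term)
    stop("shared fractions exceed genes_per_term resolution")
  structure(list(n_blocks = n_blocks, terms_per_block = terms_per_block,
                 genes_per_term = genes_per_term,
                 within = within_block_shared_fraction,
                 between = between_block_shared_fraction,
                 n_value_range = n_value_range,
                 p_value_range = p_value_range,
                 levels = levels, bridge_n = bridge_n, seed = seed,
                 n_core = n_core, n_between = n_between),
            class = "planted_design")
}

#' Generate a synthetic ontology + enrichment fixture
#'
#' Writes a miniature OBO ontology and a generic-dialect enrichment table
#' realizing the design's planted overlap structure, and returns the true
#' block (and sub-block) assignment per term. Byte-deterministic given the
#' design's seed.
#'
#' @param design A `planted_design`.
#' @param dir Directory to write into (created if needed).
#' @return List with `obo` and `enrichment` file paths and `truth`, a data
#'   frame with columns `go_id`, `block` (level-1 label), `sub_block`
#'   (level-2 label, or `"bridge"` for bridge terms; `NA` in one-level
#'   designs).
#' @export
generate_fixture <- function(design, dir = tempfile("fixture")) {
  stopifnot(inherits(design, "planted_design"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(design$seed, {
    n_sub <- if (design$levels == 2) 2L else 1L
    next_go <- 1L
    go <- function() {
      id <- sprintf("GO:%07d", next_go)
      next_go <<- next_go + 1L
      id
    }

    root <- go()
    obo_terms <- list(list(id = root, name = "synthetic process root",
                           namespace = "biological_process",
                           parent = character(0)))
    between_pool <- if (design$n_between > 0)
      sprintf("SHARED%03d", seq_len(design$n_between * 4)) else character(0)

    rows <- list(); truth <- list()
    for (b in seq_len(design$n_blocks)) {
      branch <- go()
      obo_terms[[length(obo_terms) + 1]] <-
        list(id = branch, name = sprintf("block %d process", b),
             namespace = "biological_process", parent = root)
      block_genes <- character(0)
      for (s in seq_len(n_sub)) {
        sub_parent <- if (n_sub == 1) branch else {
          sb <- go()
          obo_terms[[length(obo_terms) + 1]] <-
            list(id = sb, name = sprintf("block %d sub-process %d", b, s),
                 namespace = "biological_process", parent = branch)
          sb
        }
        core <- sprintf("B%dS%dCORE%03d", b, s, seq_len(design$n_core))
        for (k in seq_len(design$terms_per_block)) {
          id <- go()
          obo_terms[[length(obo_terms) + 1]] <-
            list(id = id, name = sprintf("block %d.%d term %d", b, s, k),
                 namespace = "biological_process", parent = sub_parent)
          n_private <- design$genes_per_term - design$n_core -
            design$n_between
          private <- if (n_private > 0)
            sprintf("B%dS%dT%dPRIV%03d", b, s, k, seq_len(n_private))
            else character(0)
          shared <- if (design$n_between > 0)
            sample(between_pool, design$n_between) else character(0)
          rows[[length(rows) + 1]] <- list(
            go_id = id,
            description = sprintf("block %d.%d term %d", b, s, k),
            p_value = stats::runif(1, design$p_value_range[1],
                                   design$p_value_range[2]),
            n = sample(design$n_value_range[1]:design$n_value_range[2], 1),
            genes = c(core, private, shared))
          truth[[length(truth) + 1]] <- data.frame(
            go_id = id, block = sprintf("B%d", b),
            sub_block = if (n_sub > 1) sprintf("B%d-%d", b, s)
                        else NA_character_,
            stringsAsFactors = FALSE)
          block_genes <- union(block_genes, c(core, private))
        }
      }
      if (n_sub > 1) {
        id <- go()
        obo_terms[[length(obo_terms) + 1]] <-
          list(id = id, name = sprintf("block %d broad process", b),
               namespace = "biological_process", parent = branch)
        rows[[length(rows) + 1]] <- list(
          go_id = id, description = sprintf("block %d broad process", b),
          p_value = stats::runif(1, design$p_value_range[1],
                                 design$p_value_range[2]),
          n = design$bridge_n, genes = block_genes)
        truth[[length(truth) + 1]] <- data.frame(
          go_id = id, block = sprintf("B%d", b), sub_block = "bridge",
          stringsAsFactors = FALSE)
      }
    }

    obo_path <- file.path(dir, "mini.obo")
    obo_lines <- c("format-version: 1.2",
                   paste0("data-version: synthetic/seed-", design$seed))
    for (t in obo_terms) {
      obo_lines <- c(obo_lines, "", "[Term]", paste0("id: ", t$id),
                     paste0("name: ", t$name),
                     paste0("namespace: ", t$namespace))
      for (p in t$parent) obo_lines <- c(obo_lines, paste0("is_a: ", p))
    }
    writeLines(obo_lines, obo_path)

    enr_path <- file.path(dir, "enrichment.tsv")
    df <- data.frame(
      GO_ID = vapply(rows, `[[`, character(1), "go_id"),
      Description = vapply(rows, `[[`, character(1), "description"),
      Namespace = "biological_process",
      P_value = format(vapply(rows, `[[`, numeric(1), "p_value"),
                       digits = 10),
      x = vapply(rows, function(r) length(unique(r$genes)), integer(1)),
      n = vapply(rows, function(r) as.integer(r$n), integer(1)),
      Genes = vapply(rows, function(r) paste(unique(r$genes),
                                             collapse = ","), character(1)),
      stringsAsFactors = FALSE)
    utils::write.table(df, enr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    list(obo = obo_path, enrichment = enr_path,
         truth = do.call(rbind, truth))
  })
}
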