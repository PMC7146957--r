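# Serialization and figure companions. Figure-level checks assert on the
# machine-readable companion tables, never on rendered pixels.

setup_result <- function(seed = 1, n_blocks = 2) {
  fx <- generate_fixture(planted_design(n_blocks = n_blocks, seed = seed))
  g <- read_obo(fx$obo)
  res <- run_gomcl(read_enrichment(fx$enrichment), g)
  list(fx = fx, graph = g, res = res)
}

test_that("the cluster table has one labeled row per post-trim term", {
  s <- setup_result()
  path <- tempfile(fileext = ".tsv")
  write_cluster_table(s$res, path)
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "#")))          # provenance header
  expect_true(any(grepl("obo_data_version", lines)))
  df <- read_out_tsv(path)
  expect_identical(nrow(df), nrow(s$res$terms))
  expect_true(all(df$cluster %in% c("C1", "C2")))
  expect_setequal(df$go_id, s$res$terms$go_id)
  # within each cluster rows are ordered by ascending p-value
  for (lab in unique(df$cluster))
    expect_false(is.unsorted(df$p_value[df$cluster == lab]))
})

test_that("the summary has one row per cluster in label order", {
  s <- setup_result()
  path <- tempfile(fileext = ".tsv")
  write_summary(s$res, path)
  df <- read_out_tsv(path)
  expect_identical(df$cluster, c("C1", "C2"))
  expect_identical(df$n_terms,
                   vapply(s$res$clusters, function(c) nrow(c$members),
                          integer(1)))
  expect_identical(df$n_genes,
                   vapply(s$res$clusters, function(c) length(c$gene_union),
                          integer(1)))
  expect_true(all(grepl("^GO:", df$rep_most_genes)))
})

test_that("SIF export covers edges and isolated nodes", {
  x <- make_enrichment(list(
    list(go_id = go_acc(1), genes = c("a", "b")),
    list(go_id = go_acc(2), genes = c("a", "b", "c")),
    list(go_id = go_acc(3), genes = "z")))
  net <- build_network(x, "OC", 0.5)
  path <- tempfile(fileext = ".sif")
  write_sif(net, path)
  lines <- readLines(path)
  expect_identical(lines[1], paste(go_acc(1), "sim", go_acc(2), sep = "\t"))
  expect_true(go_acc(3) %in% lines)   # isolated node as single-column line
  eda <- utils::read.delim(
    paste0(tools::file_path_sans_ext(path), "_edge_attributes.tsv"))
  expect_identical(nrow(eda), 1L)
  expect_equal(eda$weight, 1)

  g <- chain <- read_obo(write_obo_fixture(list(
    list(id = go_acc(1)),
    list(id = go_acc(2), is_a = go_acc(1)),
    list(id = go_acc(3), is_a = go_acc(2)))))
  h <- cluster_hierarchy(g, c(go_acc(1), go_acc(2)))
  hpath <- tempfile(fileext = ".sif")
  write_sif(h, hpath)
  expect_identical(readLines(hpath),
                   paste(go_acc(1), "isa_direct", go_acc(2), sep = "\t"))
  h2 <- cluster_hierarchy(g, c(go_acc(1), go_acc(3)))
  write_sif(h2, hpath)
  expect_identical(readLines(hpath),
                   paste(go_acc(1), "isa_indirect", go_acc(3), sep = "\t"))
})

test_that("heatmap companion equals the all-pairs similarity oracle", {
  s <- setup_result()
  path <- tempfile(fileext = ".pdf")
  plot_heatmap(s$res, path)
  mat_path <- paste0(tools::file_path_sans_ext(path), "_matrix.tsv")
  m <- utils::read.delim(mat_path, check.names = FALSE)
  ids <- m$go_id
  vals <- as.matrix(m[, -1])
  # brute-force all-pairs OC on the term list
  terms <- s$res$terms
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    gi <- terms$genes[[match(ids[i], terms$go_id)]]
    gj <- terms$genes[[match(ids[j], terms$go_id)]]
    expect_equal(unname(vals[i, j]), overlap_coeff(gi, gj),
                 tolerance = 1e-9)
  }
  # cluster blocks are contiguous along the axes
  labs <- terms$cluster[match(ids, terms$go_id)]
  expect_identical(labs, labs[order(match(labs, unique(labs)))])
})

test_that("network figure companions encode size, shade and colors", {
  s <- setup_result()
  path <- tempfile(fileext = ".pdf")
  plot_network(s$res, path, layout_seed = 42)
  nodes <- utils::read.delim(
    paste0(tools::file_path_sans_ext(path), "_nodes.tsv"))
  expect_identical(nrow(nodes), nrow(s$res$terms))
  # node size strictly increases with x
  ord <- order(nodes$x)
  expect_true(all(diff(nodes$size[ord])[diff(nodes$x[ord]) > 0] > 0))
  # equal p-values get equal shades
  agg <- tapply(nodes$shade, nodes$p_value, function(v) length(unique(v)))
  expect_true(all(agg == 1))
  # one color per cluster
  expect_identical(length(unique(nodes$color)),
                   length(unique(nodes$cluster)))
  # fixed seed -> identical layout on re-run
  path2 <- tempfile(fileext = ".pdf")
  plot_network(s$res, path2, layout_seed = 42)
  nodes2 <- utils::read.delim(
    paste0(tools::file_path_sans_ext(path2), "_nodes.tsv"))
  expect_identical(nodes$lay_x, nodes2$lay_x)
})

test_that("cohesion figure companion carries the CDF per cluster", {
  s <- setup_result()
  coh <- result_cohesion(s$res)
  path <- tempfile(fileext = ".pdf")
  plot_cohesion(coh, path)
  curves <- utils::read.delim(
    paste0(tools::file_path_sans_ext(path), "_curves.tsv"))
  for (lab in names(coh)) {
    want <- cumulative_curve(coh[[lab]])
    got <- curves[curves$cluster == lab, ]
    expect_equal(got$similarity, want$similarity)
    expect_equal(got$cum_fraction, want$cum_fraction)
  }
})

test_that("hierarchy figure companions mirror the hierarchy edges", {
  s <- setup_result()
  cl <- s$res$clusters[[1]]
  h <- cluster_hierarchy(s$graph, cl)
  path <- tempfile(fileext = ".pdf")
  plot_hierarchy(h, s$res, s$graph, path)
  edges <- utils::read.delim(
    paste0(tools::file_path_sans_ext(path), "_edges.tsv"))
  expect_identical(nrow(edges), nrow(h$edges))
  nodes <- utils::read.delim(
    paste0(tools::file_path_sans_ext(path), "_nodes.tsv"))
  expect_setequal(nodes$node, h$nodes)
  depth <- gomclust:::term_depth_table(s$graph)
  expect_identical(nodes$depth, unname(depth[nodes$node]))
})

test_that("text outputs are byte-identical across repeated writes", {
  s <- setup_result()
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_cluster_table(s$res, p1)
  write_cluster_table(s$res, p2)
  expect_identical(readLines(p1), readLines(p2))
  write_summary(s$res, p1); write_summary(s$res, p2)
  expect_identical(readLines(p1), readLines(p2))
})
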