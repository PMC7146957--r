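# Enrichment-file dialects: detection, parsing, normalization.

bingo_file <- function() {
  path <- tempfile(fileext = ".bgo")
  writeLines(c(
    "! BiNGO output", "! selected statistic: hypergeometric",
    paste("GO-ID", "p-value", "corr p-value", "x", "n", "X", "N",
          "Description", "Genes in test set", sep = "\t"),
    paste("8150", "1.0E-4", "2.0E-3", "10", "3000", "500", "20000",
          "biological_process",
          paste(sprintf("A%d", 1:10), collapse = "|"), sep = "\t"),
    paste("9987", "1.0E-5", "3.0E-4", "3", "1200", "500", "20000",
          "cellular process", "b1|b2|A1", sep = "\t")), path)
  path
}

gem_file <- function() {
  path <- tempfile(fileext = ".txt")
  writeLines(c(
    paste("GO.ID", "Description", "p.Val", "FDR", "Phenotype", "Genes",
          sep = "\t"),
    paste("GO:0008150", "biological process", "1e-4", "2e-3", "+",
          "g1, g2, g3", sep = "\t")), path)
  path
}

agrigo_file <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("GO_acc", "term_type", "Term", "queryitem", "querytotal",
          "bgitem", "bgtotal", "pvalue", "FDR", "entries", sep = "\t"),
    paste("GO:0009987", "P", "cellular process", "3", "100", "900",
          "25000", "1e-6", "1e-4", "AT1G01010//AT1G01020//AT1G01030",
          sep = "\t")), path)
  path
}

gorilla_file <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    paste("GO term", "Description", "P-value", "FDR q-value", "Enrichment",
          "N", "B", "n", "b", "Genes", sep = "\t"),
    paste("GO:0008150", "biological process", "1e-7", "5e-5", "2.1",
          "10000", "800", "300", "3",
          "[ABC1 - some kinase], [DEF2 - unknown], [GHI3 - factor]",
          sep = "\t")), path)
  path
}

generic_rows <- list(
  list(go_id = go_acc(10), genes = c("g1", "g2", "g3"), p = 0.01, n = 50),
  list(go_id = go_acc(11), genes = c("g2", "g3", "g4"), p = 0.002, n = 60))

test_that("dialects are detected from header signatures", {
  expect_identical(detect_dialect(bingo_file()), "bingo")
  expect_identical(detect_dialect(gem_file()), "gprofiler")
  expect_identical(detect_dialect(agrigo_file()), "agrigo")
  expect_identical(detect_dialect(gorilla_file()), "gorilla")
  expect_identical(detect_dialect(write_generic_file(generic_rows)),
                   "generic")
  junk <- tempfile()
  writeLines(c("foo,bar,baz", "1,2,3"), junk)
  expect_error(detect_dialect(junk), "unrecognized")
})

test_that("BiNGO rows map onto the normalized record", {
  x <- read_enrichment(bingo_file())
  expect_identical(attr(x, "source_dialect"), "bingo")
  r <- x[x$go_id == "GO:0008150", ]
  expect_identical(r$go_id, "GO:0008150")     # zero-padded from "8150"
  expect_equal(r$p_value, 2.0e-3)             # corrected column
  expect_identical(r$x, 10L)
  expect_identical(r$n, 3000L)
  expect_identical(r$genes[[1]], sprintf("A%d", c(1, 10, 2:9)))
  # mixed-case members are upper-cased so overlaps survive
  r2 <- x[x$go_id == "GO:0009987", ]
  expect_true(all(c("B1", "B2", "A1") %in% r2$genes[[1]]))
})

test_that("g:Profiler GEM, agriGO and GOrilla dialects parse", {
  g <- read_enrichment(gem_file())
  expect_identical(g$x, 3L)
  expect_true(is.na(g$n))
  expect_equal(g$p_value, 2e-3)

  a <- read_enrichment(agrigo_file())
  expect_identical(a$genes[[1]], c("AT1G01010", "AT1G01020", "AT1G01030"))
  expect_identical(a$n, 900L)
  expect_identical(a$namespace, "biological_process")

  o <- read_enrichment(gorilla_file())
  expect_identical(o$genes[[1]], c("ABC1", "DEF2", "GHI3"))
  expect_identical(o$n, 800L)
  expect_equal(o$p_value, 5e-5)
})

test_that("gene normalization dedupes, trims and upper-cases idempotently", {
  path <- write_generic_file(list(
    list(go_id = go_acc(1), genes = c("g1", "G1", " g2 "), p = 0.01,
         n = 10)))
  x <- read_enrichment(path)
  expect_identical(x$genes[[1]], c("G1", "G2"))
  expect_identical(x$x, 2L)
  # idempotence: re-write and re-read changes nothing
  out <- tempfile(fileext = ".tsv")
  write_enrichment(x, out)
  y <- read_enrichment(out)
  expect_identical(y$genes, x$genes)
  expect_identical(y$x, x$x)
})

test_that("generic round-trip reproduces the list exactly", {
  path <- write_generic_file(generic_rows)
  x <- read_enrichment(path)
  out <- tempfile(fileext = ".tsv")
  write_enrichment(x, out)
  y <- read_enrichment(out)
  for (col in c("go_id", "description", "namespace", "x", "n", "genes"))
    expect_identical(y[[col]], x[[col]])
  expect_equal(y$p_value, x$p_value)
})

test_that("malformed rows fail loudly with their location", {
  bad_p <- tempfile(fileext = ".tsv")
  writeLines(c("GO_ID\tDescription\tP_value\tn\tGenes",
               "GO:0000001\tterm\t1.5\t10\tg1"), bad_p)
  expect_error(read_enrichment(bad_p), "row 2.*not in \\(0, 1\\]")

  no_genes <- tempfile(fileext = ".tsv")
  writeLines(c("GO_ID\tDescription\tP_value\tn\tGenes",
               "GO:0000001\tterm\t0.01\t10\t"), no_genes)
  expect_error(read_enrichment(no_genes), "empty gene member list")

  empty <- tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(read_enrichment(empty), "empty")
})

test_that("duplicate accessions collapse to the smallest p-value", {
  path <- write_generic_file(list(
    list(go_id = go_acc(1), genes = c("g1"), p = 0.05, n = 10),
    list(go_id = go_acc(1), genes = c("g1", "g2"), p = 0.001, n = 10)))
  x <- suppressMessages(read_enrichment(path))
  expect_identical(nrow(x), 1L)
  expect_equal(x$p_value, 0.001)
  expect_identical(x$x, 2L)
})

test_that("namespace filtering takes namespaces from the ontology", {
  g <- read_obo(write_obo_fixture(list(
    list(id = go_acc(1), ns = "biological_process"),
    list(id = go_acc(2), ns = "biological_process", is_a = go_acc(1)),
    list(id = go_acc(3), ns = "biological_process", is_a = go_acc(1)),
    list(id = go_acc(4), ns = "molecular_function"),
    list(id = go_acc(5), ns = "molecular_function", is_a = go_acc(4)))))
  x <- make_enrichment(lapply(1:5, function(i)
    list(go_id = go_acc(i), genes = sprintf("g%d", i), n = 10)))
  bp <- filter_namespaces(x, g, "biological_process")
  expect_identical(nrow(bp), 3L)
  expect_true(all(bp$namespace == "biological_process"))
  all3 <- filter_namespaces(x, g, c("biological_process",
                                    "molecular_function",
                                    "cellular_component"))
  expect_identical(all3$go_id, x$go_id)
  cc <- filter_namespaces(x, g, "cellular_component")
  expect_identical(nrow(cc), 0L)
})
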