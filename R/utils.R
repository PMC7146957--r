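#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

is_go_accession <- function(x) grepl("^GO:[0-9]{7}$", x)

# "C10" sorts after "C2"; sub-labels "C1-2" after "C1-1".
label_sort_key <- function(labels) {
  parts <- strsplit(sub("^C", "", labels), "-", fixed = TRUE)
  major <- vapply(parts, function(p) as.integer(p[[1]]), integer(1))
  minor <- vapply(parts, function(p) if (length(p) > 1) as.integer(p[[2]]) else 0L,
                  integer(1))
  order(major, minor)
}

vlog <- function(..., verbose = getOption("gomclust.verbose", TRUE)) {
  if (isTRUE(verbose)) message(...)
}
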