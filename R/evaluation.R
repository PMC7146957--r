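# Cluster-quality evaluation: the distribution of pairwise similarity
# indexes within each cluster, and the fraction at or above a threshold.

#' Within-cluster similarity distribution
#'
#' Recomputes ALL pairwise similarities among a cluster's members — the
#' network cutoff is deliberately ignored, so member pairs with no or
#' small overlap contribute zeros — and reports the proportion of pairs at
#' or above the threshold (`p_above`, the "P(>= 0.5)" statistic at the
#' default threshold). A well-separated, cohesive cluster has most of its
#' mass at high similarities; a large `p_above` gap flags a cluster worth
#' sub-clustering.
#'
#' @param cluster A `go_cluster` (from a `gomcl_result`).
#' @param metric `"OC"` or `"JC"`; use the clustering run's metric.
#' @param threshold Boundary for `p_above`; pairs with similarity equal to
#'   the threshold count as above. Default 0.5.
#' @return A `cluster_cohesion`: list with `label`, `n_members`,
#'   `pairwise_sims` (sorted), `threshold`, `p_above` (`NA` for a
#'   singleton cluster, where cohesion is undefined).
#' @export
cohesion <- function(cluster, metric = c("OC", "JC"), threshold = 0.5) {
  metric <- match.arg(metric)
  stopifnot(threshold >= 0, threshold <= 1)
  mem <- cluster$members
  m <- nrow(mem)
  if (m < 2) {
    return(structure(list(label = cluster$label, n_members = m,
                          pairwise_sims = numeric(0), threshold = threshold,
                          p_above = NA_real_),
                     class = "cluster_cohesion"))
  }
  f <- sim_fun(metric)
  sims <- numeric(m * (m - 1) / 2)
  k <- 0L
  for (i in seq_len(m - 1))
    for (j in (i + 1):m) {
      k <- k + 1L
      sims[k] <- f(mem$genes[[i]], mem$genes[[j]])
    }
  structure(list(label = cluster$label, n_members = m,
                 pairwise_sims = sort(sims), threshold = threshold,
                 p_above = mean(sims >= threshold)),
            class = "cluster_cohesion")
}

#' @export
print.cluster_cohesion <- function(x, ...) {
  cat(sprintf("%s: %d members, %d pairs, P(>= %.2f) = %s\n", x$label,
              x$n_members, length(x$pairwise_sims), x$threshold,
              if (is.na(x$p_above)) "n/a (singleton)"
              else sprintf("%.3f", x$p_above)))
  invisible(x)
}

#' Cohesion of every cluster in a result
#'
#' @param result A `gomcl_result`.
#' @param metric Defaults to the run's metric.
#' @param threshold See [cohesion()].
#' @return Named list of `cluster_cohesion` objects (by label).
#' @export
result_cohesion <- function(result, metric = NULL, threshold = 0.5) {
  metric <- metric %||% result$parameters$metric
  out <- lapply(result$clusters, cohesion, metric = metric,
                threshold = threshold)
  names(out) <- vapply(result$clusters, `[[`, character(1), "label")
  out
}

#' Empirical cumulative distribution of within-cluster similarities
#'
#' @param coh A `cluster_cohesion` with at least one pair.
#' @return Data frame with columns `similarity` (sorted unique values) and
#'   `cum_fraction` (fraction of pairs with similarity <= that value).
#' @export
cumulative_curve <- function(coh) {
  sims <- coh$pairwise_sims
  if (!length(sims)) stop("no pairwise similarities (singleton cluster)")
  u <- sort(unique(sims))
  data.frame(similarity = u,
             cum_fraction = vapply(u, function(s) mean(sims <= s),
                                   numeric(1)))
}

#' Write the cohesion table
#'
#' TAB-separated: `cluster`, `n_members`, `n_pairs`, `p_above` at the
#' configured threshold.
#'
#' @param cohesions List of `cluster_cohesion` (see [result_cohesion()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohesion_table <- function(cohesions, path) {
  df <- data.frame(
    cluster = vapply(cohesions, `[[`, character(1), "label"),
    n_members = vapply(cohesions, `[[`, integer(1), "n_members"),
    n_pairs = vapply(cohesions, function(c) length(c$pairwise_sims),
                     integer(1)),
    p_above = vapply(cohesions, function(c)
      if (is.na(c$p_above)) "NA" else sprintf("%.6f", c$p_above),
      character(1)),
    stringsAsFactors = FALSE)
  thr <- cohesions[[1]]$threshold
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# within-cluster similarity; p_above = fraction of ",
                    "pairs with similarity >= ", thr), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
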