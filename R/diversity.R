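#' Per-sample alpha diversity
#'
#' Computes OTU richness (number of detected OTUs), the Shannon index
#' (natural log by default) and the Simpson index for every sample.
#' Diversity should be computed on rarefied counts so depths are
#' comparable.
#'
#' @param table an [otu_table] with positive sample totals
#' @param shannon_base logarithm base for Shannon (default `exp(1)`, nats)
#' @param simpson which Simpson variant to report: `"gini"` (default,
#'   Gini-Simpson `1 - sum(p^2)`), `"simpson"` (`sum(p^2)` itself) or
#'   `"inverse"` (`1 / sum(p^2)`)
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `simpson`
#' @export
alpha_diversity <- function(table, shannon_base = exp(1),
                            simpson = c("gini", "simpson", "inverse")) {
  stopifnot(inherits(table, "otu_table"))
  simpson <- match.arg(simpson)
  rel <- relative_abundance(table)
  shannon <- apply(rel, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log(p, base = shannon_base))
  })
  lambda <- rowSums(rel^2)
  simp <- switch(simpson, gini = 1 - lambda, simpson = lambda,
                 inverse = 1 / lambda)
  data.frame(sample_id = sample_ids(table),
             richness = as.integer(rowSums(table$counts >= 1L)),
             shannon = unname(shannon), simpson = unname(simp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two groups of diversity values. The exact null distribution is
#' used when both groups have at most 12 values and the pooled data carry no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is applied.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2
#' @return list with `statistic` (rank-sum W of the first group),
#'   `p_value`, and `exact` (logical: exact distribution used?)
#' @export
rank_sum_test <- function(values_a, values_b) {
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) {
    # all observations identical: no evidence of any shift
    return(list(statistic = length(values_a) * length(values_b) / 2,
                p_value = 1, exact = FALSE))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- length(values_a) <= 12L && length(values_b) <= 12L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = exact)
}

#' Pairwise diversity comparisons between groups
#'
#' Runs [rank_sum_test()] for each diversity index and each pair of groups.
#'
#' @param table an [otu_table]
#' @param grouping metadata column name (default `"population"`) or a named
#'   sample-to-group vector
#' @param ... passed to [alpha_diversity()]
#' @return list with `per_sample` (the [alpha_diversity()] table plus a
#'   `group` column) and `comparisons` (data.frame: `group_a`, `group_b`,
#'   `index`, `statistic`, `p_value`)
#' @export
compare_diversity <- function(table, grouping = "population", ...) {
  stopifnot(inherits(table, "otu_table"))
  grouping <- resolve_grouping(table, grouping)
  div <- alpha_diversity(table, ...)
  div$group <- unname(grouping[div$sample_id])
  groups <- sort(unique(div$group))
  if (length(groups) < 2L) stop("need at least 2 groups to compare")
  pairs <- utils::combn(groups, 2L)
  rows <- list()
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    for (index in c("richness", "shannon", "simpson")) {
      ht <- rank_sum_test(div[div$group == a, index],
                          div[div$group == b, index])
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = a, group_b = b, index = index,
        statistic = ht$statistic, p_value = ht$p_value,
        stringsAsFactors = FALSE)
    }
  }
  list(per_sample = div, comparisons = do.call(rbind, rows))
}
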