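#' Bray-Curtis dissimilarities among samples
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`, computed on counts.
#'
#' @param table an [otu_table] with positive sample totals
#' @return a `dist` object with attribute `metric = "bray_curtis"`
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (any(sample_totals(table) == 0))
    stop("Bray-Curtis undefined for all-zero samples")
  d <- vegan::vegdist(table$counts, method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Binary Jaccard dissimilarities
#'
#' `d(A, B) = 1 - |A intersect B| / |A union B|` on presence/absence of
#' OTUs, among samples (`margin = "samples"`, default) or among OTUs across
#' samples (`margin = "otus"`, as used for ordination of neutral-model
#' partitions).
#'
#' @param table an [otu_table]
#' @param margin `"samples"` or `"otus"`
#' @return a `dist` object with attribute `metric = "jaccard_binary"`
#' @export
jaccard_binary <- function(table, margin = c("samples", "otus")) {
  stopifnot(inherits(table, "otu_table"))
  margin <- match.arg(margin)
  pa <- (table$counts >= 1L) * 1
  if (margin == "otus") pa <- t(pa)
  if (any(rowSums(pa) == 0))
    stop("Jaccard undefined for rows with no presences")
  d <- vegan::vegdist(pa, method = "jaccard", binary = TRUE)
  attr(d, "metric") <- "jaccard_binary"
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: Gower double-centering of
#' `-0.5 * D^2`, symmetric eigendecomposition, and coordinates scaled by the
#' square roots of the positive eigenvalues. Negative eigenvalues (possible
#' for non-Euclidean dissimilarities such as Bray-Curtis) are reported
#' unmodified; proportions explained are taken over the positive ones. Axis
#' signs follow a fixed convention (the largest-magnitude loading of each
#' axis is positive) so results are reproducible across runs.
#'
#' @param dm a `dist` object or symmetric matrix of dissimilarities
#' @return an object of class `pcoa_result`: list with `coordinates`
#'   (items x positive axes, named `PCo1`, `PCo2`, ...), `eigenvalues`
#'   (all, descending) and `proportion_explained` (per positive axis)
#' @export
pcoa <- function(dm) {
  D <- as.matrix(dm)
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  A <- -0.5 * D^2
  G <- A - matrix(rowMeans(A), n, n) -
    matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = length(pos))
  # sign convention: largest |loading| per axis made positive
  for (k in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, k]))
    if (coords[i, k] < 0) coords[, k] <- -coords[, k]
  }
  dimnames(coords) <- list(labels, paste0("PCo", seq_along(pos)))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 proportion_explained = e$values[pos] / sum(e$values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("pcoa_result:", nrow(x$coordinates), "items,",
      ncol(x$coordinates), "positive axes\n")
  k <- min(3L, length(x$proportion_explained))
  cat("  proportion explained:",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

# shared permutation machinery -------------------------------------------

perm_pvalue <- function(stat_obs, stat_fun, grouping, n_permutations, seed,
                        exhaustive) {
  if (exhaustive) {
    perms <- enumerate_assignments(grouping)
    stats_all <- vapply(perms, stat_fun, numeric(1L))
    return(list(p = mean(stats_all >= stat_obs - 1e-12),
                n = length(perms)))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    if (stat_fun(sample(grouping)) >= stat_obs - 1e-12) hits <- hits + 1L
  }
  list(p = (hits + 1L) / (n_permutations + 1L), n = n_permutations)
}

# All distinct assignments of a label multiset to positions (identity
# included). Feasible only for small n; guarded by a hard cap.
enumerate_assignments <- function(grouping, cap = 200000L) {
  labs <- sort(unique(grouping))
  counts <- table(factor(grouping, levels = labs))
  n_assign <- factorial(length(grouping)) / prod(factorial(counts))
  if (n_assign > cap)
    stop("too many distinct assignments for exhaustive enumeration: ",
         format(n_assign))
  rec <- function(remaining) {
    if (sum(remaining) == 0L) return(list(character(0)))
    out <- list()
    for (l in names(remaining)[remaining > 0L]) {
      rem <- remaining
      rem[l] <- rem[l] - 1L
      for (tail in rec(rem)) out[[length(out) + 1L]] <- c(l, tail)
    }
    out
  }
  rec(stats::setNames(as.integer(counts), labs))
}

check_groups <- function(dm, grouping) {
  D <- as.matrix(dm)
  if (length(grouping) != nrow(D))
    stop("grouping length must match the number of samples")
  if (!is.null(names(grouping)) && !is.null(rownames(D)))
    grouping <- grouping[rownames(D)]
  grouping <- as.character(grouping)
  sizes <- table(grouping)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("every group needs at least 2 samples")
  list(D = D, grouping = grouping)
}

#' One-way PERMANOVA (Adonis) on a distance matrix
#'
#' Distance-based multivariate analysis of variance in Anderson's
#' formulation: with `n` samples in `g` groups,
#' `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_groups sum_{i<j in group} d_ij^2 / n_g`,
#' `F = (SS_between / (g - 1)) / (SS_within / (n - g))`,
#' `R^2 = SS_between / SS_total`. Significance by permutation of group
#' labels with `p = (b + 1) / (B + 1)`, never zero; with
#' `exhaustive = TRUE` all distinct label assignments are enumerated
#' instead and `p` is the exact tail fraction (identity included).
#'
#' @param dm a `dist` or symmetric dissimilarity matrix
#' @param grouping group labels per sample (named vectors are matched to
#'   the distance labels)
#' @param n_permutations number of random permutations (default 999)
#' @param seed integer seed for the permutations
#' @param exhaustive enumerate all distinct assignments instead of sampling
#' @return an object of class `permutation_test`: list with `method`,
#'   `statistic` (pseudo-F), `effect` (R^2), `n_permutations`, `p_value`,
#'   `seed`
#' @export
permanova <- function(dm, grouping, n_permutations = 999, seed = NULL,
                      exhaustive = FALSE) {
  cg <- check_groups(dm, grouping)
  D2 <- cg$D^2
  n <- nrow(D2)
  lower <- lower.tri(D2)
  ss_total <- sum(D2[lower]) / n
  f_stat <- function(g) {
    ss_within <- 0
    for (lab in unique(g)) {
      idx <- which(g == lab)
      ss_within <- ss_within +
        sum(D2[idx, idx][lower.tri(D2[idx, idx])]) / length(idx)
    }
    ss_between <- ss_total - ss_within
    k <- length(unique(g))
    (ss_between / (k - 1)) / (ss_within / (n - k))
  }
  f_obs <- f_stat(cg$grouping)
  if (!is.finite(f_obs))
    warning("degenerate distances: pseudo-F is not finite")
  else if (stats::var(D2[lower]) == 0)
    warning("degenerate distances: all pairwise distances are equal, ",
            "pseudo-F carries no information")
  pv <- perm_pvalue(f_obs, f_stat, cg$grouping, n_permutations, seed,
                    exhaustive)
  # recompute R^2 for reporting
  ss_within <- 0
  for (lab in unique(cg$grouping)) {
    idx <- which(cg$grouping == lab)
    ss_within <- ss_within +
      sum(D2[idx, idx][lower.tri(D2[idx, idx])]) / length(idx)
  }
  structure(list(method = "permanova", statistic = f_obs,
                 effect = (ss_total - ss_within) / ss_total,
                 n_permutations = pv$n, p_value = pv$p, seed = seed,
                 exhaustive = exhaustive),
            class = "permutation_test")
}

#' ANOSIM on a distance matrix
#'
#' Rank-based comparison of between- versus within-group dissimilarities:
#' with `M = n(n-1)/2` pairwise distances ranked with mid-ranks for ties,
#' `r = (mean rank between - mean rank within) / (M / 2)`, in `[-1, 1]`.
#' Permutation p-value as in [permanova()].
#'
#' @inheritParams permanova
#' @return a `permutation_test` with `method = "anosim"`, `statistic = r`
#'   and `effect = NA`
#' @export
anosim <- function(dm, grouping, n_permutations = 999, seed = NULL,
                   exhaustive = FALSE) {
  cg <- check_groups(dm, grouping)
  n <- nrow(cg$D)
  lower <- which(lower.tri(cg$D))
  ranks <- rank(cg$D[lower])   # mid-ranks for ties
  M <- length(ranks)
  pair_rows <- row(cg$D)[lower]
  pair_cols <- col(cg$D)[lower]
  r_stat <- function(g) {
    within <- g[pair_rows] == g[pair_cols]
    (mean(ranks[!within]) - mean(ranks[within])) / (M / 2)
  }
  r_obs <- r_stat(cg$grouping)
  pv <- perm_pvalue(r_obs, r_stat, cg$grouping, n_permutations, seed,
                    exhaustive)
  structure(list(method = "anosim", statistic = r_obs, effect = NA_real_,
                 n_permutations = pv$n, p_value = pv$p, seed = seed,
                 exhaustive = exhaustive),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4), sep = "")
  if (!is.na(x$effect))
    cat(", R2 =", format(x$effect, digits = 4))
  cat(", p =", format(x$p_value, digits = 4),
      "(", x$n_permutations,
      if (isTRUE(x$exhaustive)) "exhaustive assignments" else "permutations",
      ")\n")
  invisible(x)
}

#' Ordination of above/below neutral-model partitions
#'
#' Reproduces the partition-structure view of the analysis: OTUs classified
#' above or below the neutral band (consistently across populations) are
#' embedded by principal coordinates of binary Jaccard distances computed on
#' their presence/absence patterns across samples. An OTU above in at least
#' one population and below in none is labelled `above`; symmetrically for
#' `below`; OTUs with conflicting labels across populations are dropped
#' with a message.
#'
#' @param fits named list of `neutral_fit` objects (one per population), or
#'   a single `neutral_fit`
#' @param table the [otu_table] the fits were computed from (used for the
#'   presence/absence patterns)
#' @return list with `ordination` (a [pcoa()] result over OTUs) and
#'   `labels` (data.frame `otu_id`, `partition`)
#' @export
partition_ordination <- function(fits, table) {
  stopifnot(inherits(table, "otu_table"))
  if (inherits(fits, "neutral_fit")) fits <- list(fits)
  above <- unique(unlist(lapply(fits, function(f)
    f$per_otu$otu_id[f$per_otu$partition == "above"])))
  below <- unique(unlist(lapply(fits, function(f)
    f$per_otu$otu_id[f$per_otu$partition == "below"])))
  conflict <- intersect(above, below)
  if (length(conflict)) {
    message(length(conflict),
            " OTU(s) above in one population and below in another; dropped")
    above <- setdiff(above, conflict)
    below <- setdiff(below, conflict)
  }
  above <- intersect(above, otu_ids(table))
  below <- intersect(below, otu_ids(table))
  classes <- c(length(above) > 0, length(below) > 0)
  if (sum(classes) < 2L)
    stop("need OTUs in both the above- and below-partition to ordinate")
  if (length(above) < 3L || length(below) < 3L)
    warning("a partition has fewer than 3 OTUs; ordination may be trivial")
  ids <- c(above, below)
  labels <- data.frame(otu_id = ids,
                       partition = rep(c("above", "below"),
                                       c(length(above), length(below))),
                       stringsAsFactors = FALSE)
  d <- jaccard_binary(table[, ids], margin = "otus")
  list(ordination = pcoa(d), labels = labels)
}

#' Write a distance matrix as a labelled square TSV
#'
#' @param dm a `dist` or square matrix
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_distance_matrix <- function(dm, path) {
  D <- as.matrix(dm)
  df <- data.frame(sample_id = rownames(D), D, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
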