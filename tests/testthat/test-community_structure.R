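brute_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)
brute_jaccard <- function(x, y) {
  a <- x >= 1; b <- y >= 1
  1 - sum(a & b) / sum(a | b)
}

test_that("distance metrics match brute force and metric axioms", {
  counts <- matrix(c(5L, 5L, 0L, 0L, 0L, 0L, 3L, 7L), 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), paste0("o", 1:4)))
  counts <- rbind(counts, s3 = counts["s1", ])
  tab <- otu_table(counts)
  bc <- as.matrix(bray_curtis(tab))
  expect_equal(bc["s1", "s3"], 0)          # identical samples
  expect_equal(bc["s1", "s2"], 1)          # disjoint supports
  jc <- as.matrix(jaccard_binary(tab))
  expect_equal(jc["s1", "s3"], 0)
  expect_equal(jc["s1", "s2"], 1)

  for (seed in 1:3) {
    rt <- random_otu_table(n_samples = 6, n_otus = 20, seed = seed,
                           max_count = 8)
    bc <- as.matrix(bray_curtis(rt))
    jc <- as.matrix(jaccard_binary(rt))
    expect_true(isSymmetric(bc))
    expect_true(all(diag(bc) == 0))
    for (k in 1:5) {
      ij <- sample(n_samples(rt), 2)
      expect_equal(bc[ij[1], ij[2]],
                   brute_bray(rt$counts[ij[1], ], rt$counts[ij[2], ]))
      expect_equal(jc[ij[1], ij[2]],
                   brute_jaccard(rt$counts[ij[1], ], rt$counts[ij[2], ]))
    }
  }
})

test_that("PCoA embeds Euclidean configurations exactly", {
  set.seed(17)
  pts <- matrix(rnorm(30), 10, 3,
                dimnames = list(paste0("s", 1:10), NULL))
  d <- dist(pts)
  ord <- pcoa(d)
  rec <- dist(ord$coordinates)
  expect_lt(max(abs(as.matrix(rec) - as.matrix(d))), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  expect_equal(sum(ord$proportion_explained), 1)

  # points on a line: one informative axis
  line <- matrix(c(0, 1, 2, 5), dimnames = list(paste0("s", 1:4), NULL))
  ordl <- pcoa(dist(line))
  expect_lt(max(abs(ordl$eigenvalues[-1])), 1e-9)
  axis1 <- ordl$coordinates[, 1]
  expect_equal(abs(cor(axis1, line[, 1])), 1)

  # duplicate samples land on coincident points
  dup <- rbind(pts, s11 = pts["s1", ])
  ordd <- pcoa(dist(dup))
  expect_lt(max(abs(ordd$coordinates["s1", ] - ordd$coordinates["s11", ])),
            1e-8)

  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(pcoa(asym), "symmetric")
})

test_that("PCoA agrees with classical multidimensional scaling", {
  rt <- random_otu_table(n_samples = 7, n_otus = 25, seed = 5)
  d <- bray_curtis(rt)
  ord <- pcoa(d)
  cmd <- cmdscale(d, k = 2, eig = TRUE)
  expect_equal(abs(ord$coordinates[, 1]), abs(cmd$points[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(ord$eigenvalues[1:2], cmd$eig[1:2], tolerance = 1e-8)
})

test_that("PERMANOVA matches exhaustive enumeration and vegan", {
  set.seed(23)
  pts <- rbind(matrix(rnorm(9, 0), 3), matrix(rnorm(9, 1.2), 3))
  rownames(pts) <- paste0("s", 1:6)
  d <- dist(pts)
  grouping <- rep(c("A", "B"), each = 3)

  # test-side oracle: all 20 distinct assignments, F from first principles
  D2 <- as.matrix(d)^2
  f_oracle <- function(g) {
    n <- 6
    sst <- sum(D2[lower.tri(D2)]) / n
    ssw <- 0
    for (lab in unique(g)) {
      idx <- which(g == lab)
      ssw <- ssw + sum(D2[idx, idx][lower.tri(D2[idx, idx])]) / length(idx)
    }
    ((sst - ssw) / 1) / (ssw / 4)
  }
  combos <- combn(6, 3)
  fs <- apply(combos, 2, function(idx) {
    g <- rep("B", 6); g[idx] <- "A"
    f_oracle(g)
  })
  f_obs <- f_oracle(grouping)
  p_oracle <- mean(fs >= f_obs - 1e-12)

  res <- permanova(d, grouping, exhaustive = TRUE)
  expect_equal(res$statistic, f_obs)
  expect_equal(res$p_value, p_oracle)
  expect_identical(res$n_permutations, 20L)

  # vegan cross-check of the statistic and R^2
  veg <- vegan::adonis2(d ~ g, data = data.frame(g = grouping),
                        permutations = 99)
  expect_equal(res$statistic, veg$F[1], tolerance = 1e-10)
  expect_equal(res$effect, veg$R2[1], tolerance = 1e-10)
})

test_that("ANOSIM matches exhaustive enumeration and vegan", {
  set.seed(29)
  pts <- rbind(matrix(rnorm(8, 0, 0.5), 4), matrix(rnorm(8, 2, 0.5), 4))
  rownames(pts) <- paste0("s", 1:8)
  d <- dist(pts)
  grouping <- rep(c("A", "B"), each = 4)

  ranks <- rank(as.vector(d))
  M <- length(ranks)
  pairs <- which(lower.tri(matrix(0, 8, 8)), arr.ind = TRUE)
  r_oracle <- function(g) {
    within <- g[pairs[, 1]] == g[pairs[, 2]]
    (mean(ranks[!within]) - mean(ranks[within])) / (M / 2)
  }
  res <- anosim(d, grouping, exhaustive = TRUE)
  expect_equal(res$statistic, r_oracle(grouping))
  combos <- combn(8, 4)
  rs <- apply(combos, 2, function(idx) {
    g <- rep("B", 8); g[idx] <- "A"
    r_oracle(g)
  })
  expect_equal(res$p_value, mean(rs >= res$statistic - 1e-12))

  veg <- suppressWarnings(vegan::anosim(d, grouping, permutations = 99))
  expect_equal(res$statistic, unname(veg$statistic), tolerance = 1e-10)

  # definitional maximum: all between-distances exceed all within
  far <- rbind(matrix(0.01 * rnorm(8), 4), matrix(0.01 * rnorm(8) + 50, 4))
  rownames(far) <- paste0("s", 1:8)
  resf <- anosim(dist(far), grouping, n_permutations = 99, seed = 1)
  expect_equal(resf$statistic, 1)
})

test_that("well-separated clusters reach the minimal attainable p", {
  set.seed(31)
  pts <- rbind(matrix(rnorm(24, 0, 0.1), 8), matrix(rnorm(24, 10, 0.1), 8))
  rownames(pts) <- paste0("s", 1:16)
  grouping <- rep(c("A", "B"), each = 8)
  res <- permanova(dist(pts), grouping, n_permutations = 999, seed = 7)
  expect_equal(res$p_value, 1 / 1000)
  expect_gt(res$effect, 0.9)
})

test_that("degenerate and undersized groupings are handled", {
  D <- matrix(1, 4, 4) - diag(4)
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_warning(permanova(as.dist(D), c("A", "A", "B", "B"),
                           n_permutations = 19, seed = 1),
                 "degenerate|finite")
  expect_error(permanova(as.dist(D), c("A", "A", "A", "B")), "at least 2")
  expect_error(permanova(as.dist(D), c("A", "A", "A", "A")), "2 groups")
})

test_that("permutation p-values hold their size under the null", {
  set.seed(41)
  n <- 12
  grouping <- rep(c("A", "B"), each = n / 2)
  pvals <- replicate(400, {
    d <- dist(matrix(rnorm(n * 3), n))
    permanova(d, grouping, n_permutations = 99)$p_value
  })
  expect_gt(mean(pvals <= 0.05), 0.02)
  expect_lt(mean(pvals <= 0.05), 0.09)
})

test_that("partition ordination separates disjoint presence classes", {
  counts <- matrix(0L, 6, 8,
                   dimnames = list(paste0("s", 1:6), paste0("o", 1:8)))
  counts[1:3, 1:4] <- 5L   # "above" OTUs live in samples 1-3
  counts[4:6, 5:8] <- 5L   # "below" OTUs live in samples 4-6
  tab <- otu_table(counts)
  po <- data.frame(otu_id = paste0("o", 1:8), p = 0.01,
                   freq_obs = c(rep(0.9, 4), rep(0.1, 4)),
                   freq_pred = 0.5, ci_lower = 0.3, ci_upper = 0.7,
                   partition = c(rep("above", 4), rep("below", 4)),
                   stringsAsFactors = FALSE)
  fit <- manual_fit(po, n_hosts = 6)
  res <- partition_ordination(list(P1 = fit), tab)
  expect_identical(sort(unique(res$labels$partition)), c("above", "below"))
  # disjoint classes: between-class Jaccard distance is 1, classes split
  # along the first axis
  ax1 <- res$ordination$coordinates[, 1]
  above <- res$labels$otu_id[res$labels$partition == "above"]
  expect_true(max(ax1[above]) < min(ax1[setdiff(names(ax1), above)]) ||
                min(ax1[above]) > max(ax1[setdiff(names(ax1), above)]))

  # identical presence patterns -> coincident points
  expect_lt(max(abs(res$ordination$coordinates["o1", ] -
                      res$ordination$coordinates["o2", ])), 1e-8)

  onlyabove <- po; onlyabove$partition <- "above"
  expect_error(partition_ordination(list(P1 = manual_fit(onlyabove, 6)),
                                    tab),
               "both")
})

test_that("distinct metacommunities raise PERMANOVA effect size", {
  cfg <- simulation_config(n_taxa = 80, n_hosts = 8, local_size = 400,
                           depth = 400, m = 0.2, generations = 20,
                           seed = 51)
  same <- simulate_study(cfg, n_populations = 2,
                         shared_metacommunity = TRUE)
  diff_meta <- simulate_study(cfg, n_populations = 2,
                              shared_metacommunity = FALSE)
  r2 <- function(sim) {
    g <- stats::setNames(sim$table$metadata$population,
                         sample_ids(sim$table))
    permanova(bray_curtis(sim$table), g, n_permutations = 99,
              seed = 3)$effect
  }
  p_min <- permanova(bray_curtis(diff_meta$table),
                     stats::setNames(diff_meta$table$metadata$population,
                                     sample_ids(diff_meta$table)),
                     n_permutations = 999, seed = 3)$p_value
  expect_equal(p_min, 1 / 1000)
  expect_gt(r2(diff_meta), r2(same))
})
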