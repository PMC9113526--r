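test_that("metacommunity draws are valid heavy-tailed compositions", {
  cfg <- simulation_config(n_taxa = 200, seed = 3)
  meta <- make_metacommunity(cfg)
  expect_length(meta, 200)
  expect_equal(sum(meta), 1)
  expect_true(all(diff(meta) <= 0))          # rank-abundance non-increasing
  expect_identical(meta, make_metacommunity(cfg))   # deterministic

  ls_cfg <- simulation_config(n_taxa = 100,
                              sad = list(type = "logseries", p = 0.99),
                              seed = 4)
  ls <- make_metacommunity(ls_cfg)
  expect_equal(sum(ls), 1)

  fr_cfg <- simulation_config(n_taxa = 3,
                              sad = list(type = "fractions",
                                         fractions = c(0.5, 0.3, 0.2)))
  expect_equal(unname(make_metacommunity(fr_cfg)), c(0.5, 0.3, 0.2))
  expect_error(make_metacommunity(
    simulation_config(sad = list(type = "pareto"))), "unknown SAD")
})

test_that("host simulation conserves community size", {
  cfg <- simulation_config(n_taxa = 50, local_size = 500, m = 0.2,
                           generations = 10, depth = 100, seed = 1)
  meta <- make_metacommunity(cfg)
  for (s in 1:5) {
    comp <- simulate_host(meta, cfg, host_seed = s)
    expect_identical(sum(comp), 500L)
    expect_true(all(comp >= 0L))
  }
})

test_that("full immigration reproduces multinomial sampling from the source", {
  # with m = 1 every replacement is an immigrant: after burn-in the local
  # community is an iid multinomial sample of the metacommunity
  cfg <- simulation_config(n_taxa = 20,
                           sad = list(type = "fractions",
                                      fractions = rep(1 / 20, 20)),
                           local_size = 100, m = 1, generations = 10,
                           depth = 100, seed = 2)
  meta <- make_metacommunity(cfg)
  reps <- vapply(1:200, function(s) simulate_host(meta, cfg, s),
                 integer(20))
  mean_ab <- rowMeans(reps)
  expected <- 100 * meta
  se <- sqrt(100 * meta * (1 - meta) / 200)
  expect_true(all(abs(mean_ab - expected) < 3.5 * se))
  # detection frequency across hosts matches the exact multinomial oracle
  occ <- rowMeans(reps >= 1)
  occ_expected <- 1 - (1 - meta)^100
  se_occ <- sqrt(occ_expected * (1 - occ_expected) / 200)
  expect_true(all(abs(occ - occ_expected) < 4 * se_occ))
})

test_that("without immigration drift fixes a single taxon", {
  cfg <- simulation_config(n_taxa = 10,
                           sad = list(type = "fractions",
                                      fractions = rep(0.1, 10)),
                           local_size = 50, m = 1e-12,
                           generations = 5000, depth = 50, seed = 6)
  meta <- make_metacommunity(cfg)
  for (s in 1:4) {
    comp <- simulate_host(meta, cfg, host_seed = s)
    expect_identical(max(comp), 50L)   # monodominance
  }
})

test_that("read sampling is multinomial with the right mean", {
  local <- c(a = 600, b = 300, c = 100)
  reads <- vapply(1:1000, function(s) sample_reads(local, 50, seed = s),
                  integer(3))
  expect_true(all(colSums(reads) == 50))
  expected <- 50 * local / 1000
  se <- sqrt(50 * (local / 1000) * (1 - local / 1000) / 1000)
  expect_true(all(abs(rowMeans(reads) - expected) < 3.5 * se))
  one <- sample_reads(c(x = 5), 20, seed = 1)
  expect_identical(unname(one), 20L)
  expect_error(sample_reads(c(x = 0, y = 0), 10, seed = 1), "all-zero")
})

test_that("study simulation is reproducible and carries metadata", {
  cfg <- simulation_config(n_taxa = 60, n_hosts = 8, local_size = 300,
                           depth = 300, m = 0.2, generations = 10, seed = 11)
  sim1 <- simulate_study(cfg, n_populations = 5)
  expect_identical(n_samples(sim1$table), 40L)
  expect_identical(as.integer(table(sim1$table$metadata$population)),
                   rep(8L, 5))
  sim2 <- simulate_study(cfg, n_populations = 5)
  expect_identical(sim1$table$counts, sim2$table$counts)
  expect_identical(sim1$truth$seeds, sim2$truth$seeds)
  sim3 <- simulate_study(simulation_config(n_taxa = 60, n_hosts = 8,
                                           local_size = 300, depth = 300,
                                           m = 0.2, generations = 10,
                                           seed = 12),
                         n_populations = 5)
  expect_false(identical(sim1$table$counts, sim3$table$counts))
  # per-population immigration override is recorded in the truth
  simm <- simulate_study(cfg, n_populations = 2, m = c(0.05, 0.5))
  expect_identical(unname(simm$truth$m_true), c(0.05, 0.5))
})

test_that("occupancy of rare taxa increases with immigration", {
  cfg0 <- simulation_config(n_taxa = 100, n_hosts = 10, local_size = 500,
                            depth = 500, generations = 30, seed = 21)
  meta <- make_metacommunity(cfg0)
  rare <- meta < median(meta)
  occ <- vapply(c(0.02, 0.1, 0.5), function(mm) {
    cfg <- simulation_config(n_taxa = 100,
                             sad = list(type = "fractions",
                                        fractions = unname(meta)),
                             n_hosts = 10, local_size = 500, depth = 500,
                             generations = 30, m = mm, seed = 21)
    sim <- simulate_study(cfg, n_populations = 1)
    counts <- matrix(0L, n_samples(sim$table), length(meta),
                     dimnames = list(sample_ids(sim$table), names(meta)))
    counts[, otu_ids(sim$table)] <- sim$table$counts
    mean(colMeans(counts[, rare] >= 1))
  }, numeric(1))
  expect_true(all(diff(occ) > 0))
})

test_that("burn-in is long enough for stationary summary statistics", {
  rich <- vapply(c(30L, 60L), function(g) {
    cfg <- simulation_config(n_taxa = 150, n_hosts = 10, local_size = 1000,
                             depth = 1000, m = 0.1, generations = g,
                             seed = 31)
    sim <- simulate_study(cfg, n_populations = 1)
    mean(rowSums(sim$table$counts >= 1))
  }, numeric(1))
  expect_lt(abs(rich[1] - rich[2]) / rich[2], 0.1)
})

test_that("excluded taxa are banned per host at the configured rate", {
  meta <- c(big = 0.5, mid = 0.3, small = 0.2)
  cfg <- simulation_config(n_taxa = 3,
                           sad = list(type = "fractions",
                                      fractions = unname(meta)),
                           local_size = 200, m = 0.3, generations = 5,
                           depth = 200,
                           excluded = c(big = 0.6))
  hits <- vapply(1:300, function(s) {
    comp <- simulate_host(stats::setNames(meta, names(meta)), cfg, s)
    banned <- attr(comp, "banned")
    if (length(banned)) expect_identical(unname(comp["big"]), 0L)
    length(banned) > 0
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.6), 3.5 * sqrt(0.6 * 0.4 / 300))
})

test_that("selected taxa are pinned at their protected niche quota", {
  meta <- c(dom = 0.9, nich = 0.005, rest = 0.095)
  cfg <- simulation_config(n_taxa = 3,
                           sad = list(type = "fractions",
                                      fractions = unname(meta)),
                           local_size = 1000, m = 0.1, generations = 30,
                           depth = 1000, selected = c(nich = 10))
  quota <- round(0.005 * 1000)   # 5 individuals
  for (s in 1:6) {
    comp <- simulate_host(stats::setNames(meta, names(meta)), cfg, s)
    expect_identical(unname(comp["nich"]), as.integer(quota))
  }
})
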