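#' Configuration of a neutral-assembly simulation
#'
#' Describes the stated world of a synthetic host-microbiome study: a
#' heavy-tailed metacommunity of `n_taxa` taxa, `n_hosts` local host
#' communities of `local_size` individuals assembled by Moran-type
#' death-birth dynamics with immigration probability `m` per replacement,
#' run for `generations` generations (1 generation = `local_size` events)
#' and then sequenced to `depth` multinomial reads per host.
#'
#' Non-neutral taxa are optional. `selected` taxa are maintained by the
#' host in a small protected niche: while such a taxon's local count is at
#' or below its target quota (its expected metacommunity share, at least
#' one individual) its individuals are exempt from death, and below the
#' quota its immigration weight is multiplied by the given factor (>1
#' favours establishment). Together these pin the taxon at a low, stable
#' abundance in every host, pushing occupancy above the neutral expectation
#' at that abundance — the signature of host selection. `excluded` taxa are
#' rejected wholesale by individual hosts: each host independently bans the
#' taxon with the given probability (no immigration, absent from the
#' initial community), pulling occupancy below the neutral expectation.
#' Note that a plain reweighting of the immigration pool applied equally in
#' all hosts is *not* offered as a selection mechanism: it is provably
#' equivalent to neutral assembly from a modified metacommunity and cannot
#' move taxa out of the within-partition; host selection requires
#' suppressing the between-host variance, not shifting the mean.
#'
#' @param n_taxa metacommunity richness (default 300)
#' @param sad species abundance distribution: a list
#'   `list(type = "lognormal", meanlog = 0, sdlog = 2)` (default),
#'   `list(type = "logseries", p = 0.995)`, or
#'   `list(type = "fractions", fractions = <numeric>)` for user-supplied
#'   relative abundances
#' @param n_hosts hosts per population (default 15)
#' @param local_size individuals per host community (default 5000; should be
#'   at least `depth`)
#' @param m immigration probability per replacement, in (0, 1] (default 0.1)
#' @param generations burn-in length in generations (default 30)
#' @param depth sequencing reads per host (default 5000)
#' @param seed master integer seed
#' @param selected optional named numeric vector: taxon id -> immigration
#'   weight multiplier (> 0; > 1 favours)
#' @param excluded optional named numeric vector: taxon id -> per-host
#'   rejection probability in [0, 1)
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(n_taxa = 300,
                              sad = list(type = "lognormal", meanlog = 0,
                                         sdlog = 2),
                              n_hosts = 15, local_size = 5000, m = 0.1,
                              generations = 30, depth = 5000, seed = 1,
                              selected = NULL, excluded = NULL) {
  stopifnot(n_taxa >= 2, n_hosts >= 1, local_size >= 10,
            m > 0, m <= 1, generations >= 0, depth >= 1,
            is.list(sad), !is.null(sad$type))
  if (local_size < depth)
    warning("local_size < depth: reads will oversample individuals")
  if (!is.null(selected)) {
    stopifnot(is.numeric(selected), !is.null(names(selected)),
              all(selected > 0))
  }
  if (!is.null(excluded)) {
    stopifnot(is.numeric(excluded), !is.null(names(excluded)),
              all(excluded >= 0 & excluded < 1))
  }
  if (length(intersect(names(selected), names(excluded))))
    stop("a taxon cannot be both selected and excluded")
  structure(list(n_taxa = as.integer(n_taxa), sad = sad,
                 n_hosts = as.integer(n_hosts),
                 local_size = as.integer(local_size), m = m,
                 generations = as.integer(generations),
                 depth = as.integer(depth), seed = as.integer(seed),
                 selected = selected, excluded = excluded),
            class = "simulation_config")
}

#' Draw metacommunity relative abundances
#'
#' Generates `n_taxa` relative abundances from the configured species
#' abundance distribution, sorted in decreasing order and named
#' `otu_0001 ...` by abundance rank. Deterministic given `seed`.
#'
#' @param config a [simulation_config]
#' @param seed integer seed (default: the config seed)
#' @return named numeric vector of fractions summing to 1
#' @export
make_metacommunity <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  sad <- config$sad
  n <- config$n_taxa
  set.seed(seed)
  raw <- switch(sad$type,
    lognormal = {
      meanlog <- if (is.null(sad$meanlog)) 0 else sad$meanlog
      sdlog <- if (is.null(sad$sdlog)) 2 else sad$sdlog
      stopifnot(sdlog > 0)
      stats::rlnorm(n, meanlog, sdlog)
    },
    logseries = {
      ps <- if (is.null(sad$p)) 0.995 else sad$p
      stopifnot(ps > 0, ps < 1)
      rlogseries(n, ps)
    },
    fractions = {
      fr <- sad$fractions
      stopifnot(is.numeric(fr), length(fr) == n, all(fr > 0))
      fr
    },
    stop("unknown SAD type: ", sad$type)
  )
  fr <- sort(as.numeric(raw), decreasing = TRUE)
  fr <- fr / sum(fr)
  stats::setNames(fr, sprintf("otu_%04d", seq_len(n)))
}

# Fisher log-series abundances by inverse-CDF sampling; pmf proportional to
# p^k / k. No abundance-distribution generator is available in the installed
# stack, so this small sampler is local.
rlogseries <- function(n, p, kmax = 100000L) {
  k <- seq_len(kmax)
  pmf <- p^k / k
  cdf <- cumsum(pmf) / sum(pmf)
  k[findInterval(stats::runif(n), cdf) + 1L]
}

#' Simulate the assembly of one host community
#'
#' Initialises the local community by `local_size` multinomial draws from
#' the metacommunity, then runs `generations * local_size` death-birth
#' events: one uniformly chosen individual dies and is replaced either by an
#' immigrant (probability `m`; drawn from the metacommunity weights,
#' modified by the selection and exclusion rules of the config) or by a copy
#' of a uniformly chosen surviving local individual. Per-host exclusion bans
#' are drawn first from the same seed, so the whole host is reproducible
#' from `host_seed`.
#'
#' @param meta named metacommunity fractions (see [make_metacommunity()])
#' @param config a [simulation_config]
#' @param host_seed integer seed for this host
#' @return named integer vector of final local abundances (length
#'   `n_taxa`, summing to `local_size`); attribute `"banned"` lists the
#'   taxa this host rejected
#' @export
simulate_host <- function(meta, config, host_seed) {
  stopifnot(inherits(config, "simulation_config"),
            is.numeric(meta), !is.null(names(meta)),
            abs(sum(meta) - 1) < 1e-8)
  set.seed(host_seed)

  banned <- character(0)
  if (!is.null(config$excluded)) {
    miss <- setdiff(names(config$excluded), names(meta))
    if (length(miss)) stop("excluded taxon not in metacommunity: ", miss[1L])
    hit <- stats::runif(length(config$excluded)) < config$excluded
    banned <- names(config$excluded)[hit]
  }
  meta_eff <- meta
  meta_eff[banned] <- 0
  if (all(meta_eff == 0)) stop("all taxa banned from host")
  meta_eff <- meta_eff / sum(meta_eff)

  init <- as.integer(stats::rmultinom(1L, config$local_size, meta_eff))

  sel_idx <- integer(0); sel_w <- numeric(0); sel_target <- integer(0)
  if (!is.null(config$selected)) {
    miss <- setdiff(names(config$selected), names(meta))
    if (length(miss)) stop("selected taxon not in metacommunity: ", miss[1L])
    sel_idx <- match(names(config$selected), names(meta)) - 1L
    sel_w <- as.numeric(config$selected)
    sel_target <- pmax(1L, as.integer(round(meta[names(config$selected)] *
                                              config$local_size)))
  }

  out <- moran_host_cpp(init, meta_eff, config$m, config$generations,
                        sel_idx, sel_w, sel_target)
  names(out) <- names(meta)
  attr(out, "banned") <- banned
  out
}

#' Sequence a local community to a fixed read depth
#'
#' Multinomial read sampling from the local composition, emulating
#' amplicon sequencing at a fixed depth.
#'
#' @param local non-negative abundance vector (at least one positive entry)
#' @param depth number of reads
#' @param seed integer seed
#' @return integer read-count vector summing to `depth`, names preserved
#' @export
sample_reads <- function(local, depth, seed) {
  stopifnot(is.numeric(local), length(local) >= 1L, depth >= 1)
  if (sum(local) <= 0) stop("cannot sequence an all-zero composition")
  set.seed(seed)
  reads <- as.integer(stats::rmultinom(1L, depth, local / sum(local)))
  names(reads) <- names(local)
  reads
}

#' Simulate a multi-population host-microbiome study
#'
#' Generates a full study: `n_populations` populations of `n_hosts` hosts
#' each, assembled by [simulate_host()] and sequenced by [sample_reads()],
#' assembled into one [otu_table] with population metadata, together with a
#' `simulation_truth` object recording every ground-truth quantity needed to
#' regenerate or audit the dataset. All per-population and per-host seeds
#' are derived from the master seed (`config$seed`) by a fixed-seed draw
#' from R's RNG stream, so the whole study is reproducible bit-for-bit.
#'
#' @param config a [simulation_config] shared by all populations
#' @param n_populations number of populations (default 5)
#' @param m optional numeric vector of per-population immigration rates
#'   (recycled config `m` otherwise)
#' @param population_names optional character names (default `P1`, `P2`, ...)
#' @param shared_metacommunity if `TRUE` (default) all populations draw
#'   hosts from one metacommunity; if `FALSE` each population gets an
#'   independent draw from the configured SAD
#' @return list with `table` (an [otu_table]; metadata columns
#'   `population`, `variety`, `location`) and `truth` (class
#'   `simulation_truth`)
#' @export
simulate_study <- function(config, n_populations = 5, m = NULL,
                           population_names = NULL,
                           shared_metacommunity = TRUE) {
  stopifnot(inherits(config, "simulation_config"), n_populations >= 1)
  if (is.null(population_names))
    population_names <- paste0("P", seq_len(n_populations))
  stopifnot(length(population_names) == n_populations)
  m_pop <- if (is.null(m)) rep(config$m, n_populations)
           else rep_len(m, n_populations)
  stopifnot(all(m_pop > 0 & m_pop <= 1))

  # seed streams derived once from the master seed
  set.seed(config$seed)
  meta_seeds <- sample.int(2147483646L, n_populations)
  host_seeds <- matrix(sample.int(2147483646L,
                                  n_populations * config$n_hosts),
                       nrow = n_populations)
  read_seeds <- matrix(sample.int(2147483646L,
                                  n_populations * config$n_hosts),
                       nrow = n_populations)

  meta_shared <- make_metacommunity(config, seed = meta_seeds[1L])
  counts <- NULL
  metadata <- NULL
  locals <- list()
  metas <- list()
  banned <- list()
  for (pop in seq_len(n_populations)) {
    meta <- if (shared_metacommunity) meta_shared
            else make_metacommunity(config, seed = meta_seeds[pop])
    metas[[population_names[pop]]] <- meta
    cfg <- config
    cfg$m <- m_pop[pop]
    loc <- matrix(0L, nrow = config$n_hosts, ncol = config$n_taxa,
                  dimnames = list(NULL, names(meta)))
    reads <- loc
    ban <- vector("list", config$n_hosts)
    for (h in seq_len(config$n_hosts)) {
      comp <- simulate_host(meta, cfg, host_seeds[pop, h])
      ban[[h]] <- attr(comp, "banned")
      loc[h, ] <- comp
      reads[h, ] <- sample_reads(comp, config$depth, read_seeds[pop, h])
    }
    ids <- sprintf("%s_h%02d", population_names[pop],
                   seq_len(config$n_hosts))
    rownames(loc) <- rownames(reads) <- ids
    locals[[population_names[pop]]] <- loc
    banned[[population_names[pop]]] <- stats::setNames(ban, ids)
    counts <- rbind(counts, reads)
    metadata <- rbind(metadata, data.frame(
      sample_id = ids,
      population = population_names[pop],
      variety = paste0("variety_", population_names[pop]),
      location = paste0("location_", population_names[pop]),
      stringsAsFactors = FALSE))
  }
  keep <- colSums(counts) > 0L
  table <- otu_table(counts[, keep, drop = FALSE], metadata = metadata)
  truth <- structure(list(
    config = unclass(config),
    n_populations = n_populations,
    population_names = population_names,
    m_true = stats::setNames(m_pop, population_names),
    shared_metacommunity = shared_metacommunity,
    metacommunity = if (shared_metacommunity) meta_shared else metas,
    selected_taxa = config$selected,
    excluded_taxa = config$excluded,
    banned = banned,
    local_compositions = locals,
    seeds = list(master = config$seed, metacommunity = meta_seeds,
                 hosts = host_seeds, reads = read_seeds)),
    class = "simulation_truth")
  list(table = table, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth:", x$n_populations, "populations x",
      x$config$n_hosts, "hosts,", x$config$n_taxa, "taxa\n")
  cat("  m_true:", paste(sprintf("%s=%g", names(x$m_true), x$m_true),
                         collapse = ", "), "\n")
  cat("  selected:", length(x$selected_taxa),
      "| excluded:", length(x$excluded_taxa), "taxa\n")
  invisible(x)
}

#' Serialise simulation ground truth as JSON
#'
#' @param truth a `simulation_truth` from [simulate_study()]
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_simulation_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  out <- truth
  out$local_compositions <- lapply(out$local_compositions, function(m)
    as.data.frame(m, stringsAsFactors = FALSE))
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
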