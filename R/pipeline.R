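#' @title Configuration-driven end-to-end analysis pipeline
#' @description [run_pipeline()] reproduces the shape of a full per-host
#'   microbiome neutral-assembly analysis on any conforming input (a real
#'   OTU table plus metadata, or a simulated study): standard filters,
#'   rarefaction, per-population neutral-model fits and partitions, a
#'   cross-population partition summary, alpha-diversity comparisons,
#'   Bray-Curtis distances with PCoA, PERMANOVA and ANOSIM for every group
#'   pair, and ordination of the above/below partitions. All randomness is
#'   seeded through the configuration so outputs are byte-identical across
#'   reruns.
#' @name pipeline
NULL

pipeline_keys <- function() {
  list(
    otu_table = list(type = "character", default = NULL),
    metadata = list(type = "character", default = NULL),
    simulate = list(type = "logical", default = FALSE),
    sim_n_taxa = list(type = "numeric", default = 300),
    sim_n_hosts = list(type = "numeric", default = 15),
    sim_n_populations = list(type = "numeric", default = 5),
    sim_local_size = list(type = "numeric", default = 5000),
    sim_m = list(type = "numeric", default = 0.1),
    sim_generations = list(type = "numeric", default = 30),
    sim_depth = list(type = "numeric", default = 5000),
    sim_sdlog = list(type = "numeric", default = 2),
    sim_seed = list(type = "numeric", default = NULL),
    grouping_column = list(type = "character", default = "population"),
    min_total_reads = list(type = "numeric", default = 100),
    lineage_excludes = list(type = "character", default = "Chloroplast"),
    neutral_abund_threshold = list(type = "numeric", default = 0.005),
    rarefy_depth = list(type = "numeric", default = NULL),
    rarefy_seed = list(type = "numeric", default = NULL),
    neutral_d = list(type = "numeric", default = 1),
    neutral_m_start = list(type = "numeric", default = 0.1),
    n_permutations = list(type = "numeric", default = 999),
    perm_seed = list(type = "numeric", default = NULL),
    outdir = list(type = "character", default = "ncmfit_run")
  )
}

#' Validate a pipeline configuration
#'
#' Reads a flat `key = value` text file (`#` comments allowed; values with
#' commas become vectors), fills in documented defaults, resolves any
#' unspecified seeds by drawing and recording them, and rejects unknown
#' keys and type mismatches. Exactly one of `otu_table` (with optional
#' `metadata`) and `simulate = true` must be configured. When an input
#' table and an explicit `rarefy_depth` are both given, the depth is
#' checked against the smallest sample total before any computation.
#'
#' @param path path to the config file, or a named list of settings
#' @return the resolved configuration (named list, class `pipeline_config`)
#' @export
validate_config <- function(path) {
  keys <- pipeline_keys()
  if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    raw <- list()
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE))
        stop("malformed config line (expected key = value): '", ln, "'")
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      raw[[key]] <- val
    }
  } else if (is.list(path)) {
    raw <- path
  } else stop("config must be a file path or a named list")

  unknown <- setdiff(names(raw), names(keys))
  if (length(unknown)) stop("unknown config key: ", unknown[1L])

  cfg <- lapply(keys, `[[`, "default")
  for (key in names(raw)) {
    val <- raw[[key]]
    type <- keys[[key]]$type
    if (is.character(val) && type != "character") {
      parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
      val <- switch(type,
        numeric = {
          num <- suppressWarnings(as.numeric(parts))
          if (anyNA(num))
            stop("config key '", key, "' expects a numeric value, got '",
                 raw[[key]], "'")
          num
        },
        logical = {
          lg <- as.logical(toupper(parts))
          if (anyNA(lg))
            stop("config key '", key, "' expects true/false, got '",
                 raw[[key]], "'")
          lg
        })
    } else if (is.character(val) && type == "character") {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    } else {
      ok <- switch(type, numeric = is.numeric(val),
                   logical = is.logical(val), character = is.character(val))
      if (!ok)
        stop("config key '", key, "' expects type ", type, ", got ",
             class(val)[1L])
    }
    cfg[[key]] <- val
  }

  has_input <- !is.null(cfg$otu_table)
  if (has_input && isTRUE(cfg$simulate))
    stop("config must set exactly one of 'otu_table' and 'simulate'")
  if (!has_input && !isTRUE(cfg$simulate))
    stop("config must set either 'otu_table' or 'simulate = true'")

  # resolve seeds so the run is reproducible from the echoed config
  for (s in c("sim_seed", "rarefy_seed", "perm_seed")) {
    if (is.null(cfg[[s]])) cfg[[s]] <- sample.int(2147483646L, 1L)
    cfg[[s]] <- as.integer(cfg[[s]])
  }

  if (has_input) {
    if (!file.exists(cfg$otu_table))
      stop("otu_table file not found: ", cfg$otu_table)
    if (!is.null(cfg$rarefy_depth)) {
      tab <- read_otu_table(cfg$otu_table)
      if (cfg$rarefy_depth > min(sample_totals(tab)))
        stop("rarefy_depth (", cfg$rarefy_depth,
             ") exceeds the smallest sample total (",
             min(sample_totals(tab)), ")")
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stage order: load or simulate -> min-total-reads filter -> lineage
#' exclusion -> rarefaction -> per-population neutral fit, partitioning and
#' cross-population summary (on the additionally abundance-filtered table)
#' -> alpha diversity with pairwise rank-sum tests -> Bray-Curtis distances
#' -> PCoA -> PERMANOVA and ANOSIM per group pair -> ordination of the
#' above/below partitions -> report. A stage failure aborts with the stage
#' name after writing a partial report.
#'
#' Outputs under `outdir`: `tables/` (TSV), `stats/` (JSON), `report.json`
#' (resolved config, filter reports, fit summaries, manifest with MD5
#' checksums) and `run.log`. Everything is deterministic given the resolved
#' seeds; `run.log` is excluded from the manifest.
#'
#' @param config a config file path, a named settings list, or a resolved
#'   `pipeline_config`
#' @return the run report (named list), invisibly
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  outdir <- config$outdir
  dir.create(file.path(outdir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "stats"), recursive = TRUE,
             showWarnings = FALSE)
  logfile <- file.path(outdir, "run.log")
  cat("", file = logfile)
  log_msg <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    message(msg)
  }
  report <- list(package_version = as.character(
                   utils::packageVersion("ncmfit")),
                 config = unclass(config), stages = character(0))
  stage <- function(name, expr) {
    log_msg("[stage] ", name)
    report$stages <<- c(report$stages, name)
    tryCatch(expr, error = function(e) {
      report$failed_stage <<- name
      report$error <<- conditionMessage(e)
      jsonlite::write_json(report, file.path(outdir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  table <- stage("load", {
    if (isTRUE(config$simulate)) {
      sim_cfg <- simulation_config(
        n_taxa = config$sim_n_taxa,
        sad = list(type = "lognormal", meanlog = 0, sdlog = config$sim_sdlog),
        n_hosts = config$sim_n_hosts, local_size = config$sim_local_size,
        m = config$sim_m, generations = config$sim_generations,
        depth = config$sim_depth, seed = config$sim_seed)
      sim <- simulate_study(sim_cfg,
                            n_populations = config$sim_n_populations)
      write_simulation_truth(sim$truth,
                             file.path(outdir, "stats", "truth.json"))
      log_msg("  simulated ", n_samples(sim$table), " samples x ",
              n_otus(sim$table), " OTUs")
      sim$table
    } else {
      tab <- read_otu_table(config$otu_table)
      if (!is.null(config$metadata)) {
        md <- read_metadata(config$metadata)
        tab <- otu_table(tab$counts, metadata = md, taxonomy = tab$taxonomy)
      }
      log_msg("  loaded ", n_samples(tab), " samples x ", n_otus(tab),
              " OTUs")
      tab
    }
  })

  reports <- list()
  table <- stage("filter_min_total_reads", {
    fr <- filter_min_total_reads(table, config$min_total_reads)
    reports$min_total_reads <- unclass(fr$report)
    log_msg("  ", fr$report$n_otus_before, " -> ", fr$report$n_otus_after,
            " OTUs")
    fr$table
  })
  table <- stage("filter_lineage", {
    fr <- filter_lineage(table, config$lineage_excludes)
    reports$lineage <- unclass(fr$report)
    fr$table
  })
  rarefied <- stage("rarefy", {
    depth <- if (is.null(config$rarefy_depth)) min(sample_totals(table))
             else as.integer(config$rarefy_depth)
    out <- rarefy(table, depth = depth, seed = config$rarefy_seed)
    reports$rarefaction <- attr(out, "rarefaction")
    log_msg("  depth ", depth, ", seed ", config$rarefy_seed)
    write_otu_table(out, file.path(outdir, "tables", "otu_rarefied.tsv"))
    write_metadata(out$metadata,
                   file.path(outdir, "tables", "metadata.tsv"))
    out
  })
  report$filter_reports <- reports

  grouping <- stage("grouping",
                    resolve_grouping(rarefied, config$grouping_column))
  groups <- sort(unique(grouping))

  fits <- stage("neutral_fit", {
    fr <- filter_max_relative_abundance(rarefied,
                                        config$neutral_abund_threshold)
    report$filter_reports$neutral_abundance <- unclass(fr$report)
    fits <- list()
    for (g in groups) {
      fit <- fit_neutral(fr$table, samples = names(grouping)[grouping == g],
                         d = config$neutral_d,
                         m_start = config$neutral_m_start)
      fits[[g]] <- fit
      log_msg(sprintf("  %s: m = %.4f, R2 = %.3f, within = %.1f%%", g,
                      fit$m, fit$r_squared,
                      100 * fit$partition_summary[["within"]]))
      write_neutral_fit(fit,
                        file.path(outdir, "tables",
                                  paste0("neutral_fit_", g, ".tsv")),
                        file.path(outdir, "stats",
                                  paste0("neutral_fit_", g, ".json")))
    }
    fits
  })
  report$neutral_fits <- lapply(fits, function(f)
    list(m = f$m, Nm = f$Nm, N = f$N, r_squared = f$r_squared,
         n_hosts = f$n_hosts, n_otus_fit = f$n_otus_fit,
         partition_fractions = as.list(f$partition_summary)))

  if (length(fits) >= 2L) {
    stage("cross_population_summary", {
      cps <- cross_population_summary(fits)
      utils::write.table(cps$per_otu,
                         file.path(outdir, "tables",
                                   "cross_population_partitions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$cross_population <-
        list(above_histogram = as.list(cps$above_histogram),
             n_exclusively_within = cps$n_exclusively_within)
      NULL
    })
  }

  stage("diversity", {
    cmp <- compare_diversity(rarefied, config$grouping_column)
    utils::write.table(cmp$per_sample,
                       file.path(outdir, "tables", "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cmp$comparisons,
                       file.path(outdir, "tables",
                                 "diversity_comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    NULL
  })

  tests <- stage("community_structure", {
    d <- bray_curtis(rarefied)
    write_distance_matrix(d, file.path(outdir, "tables",
                                       "distance_bray_curtis.tsv"))
    ord <- pcoa(d)
    utils::write.table(
      data.frame(sample_id = rownames(ord$coordinates),
                 ord$coordinates[, seq_len(min(3L, ncol(ord$coordinates))),
                                 drop = FALSE],
                 check.names = FALSE),
      file.path(outdir, "tables", "pcoa_coordinates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- list()
    pairs <- utils::combn(groups, 2L)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      sel <- names(grouping)[grouping %in% c(a, b)]
      dp <- bray_curtis(rarefied[sel, ])
      gp <- grouping[sel]
      pm <- permanova(dp, gp, n_permutations = config$n_permutations,
                      seed = config$perm_seed)
      an <- anosim(dp, gp, n_permutations = config$n_permutations,
                   seed = config$perm_seed)
      log_msg(sprintf("  %s vs %s: F = %.3f, R2 = %.3f, p = %.4f | r = %.3f, p = %.4f",
                      a, b, pm$statistic, pm$effect, pm$p_value,
                      an$statistic, an$p_value))
      tests[[paste(a, b, sep = "_vs_")]] <-
        list(permanova = unclass(pm), anosim = unclass(an))
    }
    jsonlite::write_json(tests, file.path(outdir, "stats", "tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    tests
  })
  report$tests <- tests

  stage("partition_ordination", {
    po <- tryCatch(
      withCallingHandlers(partition_ordination(fits, rarefied),
                          warning = function(w) {
                            log_msg("  warning: ", conditionMessage(w))
                            invokeRestart("muffleWarning")
                          }),
      error = function(e) e)
    if (inherits(po, "error")) {
      log_msg("  skipped: ", conditionMessage(po))
      report$partition_ordination <- list(skipped = conditionMessage(po))
    } else {
      coords <- po$ordination$coordinates
      utils::write.table(
        data.frame(otu_id = rownames(coords),
                   partition = po$labels$partition[
                     match(rownames(coords), po$labels$otu_id)],
                   coords[, seq_len(min(3L, ncol(coords))), drop = FALSE],
                   check.names = FALSE),
        file.path(outdir, "tables", "partition_ordination.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      report$partition_ordination <-
        list(n_above = sum(po$labels$partition == "above"),
             n_below = sum(po$labels$partition == "below"))
    }
    NULL
  })

  # manifest: every output file except the log, with checksums
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        c("run.log", "report.json")))
  report$manifest <- lapply(stats::setNames(files, files), function(f)
    unname(tools::md5sum(file.path(outdir, f))))
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_msg("[done] ", length(files) + 1L, " output files in ", outdir)
  invisible(report)
}
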