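#' @title Filtering and normalisation of OTU tables
#' @description Filters mirror a standard amplicon workflow: drop globally
#'   rare OTUs, drop unwanted lineages (chloroplast reads), rarefy all
#'   samples to a common depth, and (immediately before neutral-model
#'   fitting only) drop OTUs that never reach a minimum per-sample relative
#'   abundance. Each filter returns the reduced table together with a
#'   `filter_report` that reconciles exactly
#'   (`before - removed = after` on both axes).
#' @name preprocess
NULL

new_filter_report <- function(rule, params, before, after, removed_otu_ids,
                              removed_sample_ids = character(0)) {
  structure(list(rule = rule, params = params,
                 n_otus_before = n_otus(before),
                 n_otus_after = n_otus(after),
                 n_samples_before = n_samples(before),
                 n_samples_after = n_samples(after),
                 removed_otu_ids = removed_otu_ids,
                 removed_sample_ids = removed_sample_ids),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report [", x$rule, "]: ", x$n_otus_before, " -> ",
      x$n_otus_after, " OTUs, ", x$n_samples_before, " -> ",
      x$n_samples_after, " samples\n", sep = "")
  invisible(x)
}

#' Remove OTUs with low total read count
#'
#' Drops every OTU whose read count summed over all samples is below
#' `min_reads` (default 100, the usual pre-analysis cutoff for sequencing
#' noise). Samples are never removed.
#'
#' @param table an [otu_table]
#' @param min_reads positive integer threshold; an OTU survives iff its
#'   total is `>= min_reads`
#' @return list with elements `table` (filtered [otu_table]) and `report`
#'   (a `filter_report`)
#' @export
filter_min_total_reads <- function(table, min_reads = 100) {
  stopifnot(inherits(table, "otu_table"),
            is.numeric(min_reads), length(min_reads) == 1L, min_reads >= 1)
  totals <- colSums(table$counts)
  keep <- totals >= min_reads
  out <- table[, keep]
  list(table = out,
       report = new_filter_report("min_total_reads",
                                  list(min_reads = min_reads),
                                  table, out, otu_ids(table)[!keep]))
}

#' Remove OTUs whose lineage matches excluded taxon names
#'
#' Drops OTUs whose taxonomy string contains any of `exclude_names` as a
#' case-insensitive exact token (tokens are the semicolon-delimited rank
#' names, rank prefixes such as `c__` stripped). The stock use is removing
#' chloroplast 16S reads. OTUs without taxonomy are retained.
#'
#' @param table an [otu_table]
#' @param exclude_names character vector of taxon names, default
#'   `"Chloroplast"`
#' @return list with `table` and `report` as in [filter_min_total_reads()]
#' @export
filter_lineage <- function(table, exclude_names = "Chloroplast") {
  stopifnot(inherits(table, "otu_table"))
  if (length(exclude_names) == 0L || is.null(table$taxonomy)) {
    return(list(table = table,
                report = new_filter_report("lineage",
                                           list(exclude = exclude_names),
                                           table, table, character(0))))
  }
  excl <- tolower(exclude_names)
  hit <- vapply(table$taxonomy, function(lin) {
    if (is.na(lin)) return(FALSE)
    tokens <- tolower(unname(parse_lineage(lin)))
    any(tokens %in% excl)
  }, logical(1L))
  out <- table[, !hit]
  list(table = out,
       report = new_filter_report("lineage", list(exclude = exclude_names),
                                  table, out, otu_ids(table)[hit]))
}

#' Remove OTUs that never reach a minimum relative abundance
#'
#' Applied immediately before neutral-model fitting. An OTU is retained iff
#' its per-sample relative abundance reaches at least `threshold` in at
#' least one sample (`stat = "max"`, default) or on average across samples
#' (`stat = "mean"`). The default threshold of 0.005 (0.5%) restricts the
#' fit to OTUs quantifiable within single hosts.
#'
#' @param table an [otu_table] with positive sample totals
#' @param threshold fraction in (0, 1), default `0.005`
#' @param stat `"max"` (default) or `"mean"` per-sample relative abundance
#' @return list with `table` and `report` as in [filter_min_total_reads()]
#' @export
filter_max_relative_abundance <- function(table, threshold = 0.005,
                                          stat = c("max", "mean")) {
  stopifnot(inherits(table, "otu_table"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1, n_otus(table) > 0)
  stat <- match.arg(stat)
  rel <- relative_abundance(table)
  per_otu <- if (stat == "max") apply(rel, 2L, max) else colMeans(rel)
  keep <- per_otu >= threshold
  out <- table[, keep]
  list(table = out,
       report = new_filter_report("max_relative_abundance",
                                  list(threshold = threshold, stat = stat),
                                  table, out, otu_ids(table)[!keep]))
}

#' Rarefy every sample to a common depth
#'
#' Random subsampling of reads without replacement (a single draw per
#' sample, so counts stay integral), the standard depth normalisation before
#' diversity and neutral-model analyses. OTUs left with zero counts in all
#' samples are dropped. Deterministic given `seed`.
#'
#' @param table an [otu_table]
#' @param depth target reads per sample; defaults to the smallest sample
#'   total. Must not exceed any sample total.
#' @param seed integer RNG seed (required, recorded on the result)
#' @return a rarefied [otu_table]; the attribute `"rarefaction"` records
#'   `depth` and `seed`
#' @export
rarefy <- function(table, depth = min(sample_totals(table)), seed) {
  stopifnot(inherits(table, "otu_table"))
  if (missing(seed)) stop("rarefy() requires an explicit seed")
  depth <- as.integer(depth)
  stopifnot(depth >= 1L)
  totals <- sample_totals(table)
  if (any(totals < depth)) {
    worst <- which.min(totals)
    stop("sample '", sample_ids(table)[worst], "' has only ",
         totals[worst], " reads, fewer than depth ", depth)
  }
  set.seed(seed)
  sub <- withCallingHandlers(
    vegan::rrarefy(table$counts, depth),
    # rrarefy warns when the smallest positive count exceeds 1; that is a
    # perfectly regular state for filtered OTU tables
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  keep <- colSums(sub) > 0L
  out <- otu_table(sub[, keep, drop = FALSE],
                   metadata = table$metadata,
                   taxonomy = if (!is.null(table$taxonomy))
                     table$taxonomy[keep])
  attr(out, "rarefaction") <- list(depth = depth, seed = seed)
  out
}

#' Per-sample relative abundances
#'
#' @param table an [otu_table] with all sample totals positive
#' @return numeric matrix (samples x OTUs); every row sums to 1
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  totals <- sample_totals(table)
  if (any(totals == 0))
    stop("sample '", sample_ids(table)[totals == 0][1L],
         "' has zero total reads")
  table$counts / totals
}

#' Core OTUs of a sample set
#'
#' OTUs detected (count >= 1) in every sample of the chosen subset.
#'
#' @param table an [otu_table]
#' @param samples optional character vector of sample ids (default: all)
#' @return character vector of OTU ids
#' @export
core_otus <- function(table, samples = NULL) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(samples)) samples <- sample_ids(table)
  if (length(samples) == 0L) stop("empty sample subset")
  missing <- setdiff(samples, sample_ids(table))
  if (length(missing)) stop("unknown sample(s): ",
                            paste(missing, collapse = ", "))
  sub <- table$counts[samples, , drop = FALSE]
  otu_ids(table)[colSums(sub >= 1L) == length(samples)]
}

#' Core OTU sets per group and their Venn-style breakdown
#'
#' Computes the per-group core (OTUs present in every sample of the group,
#' via [core_otus()]), the OTUs shared by all groups, and the OTUs unique to
#' each group's core.
#'
#' @param table an [otu_table]
#' @param grouping named character vector mapping sample id to group, or the
#'   name of a metadata column (default `"population"`)
#' @return list with `core` (named list of per-group core OTU id vectors),
#'   `shared_all` (intersection across groups), `unique` (per-group core
#'   OTUs found in no other group's core) and `counts` (named integer
#'   summary)
#' @export
shared_across_groups <- function(table, grouping = "population") {
  stopifnot(inherits(table, "otu_table"))
  grouping <- resolve_grouping(table, grouping)
  groups <- split(names(grouping), grouping)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("group with zero samples")
  core <- lapply(groups, function(s) core_otus(table, s))
  shared_all <- Reduce(intersect, core)
  unique_sets <- lapply(seq_along(core), function(i)
    setdiff(core[[i]], unlist(core[-i], use.names = FALSE)))
  names(unique_sets) <- names(core)
  list(core = core, shared_all = shared_all, unique = unique_sets,
       counts = c(stats::setNames(lengths(core),
                                  paste0("core_", names(core))),
                  shared_all = length(shared_all),
                  stats::setNames(lengths(unique_sets),
                                  paste0("unique_", names(unique_sets)))))
}

# Resolve a grouping spec (metadata column name or named vector) to a named
# character vector over all samples of the table.
resolve_grouping <- function(table, grouping) {
  if (is.character(grouping) && length(grouping) == 1L &&
      is.null(names(grouping))) {
    if (is.null(table$metadata) || !grouping %in% names(table$metadata))
      stop("metadata column not found: ", grouping)
    return(stats::setNames(table$metadata[[grouping]], sample_ids(table)))
  }
  if (is.null(names(grouping)))
    stop("grouping must be a metadata column name or a named vector")
  missing <- setdiff(sample_ids(table), names(grouping))
  if (length(missing)) stop("grouping missing sample(s): ",
                            paste(missing, collapse = ", "))
  stats::setNames(as.character(grouping[sample_ids(table)]),
                  sample_ids(table))
}
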