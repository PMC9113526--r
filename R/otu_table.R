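#' Construct an OTU table
#'
#' The central data container of the package: a non-negative integer count
#' matrix of samples (hosts) by OTUs, with optional per-sample metadata and
#' per-OTU taxonomy strings. The internal orientation is always
#' samples-in-rows, OTUs-in-columns; on-disk files conventionally store the
#' transpose (OTUs as rows), which the readers and writers handle.
#'
#' @param counts numeric matrix of non-negative integral counts with unique,
#'   non-empty row names (sample ids) and column names (OTU ids). Rows are
#'   samples, columns OTUs.
#' @param metadata optional `data.frame` of per-sample variables. Either its
#'   row names are sample ids or it has a `sample_id` column. Every sample in
#'   `counts` must be present. Typical columns: `population`, `variety`,
#'   `location`. All values are kept as character strings.
#' @param taxonomy optional named character vector of semicolon-delimited
#'   lineages (e.g. `"k__Bacteria;p__Proteobacteria;..."`), named by OTU id.
#'   Names must be a subset of the OTU ids; missing OTUs get `NA`.
#' @return an object of class `otu_table`: a list with elements `counts`
#'   (integer matrix), `metadata` (data.frame or `NULL`) and `taxonomy`
#'   (named character vector or `NULL`, aligned to the OTU ids).
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 1L, 3L, 4L), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2", "otu3")))
#' tab <- otu_table(m)
#' n_samples(tab); n_otus(tab)
#' @export
otu_table <- function(counts, metadata = NULL, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  # R stores zero-length dimnames as NULL, so empty margins are exempt
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("counts must have sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated sample id: ",
         rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stop("duplicated OTU id: ",
         colnames(counts)[duplicated(colnames(counts))][1L])
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("counts must not contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integral (no fractional reads)")
  storage.mode(counts) <- "integer"

  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
    if ("sample_id" %in% names(metadata)) {
      if (anyDuplicated(metadata$sample_id))
        stop("duplicated sample_id in metadata: ",
             metadata$sample_id[duplicated(metadata$sample_id)][1L])
      rownames(metadata) <- metadata$sample_id
      metadata$sample_id <- NULL
    }
    missing <- setdiff(rownames(counts), rownames(metadata))
    if (length(missing))
      stop("metadata missing sample(s): ", paste(missing, collapse = ", "))
    metadata <- metadata[rownames(counts), , drop = FALSE]
    metadata[] <- lapply(metadata, as.character)
  }

  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)))
      stop("taxonomy must be named by OTU id")
    unknown <- setdiff(names(taxonomy), colnames(counts))
    if (length(unknown))
      stop("taxonomy names not in OTU ids: ", paste(unknown, collapse = ", "))
    full <- stats::setNames(rep(NA_character_, ncol(counts)), colnames(counts))
    full[names(taxonomy)] <- as.character(taxonomy)
    taxonomy <- full
  }

  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "otu_table")
}

#' @rdname otu_table
#' @param x an `otu_table`
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
otu_ids <- function(x) {
  ids <- colnames(x$counts)
  if (is.null(ids)) character(0) else ids
}

#' @rdname otu_table
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_otus <- function(x) ncol(x$counts)

#' @rdname otu_table
#' @export
sample_totals <- function(x) rowSums(x$counts)

#' Subset an OTU table
#'
#' `x[i, j]` keeps samples `i` and OTUs `j` (ids, indices or logical),
#' carrying metadata and taxonomy along.
#'
#' @param x an `otu_table`
#' @param i,j sample and OTU selectors
#' @param ... ignored
#' @export
`[.otu_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  metadata <- if (!is.null(x$metadata))
    x$metadata[rownames(counts), , drop = FALSE]
  taxonomy <- if (!is.null(x$taxonomy)) x$taxonomy[colnames(counts)]
  otu_table(counts, metadata = metadata, taxonomy = taxonomy)
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table:", n_samples(x), "samples x", n_otus(x), "OTUs\n")
  cat("  total reads:", sum(x$counts),
      "| sample depth range:", paste(range(sample_totals(x)), collapse = "-"),
      "\n")
  if (!is.null(x$metadata))
    cat("  metadata columns:", paste(names(x$metadata), collapse = ", "), "\n")
  if (!is.null(x$taxonomy))
    cat("  taxonomy present for", sum(!is.na(x$taxonomy)), "OTUs\n")
  invisible(x)
}

#' Parse a semicolon-delimited lineage string
#'
#' Splits a lineage such as `"k__Bacteria;p__Proteobacteria"` or
#' `"Bacteria;Proteobacteria"` into named rank tokens. Tokens carrying a
#' conventional rank prefix (`k__`, `p__`, `c__`, `o__`, `f__`, `g__`,
#' `d__`) are assigned that rank; unprefixed tokens are assigned ranks
#' positionally from kingdom downwards.
#'
#' @param lineage a single lineage string (or `NA`)
#' @return named character vector of taxon names (possibly empty strings for
#'   unassigned ranks)
#' @export
parse_lineage <- function(lineage) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  if (is.na(lineage) || !nzchar(lineage))
    return(stats::setNames(character(0), character(0)))
  tokens <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1L]])
  prefix <- regmatches(tokens, regexpr("^[a-zA-Z]__", tokens))
  has_prefix <- grepl("^[a-zA-Z]__", tokens)
  names_out <- character(length(tokens))
  prefix_map <- c(k = "kingdom", d = "kingdom", p = "phylum", c = "class",
                  o = "order", f = "family", g = "genus", s = "species")
  pos <- 1L
  for (t in seq_along(tokens)) {
    if (has_prefix[t]) {
      key <- tolower(substr(tokens[t], 1L, 1L))
      names_out[t] <- if (key %in% names(prefix_map)) prefix_map[[key]]
                      else paste0("rank", t)
      tokens[t] <- sub("^[a-zA-Z]__", "", tokens[t])
      pos <- match(names_out[t], ranks, nomatch = pos)
      if (!is.na(pos)) pos <- pos + 1L
    } else {
      names_out[t] <- if (pos <= length(ranks)) ranks[pos]
                      else paste0("rank", t)
      pos <- pos + 1L
    }
  }
  stats::setNames(tokens, names_out)
}
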