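#' Read an OTU count table from a tab-separated file
#'
#' The expected dialect is the common amplicon-pipeline export: tab-separated,
#' UTF-8, first column holding row identifiers, remaining columns integer
#' counts, and optionally a final column named `taxonomy` (case-insensitive)
#' holding semicolon-delimited lineages. By default rows are OTUs and columns
#' are samples; set `orientation = "samples_as_rows"` for the transpose.
#' Internally the table is always normalised to samples-in-rows.
#'
#' @param path path to the TSV file
#' @param orientation `"otus_as_rows"` (default, the common convention) or
#'   `"samples_as_rows"`
#' @return an [otu_table]
#' @seealso [write_otu_table()], [read_metadata()]
#' @export
read_otu_table <- function(path,
                           orientation = c("otus_as_rows",
                                           "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 1L) stop("malformed table (no columns): ", path)
  row_ids <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  if (anyDuplicated(row_ids))
    stop("duplicated identifier in first column of ", path, ": ",
         row_ids[duplicated(row_ids)][1L])
  if (anyDuplicated(colnames(df)))
    stop("duplicated identifier in header of ", path, ": ",
         colnames(df)[duplicated(colnames(df))][1L])

  taxonomy <- NULL
  if (ncol(df) >= 1L && tolower(colnames(df)[ncol(df)]) == "taxonomy") {
    if (orientation == "samples_as_rows")
      stop("taxonomy column is only valid with OTUs as rows")
    taxonomy <- stats::setNames(df[[ncol(df)]], row_ids)
    df <- df[, -ncol(df), drop = FALSE]
  }

  mat <- as.matrix(df)
  num <- suppressWarnings(as.numeric(mat))
  bad <- which(is.na(num) & !is.na(mat))
  if (length(bad)) {
    b <- bad[1L]
    stop("non-numeric count in ", path, " at row '",
         row_ids[(b - 1L) %% nrow(mat) + 1L], "', column '",
         colnames(mat)[(b - 1L) %/% nrow(mat) + 1L], "': ", mat[b])
  }
  dim(num) <- dim(mat)
  bad <- which(num < 0 | num != round(num))
  if (length(bad)) {
    b <- bad[1L]
    stop("negative or fractional count in ", path, " at row '",
         row_ids[(b - 1L) %% nrow(num) + 1L], "', column '",
         colnames(mat)[(b - 1L) %/% nrow(num) + 1L], "': ", mat[b])
  }
  dimnames(num) <- list(row_ids, colnames(df))
  if (orientation == "otus_as_rows") num <- t(num)
  otu_table(num, taxonomy = taxonomy)
}

#' Write an OTU table as a tab-separated file
#'
#' Writes OTUs as rows and samples as columns (the on-disk convention),
#' appending a final `taxonomy` column when lineages are present.
#' [read_otu_table()] inverts the output exactly, so write-then-read is the
#' identity.
#'
#' @param table an [otu_table]
#' @param path destination file path
#' @return the path, invisibly
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  counts <- t(table$counts)   # OTUs as rows on disk
  ids <- c(rownames(counts), colnames(counts))
  if (any(grepl("\t", ids, fixed = TRUE)))
    stop("identifiers containing tabs cannot be written")
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) {
    tax <- table$taxonomy[rownames(counts)]
    tax[is.na(tax)] <- ""
    df$taxonomy <- tax
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Read a sample-metadata table
#'
#' TSV with a header that must include a `sample_id` column; every other
#' column is preserved verbatim as character (typical grouping columns:
#' `population`, `variety`, `location`).
#'
#' @param path path to the metadata TSV
#' @return data.frame keyed by sample id (row names), all columns character
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "")
  if (!"sample_id" %in% colnames(df))
    stop("metadata file ", path, " lacks required column 'sample_id'")
  if (ncol(df) < 2L)
    stop("metadata file ", path, " needs at least one grouping column")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in ", path, ": ",
         df$sample_id[duplicated(df$sample_id)][1L])
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  df
}

#' Write a sample-metadata table
#'
#' Inverse of [read_metadata()]: writes row names back as a leading
#' `sample_id` column.
#'
#' @param metadata data.frame keyed by sample id
#' @param path destination file path
#' @return the path, invisibly
#' @export
write_metadata <- function(metadata, path) {
  df <- data.frame(sample_id = rownames(metadata), metadata,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
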