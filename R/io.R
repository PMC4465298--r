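#' Read a count matrix from TSV or CSV
#'
#' Expects transcripts in rows with ids in the first column and a header of
#' sample ids.  The delimiter is taken from the file extension (`.csv` =
#' comma, otherwise tab) unless forced via `dialect`.  Entries must be
#' nonnegative integers; violations are reported with their coordinates.
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"tsv"` or `"csv"`.
#' @return A validated transcripts-by-samples integer matrix.
#' @export
read_count_matrix <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto")
    dialect <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("expected an id column plus >= 1 sample column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(col) | col < 0 | col != floor(col))
    if (length(bad))
      stop("invalid count at row '", ids[bad[1L]], "', column '",
           colnames(vals)[j], "': ", vals[[j]][bad[1L]])
    vals[[j]] <- col
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  check_count_matrix(m)
}

#' Write a count matrix as TSV or CSV
#'
#' Inverse of [read_count_matrix()]: transcript ids in the first column
#' (named `transcript_id`), sample ids as the header.
#'
#' @param counts transcripts-by-samples matrix.
#' @param path output path; extension `.csv` selects comma separation.
#' @export
write_count_matrix <- function(counts, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample-to-group design table
#'
#' @param path TSV/CSV with columns `sample_id` and `group`; exactly two
#'   distinct group labels are required (the first label in sorted order
#'   becomes group A).
#' @return A [de_design()].
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("design file needs columns: sample_id, group")
  groups <- sort(unique(as.character(df[[2L]])))
  if (length(groups) != 2L)
    stop("design must contain exactly two groups, found: ",
         paste(groups, collapse = ", "))
  de_design(df[[1L]][df[[2L]] == groups[1L]],
            df[[1L]][df[[2L]] == groups[2L]])
}

#' Write a DE result table as TSV
#'
#' Columns: transcript_id, t_stat, p_value, p_adjusted, significant.
#'
#' @param result a `"degps_result"` (or its `table`).
#' @param path output path.
#' @export
write_de_result <- function(result, path) {
  tab <- if (inherits(result, "degps_result")) result$table else result
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' Accepts simple TOML/YAML-flavoured flat files: one `key = value` or
#' `key: value` per line, `#` comments, blank lines ignored.  Values are
#' type-converted (numbers, logicals, comma-separated vectors).  Files
#' ending in `.json` are parsed with jsonlite instead when available.
#'
#' @param path config file path.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (tolower(tools::file_ext(path)) == "json" &&
      requireNamespace("jsonlite", quietly = TRUE))
    return(jsonlite::fromJSON(path, simplifyVector = TRUE))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*[=:]\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: '", ln, "'")
    val <- trimws(m[3L])
    val <- gsub('^"|"$', "", val)
    parts <- trimws(strsplit(val, ",")[[1L]])
    out[[m[2L]]] <- utils::type.convert(parts, as.is = TRUE)
  }
  out
}
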