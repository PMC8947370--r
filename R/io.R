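# Reading and writing joint distributions and decomposition reports.
#
# TSV dialect: a header line naming the variables plus a final `p` column;
# one row per support point; outcome tokens are arbitrary strings; the
# probability is a decimal or a rational `a/b`. The last variable column
# is the target. JSON form: {"variables": [...], "table": [[outcomes..., p], ...]}.

parse_prob_token <- function(tok) {
  tok <- trimws(tok)
  frac <- grepl("^[-+]?[0-9]+\\s*/\\s*[0-9]+$", tok)
  out <- numeric(length(tok))
  out[frac] <- vapply(strsplit(tok[frac], "/"), function(ab)
    as.numeric(ab[1]) / as.numeric(ab[2]), 1.0)
  out[!frac] <- suppressWarnings(as.numeric(tok[!frac]))
  if (anyNA(out))
    pid_stop("pid_io_error",
             paste("unparseable probability token:", tok[which(is.na(out))[1]]))
  out
}

#' Read a joint distribution from TSV or JSON
#'
#' @param path File path. Files ending in `.json` are parsed as the JSON
#'   form; anything else as the TSV dialect (tab-separated, header with
#'   variable names and a final `p` column, probabilities decimal or
#'   rational `a/b`).
#' @return A validated `pid_dist`.
#' @export
read_distribution <- function(path) {
  if (!file.exists(path)) pid_stop("pid_io_error", paste("no such file:", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::fromJSON(path, simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
    if (is.null(j$variables) || is.null(j$table))
      pid_stop("pid_io_error", "JSON distribution needs 'variables' and 'table'")
    nv <- length(j$variables)
    rows <- lapply(j$table, function(r) {
      if (length(r) != nv + 1)
        pid_stop("pid_io_error", "JSON table row has wrong length")
      r
    })
    tab <- as.data.frame(do.call(rbind, lapply(rows, function(r)
      as.character(unlist(r)))), stringsAsFactors = FALSE)
    names(tab) <- c(unlist(j$variables), "p")
    tab$p <- parse_prob_token(tab$p)
    return(joint_dist(tab))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) pid_stop("pid_io_error", "TSV file needs a header and at least one row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (tolower(header[length(header)]) != "p")
    pid_stop("pid_io_error", "TSV header must end with a 'p' column")
  nv <- length(header) - 1
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(vapply(cells, length, 1L) != nv + 1)
  if (length(bad))
    pid_stop("pid_io_error", sprintf("malformed TSV row at line %d", bad[1] + 1L))
  tab <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(tab) <- header
  tab$p <- parse_prob_token(tab$p)
  joint_dist(tab)
}

#' Write a joint distribution
#'
#' @param dist A `pid_dist`.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- as.data.frame(dist)
  if (format == "tsv") {
    tab$p <- format(tab$p, digits = 17, scientific = FALSE, trim = TRUE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    obj <- list(variables = dist$vars,
                table = lapply(seq_len(nrow(tab)), function(r)
                  c(as.list(tab[r, dist$vars]), tab$p[r])))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Serialize a decomposition report to JSON
#'
#' Values are rounded to `precision` decimals for display; internal
#' computations are never rounded.
#'
#' @param report A `pid_decomposition` (or any list of named numeric
#'   results).
#' @param path Output path; `NULL` returns the JSON string.
#' @param precision Decimal digits kept (default 6, matching the
#'   benchmark tables' precision; use `NA` for full precision).
#' @return The path (or JSON string when `path` is `NULL`), invisibly.
#' @export
write_report <- function(report, path = NULL, precision = 6) {
  rnd <- function(x) {
    if (is.numeric(x) && !is.na(precision)) round(x, precision) else x
  }
  deep <- function(x) if (is.list(x)) lapply(x, deep) else rnd(x)
  obj <- deep(unclass(report))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
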