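#' Tabular report with provenance header
#'
#' A data.frame carrying a provenance attribute (tool version, parameter
#' hash, analysis window) that survives CSV/JSON round trips. All numeric
#' outputs of the package travel through this carrier.
#'
#' @param df data.frame of results.
#' @param params list of parameters that produced the values (hashed into the
#'   header).
#' @param window an `analysis_window` or NULL.
#' @return `df` with class `tabular_report` and attribute `provenance`.
#' @export
tabular_report <- function(df, params = list(), window = NULL) {
  stopifnot(is.data.frame(df))
  prov <- list(
    tool = paste0("aptanet ", as.character(utils::packageVersion("aptanet"))),
    config_hash = param_hash(params),
    window = if (is.null(window)) "all" else
      sprintf("[%d,%d)", window$start, window$end)
  )
  structure(df, class = c("tabular_report", class(df)), provenance = prov)
}

# order-stable polynomial rolling hash over deparsed parameters
param_hash <- function(params) {
  s <- paste(deparse(params[order(names2(params))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) rep("", length(x)) else nm
}

#' Write a tabular report (CSV or JSON dialect)
#'
#' CSV carries the provenance as `#`-prefixed header lines before the column
#' header; JSON as a `provenance` object beside `data`. [read_report()]
#' inverts either dialect exactly (floats to full precision).
#'
#' @param report a [tabular_report()].
#' @param path output path; dialect from extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  prov <- attr(report, "provenance")
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(report)
  if (ext == "json") {
    jsonlite::write_json(list(provenance = prov, data = df), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (k in names(prov))
      writeLines(sprintf("# %s: %s", k, prov[[k]]), con)
    utils::write.csv(format_full(df), con, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

# full-precision decimal rendering so read-back is <=1e-9 relative
format_full <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Read back a tabular report written by [write_report()]
#' @param path file written by [write_report()].
#' @return a `tabular_report`.
#' @export
read_report <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(x$data)
    prov <- x$provenance
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    hdr <- grep("^# ", lines)
    prov <- list()
    for (i in hdr) {
      kv <- sub("^# ([^:]+): (.*)$", "\\1\n\\2", lines[i])
      kv <- strsplit(kv, "\n")[[1L]]
      prov[[kv[1L]]] <- if (length(kv) > 1L) kv[2L] else ""
    }
    body <- lines[setdiff(seq_along(lines), hdr)]
    df <- utils::read.csv(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(df) == 0L) df <- df[0, , drop = FALSE]
  }
  structure(df, class = c("tabular_report", class(df)), provenance = prov)
}
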