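#' @keywords internal
"_PACKAGE"

# Canonical morph order used everywhere counts are reported.
MORPHS <- c("O", "Y", "OY", "G")

SEXES <- c("male", "female", "unknown")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a flat key-value configuration file
#'
#' Parses a minimal YAML-like format: one `key: value` pair per line,
#' `#` comments and blank lines ignored. Values are returned as character
#' strings; callers coerce as needed. Used by the command-line interface and
#' by [read_pedigree()] for column aliases.
#'
#' @param path Path to the configuration file.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln, call. = FALSE)
    out[[m[2]]] <- trimws(m[3])
  }
  out
}

# Consistent error with row/field context for table validation.
ped_error <- function(msg, ids = NULL) {
  if (!is.null(ids) && length(ids)) {
    msg <- paste0(msg, " [ids: ", paste(utils::head(ids, 10), collapse = ", "),
                  if (length(ids) > 10) ", ..." else "", "]")
  }
  stop(msg, call. = FALSE)
}
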