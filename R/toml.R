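# Minimal TOML subset reader/writer for run configurations: tables
# ([a.b]), arrays of tables ([[a]]), bare keys, strings, numbers,
# booleans, flat arrays and # comments.  This covers the configuration
# grammar the package emits; it is not a general TOML implementation.

toml_parse_value <- function(txt, line) {
  txt <- trimws(txt)
  if (txt == "") stop("empty value on line ", line)
  if (startsWith(txt, "[")) {
    if (!endsWith(txt, "]")) stop("unterminated array on line ", line)
    inner <- trimws(substr(txt, 2, nchar(txt) - 1))
    if (inner == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    vals <- lapply(parts, toml_parse_value, line = line)
    return(unlist(vals, use.names = FALSE))
  }
  if (startsWith(txt, "\"")) {
    if (!endsWith(txt, "\"") || nchar(txt) < 2)
      stop("unterminated string on line ", line)
    return(substr(txt, 2, nchar(txt) - 1))
  }
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(txt))
  if (is.na(num)) stop("cannot parse value '", txt, "' on line ", line)
  num
}

strip_comment <- function(ln) {
  # drop a # comment not inside a string
  instr <- FALSE
  chars <- strsplit(ln, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "\"") instr <- !instr
    if (chars[i] == "#" && !instr) return(substr(ln, 1, i - 1))
  }
  ln
}

# path helpers handling mixed character/integer keys
toml_get <- function(root, keys) {
  for (k in keys) {
    if (is.null(root)) return(NULL)
    root <- if (is.numeric(k)) root[[k]] else root[[as.character(k)]]
  }
  root
}

toml_set <- function(root, keys, val) {
  if (length(keys) == 1) {
    k <- keys[[1]]
    if (is.numeric(k)) root[[k]] <- val else root[[as.character(k)]] <- val
    return(root)
  }
  k <- keys[[1]]
  sub <- if (is.numeric(k)) root[[k]] else root[[as.character(k)]]
  if (is.null(sub)) sub <- list()
  sub <- toml_set(sub, keys[-1], val)
  if (is.numeric(k)) root[[k]] <- sub else root[[as.character(k)]] <- sub
  root
}

#' Read a TOML configuration file
#'
#' Supports the subset used by the package configuration: `[table]`,
#' `[table.sub]`, `[[array-of-tables]]`, `key = value` with strings,
#' numbers, booleans and flat arrays, and `#` comments.
#'
#' @param path input path.
#' @return nested named list.
#' @export
read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  root <- list()
  cursor <- list() # current table path (mixed character/integer keys)
  for (li in seq_along(lines)) {
    ln <- trimws(strip_comment(lines[li]))
    if (ln == "") next
    if (grepl("^\\[\\[.*\\]\\]$", ln)) {
      name <- trimws(substr(ln, 3, nchar(ln) - 2))
      parts <- as.list(strsplit(name, ".", fixed = TRUE)[[1]])
      existing <- toml_get(root, parts)
      if (is.null(existing)) existing <- list()
      root <- toml_set(root, parts, c(existing, list(list())))
      cursor <- c(parts, list(length(existing) + 1L))
    } else if (grepl("^\\[.*\\]$", ln)) {
      name <- trimws(substr(ln, 2, nchar(ln) - 1))
      cursor <- as.list(strsplit(name, ".", fixed = TRUE)[[1]])
      if (is.null(toml_get(root, cursor)))
        root <- toml_set(root, cursor, list())
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      key <- gsub("^\"|\"$", "", key)
      val <- toml_parse_value(substr(ln, eq + 1, nchar(ln)), li)
      root <- toml_set(root, c(cursor, list(key)), val)
    } else {
      stop("cannot parse TOML line ", li, ": ", ln)
    }
  }
  root
}

toml_format_value <- function(v) {
  if (is.character(v) && length(v) == 1) return(sprintf("\"%s\"", v))
  if (is.logical(v) && length(v) == 1) return(if (v) "true" else "false")
  fmt1 <- function(x) {
    if (is.numeric(x) && x == round(x) && abs(x) < 1e15)
      sprintf("%.1f", x) else format(x, digits = 17)
  }
  if (is.numeric(v) && length(v) == 1) {
    if (v == round(v) && abs(v) < 1e15 && is.integer(v))
      return(format(v))
    return(format(v, digits = 17))
  }
  paste0("[", paste(vapply(v, function(x) toml_format_value(x),
                           character(1)), collapse = ", "), "]")
}

#' Write a nested list as TOML
#'
#' Inverse of [read_toml()] on its supported subset; `parse -> serialize
#' -> parse` is a fixed point.
#'
#' @param x nested named list.
#' @param path output path.
#' @export
write_toml <- function(x, path) {
  out <- character(0)
  emit_table <- function(tbl, prefix) {
    scalars <- names(tbl)[!vapply(tbl, function(v)
      is.list(v), logical(1))]
    for (k in scalars)
      out <<- c(out, paste0(k, " = ", toml_format_value(tbl[[k]])))
    for (k in setdiff(names(tbl), scalars)) {
      sub <- tbl[[k]]
      full <- if (prefix == "") k else paste0(prefix, ".", k)
      if (length(sub) && is.null(names(sub))) {
        # array of tables
        for (el in sub) {
          out <<- c(out, "", paste0("[[", full, "]]"))
          emit_table(el, full)
        }
      } else {
        out <<- c(out, "", paste0("[", full, "]"))
        emit_table(sub, full)
      }
    }
  }
  emit_table(x, "")
  writeLines(out, path)
  invisible(path)
}
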