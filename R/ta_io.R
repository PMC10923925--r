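# Plain-text TSV serialization. One dialect only: UTF-8, LF endings, decimal
# points, OD units, wavelength in nm and delay in ps. Full "%.17g" precision
# so a write -> read round trip is bit exact. Writers prepend "# key=value"
# provenance comments; readers skip any line starting with "#".

fmt_num <- function(x) sprintf("%.17g", x)

provenance_lines <- function(meta) {
  meta <- c(tool = paste0("tadecomp ", as.character(utils::packageVersion("tadecomp"))),
            meta)
  paste0("# ", names(meta), "=", unname(meta))
}

# strict numeric parser: refuses decimal commas and anything non-numeric
parse_cell <- function(token, where) {
  if (grepl(",", token, fixed = TRUE))
    stop(sprintf("decimal comma in %s: '%s' (files must use '.' decimals)",
                 where, token))
  val <- suppressWarnings(as.numeric(token))
  if (is.na(val))
    stop(sprintf("non-numeric or NaN cell in %s: '%s'", where, token))
  val
}

read_tsv_body <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("file contains no data rows: ", path)
  strsplit(lines, "\t", fixed = TRUE)
}

#' Write / read a TA map as TSV
#'
#' Layout: corner cell `delay_ps\\wavelength_nm`, first row the wavelength
#' axis, first column the delay axis, body the dOD matrix in OD units.
#'
#' @param map A [ta_map()].
#' @param path Output file.
#' @param meta Named character vector of extra provenance `# key=value` lines
#'   (e.g. seed, generating command).
#' @return `write_tamap` returns `path` invisibly; `read_tamap` a [ta_map()].
#' @export
write_tamap <- function(map, path, meta = character()) {
  stopifnot(inherits(map, "ta_map"))
  header <- paste(c("delay_ps\\wavelength_nm", fmt_num(map$wavelength)),
                  collapse = "\t")
  rows <- vapply(seq_along(map$delay), function(i)
    paste(c(fmt_num(map$delay[i]), fmt_num(map$dod[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(provenance_lines(meta), header, rows), path, sep = "\n",
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tamap
#' @export
read_tamap <- function(path) {
  toks <- read_tsv_body(path)
  header <- toks[[1]]
  if (header[1] != "delay_ps\\wavelength_nm")
    stop("TA map header corner must be 'delay_ps\\wavelength_nm', got '",
         header[1], "'")
  wl <- vapply(seq_along(header[-1]), function(j)
    parse_cell(header[-1][j], sprintf("wavelength header column %d", j)), 0)
  if (any(diff(wl) <= 0))
    stop("wavelength axis in file is not strictly ascending")
  body <- toks[-1]
  if (length(body) == 0) stop("TA map file has no delay rows")
  ncol_expect <- length(wl) + 1L
  dod <- matrix(0, length(body), length(wl))
  delays <- numeric(length(body))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol_expect)
      stop(sprintf("ragged row %d: expected %d cells, found %d",
                   i, ncol_expect, length(row)))
    delays[i] <- parse_cell(row[1], sprintf("delay column, row %d", i))
    for (j in seq_along(wl))
      dod[i, j] <- parse_cell(row[j + 1L],
                              sprintf("row %d, column %d", i, j))
  }
  if (any(diff(delays) <= 0))
    stop("delay axis in file is not strictly ascending")
  ta_map(wl, delays, dod)
}

write_two_column <- function(x_vals, y_vals, headers, path, meta) {
  rows <- paste(fmt_num(x_vals), fmt_num(y_vals), sep = "\t")
  writeLines(c(provenance_lines(meta), paste(headers, collapse = "\t"), rows),
             path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_two_column <- function(path, headers) {
  toks <- read_tsv_body(path)
  if (!identical(toks[[1]], headers))
    stop(sprintf("expected header '%s', got '%s'",
                 paste(headers, collapse = "\t"),
                 paste(toks[[1]], collapse = "\t")))
  body <- toks[-1]
  if (length(body) == 0) stop("no data rows in ", path)
  x <- numeric(length(body)); y <- numeric(length(body))
  for (i in seq_along(body)) {
    if (length(body[[i]]) != 2L)
      stop(sprintf("ragged row %d: expected 2 cells, found %d",
                   i, length(body[[i]])))
    x[i] <- parse_cell(body[[i]][1], sprintf("row %d, column 1", i))
    y[i] <- parse_cell(body[[i]][2], sprintf("row %d, column 2", i))
  }
  list(x = x, y = y)
}

#' Write / read spectra and traces as two-column TSV
#'
#' Spectra use header `wavelength_nm` / `od`; traces `delay_ps` / `dod`.
#'
#' @param spec A [ta_spectrum()]; `trace` a [ta_trace()].
#' @param trace A [ta_trace()].
#' @param path File path.
#' @param meta Named character vector of provenance lines.
#' @return Readers return the reconstructed object; writers `path` invisibly.
#' @export
write_spectrum <- function(spec, path, meta = character()) {
  stopifnot(inherits(spec, "ta_spectrum"))
  write_two_column(spec$wavelength, spec$od, c("wavelength_nm", "od"), path, meta)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- read_two_column(path, c("wavelength_nm", "od"))
  if (any(diff(d$x) <= 0))
    stop("wavelength axis in file is not strictly ascending")
  ta_spectrum(d$x, d$y)
}

#' @rdname write_spectrum
#' @export
write_trace <- function(trace, path, meta = character()) {
  stopifnot(inherits(trace, "ta_trace"))
  if (is.finite(trace$center))
    meta <- c(meta, probe_center_nm = fmt_num(trace$center),
              probe_bandwidth_nm = fmt_num(trace$bandwidth))
  write_two_column(trace$delay, trace$dod, c("delay_ps", "dod"), path, meta)
}

#' @rdname write_spectrum
#' @export
read_trace <- function(path) {
  d <- read_two_column(path, c("delay_ps", "dod"))
  if (any(diff(d$x) <= 0))
    stop("delay axis in file is not strictly ascending")
  meta <- read_meta(path)
  ta_trace(d$x, d$y,
           center = if ("probe_center_nm" %in% names(meta))
             as.numeric(meta[["probe_center_nm"]]) else NA_real_,
           bandwidth = if ("probe_bandwidth_nm" %in% names(meta))
             as.numeric(meta[["probe_bandwidth_nm"]]) else NA_real_)
}

#' Read the `# key=value` provenance comments of any tadecomp TSV file
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[startsWith(lines, "#")]
  kv <- sub("^#\\s*", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(vals, keys)
}
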