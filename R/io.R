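# tab-delimited text I/O with '#'-prefixed key: value metadata headers;
# numbers are written in scientific notation with enough digits for
# lossless (1e-12) round trips

write_header <- function(con, meta) {
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.null(v) || length(v) == 0L) next
    writeLines(paste0("# ", nm, ": ", paste(v, collapse = " ")), con)
  }
}

read_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

parse_num <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) abort_pc("malformed ", what, " at line ", lineno)
  v
}

#' Write / read a photocurrent trace
#'
#' Two columns (`time_s`, `current_pA`) after '#' header lines carrying
#' voltage_mV, e_rev_mV, conductance_scale and the light window.
#'
#' @param trace a `photocurrent_trace`.
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns the
#'   trace with its metadata attributes restored.
#' @export
write_trace <- function(trace, path) {
  meta <- trace_meta(trace)
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, list(
    voltage_mV = num_fmt(meta$voltage_mV),
    e_rev_mV = num_fmt(meta$e_rev_mV),
    conductance_scale = num_fmt(meta$conductance_scale),
    light_on_s = if (!is.null(meta$light_window)) num_fmt(meta$light_window[1]),
    light_off_s = if (!is.null(meta$light_window)) num_fmt(meta$light_window[2])))
  writeLines("time_s\tcurrent_pA", con)
  writeLines(paste(num_fmt(trace$time_s), num_fmt(trace$current_pA), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) abort_pc("empty trace file: ", path)
  meta <- read_header(lines)
  body <- which(!grepl("^#", lines))
  if (length(body) < 2L) abort_pc("trace file has no data rows: ", path)
  header_row <- lines[body[1]]
  if (!identical(strsplit(header_row, "\t")[[1]][1:2], c("time_s", "current_pA"))) {
    abort_pc("unexpected column header at line ", body[1])
  }
  rows <- lines[body[-1]]
  parts <- strsplit(rows, "\t")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) abort_pc("malformed trace row at line ", body[-1][bad[1]])
  t <- parse_num(vapply(parts, `[[`, "", 1L), "time", body[2])
  i <- parse_num(vapply(parts, `[[`, "", 2L), "current", body[2])
  lw <- if (!is.null(meta$light_on_s)) {
    c(as.numeric(meta$light_on_s), as.numeric(meta$light_off_s))
  }
  new_photocurrent_trace(tibble::tibble(time_s = t, current_pA = i),
                         voltage_mV = as.numeric(meta$voltage_mV %||% NA),
                         e_rev_mV = as.numeric(meta$e_rev_mV %||% NA),
                         conductance_scale = as.numeric(meta$conductance_scale %||% NA),
                         light_window = lw)
}

#' Write / read a time-resolved spectral matrix
#'
#' The first non-comment row holds the axis-kind tag in cell (0,0) followed
#' by the times (s); each following row is an axis value and one delta-A per
#' time. Excluded ranges are stored as '# excluded: lo-hi' header lines.
#'
#' @param data a [time_resolved_spectra()].
#' @param path file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` the object.
#' @export
write_matrix <- function(data, path) {
  con <- file(path, "w"); on.exit(close(con))
  meta <- data$metadata
  keep <- vapply(meta, function(v) is.character(v) || is.numeric(v), logical(1))
  write_header(con, meta[keep])
  for (r in data$excluded_ranges %||% list()) {
    writeLines(paste0("# excluded: ", num_fmt(r[1]), "-", num_fmt(r[2])), con)
  }
  tag <- if (data$axis_kind == "wavelength") "wavelength_nm" else "wavenumber_cm"
  writeLines(paste(c(tag, num_fmt(data$times)), collapse = "\t"), con)
  for (i in seq_along(data$axis_values)) {
    writeLines(paste(c(num_fmt(data$axis_values[i]), num_fmt(data$delta_A[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) abort_pc("empty matrix file: ", path)
  excl <- lapply(grep("^#\\s*excluded:", lines, value = TRUE), function(h) {
    v <- sub("^#\\s*excluded:\\s*", "", h)
    parts <- strsplit(v, "(?<=[0-9])-(?=[0-9+-])", perl = TRUE)[[1]]
    as.numeric(parts)
  })
  body <- which(!grepl("^#", lines))
  if (length(body) < 2L) abort_pc("matrix file has no data rows: ", path)
  head_parts <- strsplit(lines[body[1]], "\t")[[1]]
  axis_kind <- switch(head_parts[1],
                      wavelength_nm = "wavelength",
                      wavenumber_cm = "wavenumber",
                      abort_pc("unknown axis tag '", head_parts[1], "' at line ", body[1]))
  times <- parse_num(head_parts[-1], "time header", body[1])
  rows <- strsplit(lines[body[-1]], "\t")
  bad <- which(lengths(rows) != length(times) + 1L)
  if (length(bad)) abort_pc("malformed matrix row at line ", body[-1][bad[1]])
  axis_values <- parse_num(vapply(rows, `[[`, "", 1L), "axis value", body[2])
  M <- t(vapply(rows, function(r) parse_num(r[-1], "delta_A row", NA), numeric(length(times))))
  time_resolved_spectra(axis_values, times, M, axis_kind = axis_kind,
                        excluded_ranges = if (length(excl)) excl else NULL,
                        metadata = read_header(lines))
}

#' Write / read a generic two-column series
#'
#' Used for IV series (`voltage_mV`, `current_pA`), recovery series
#' (`interval_s`, `peak_ratio`), titrations (`pH`, `amplitude`), action
#' spectra and steady-state spectra. Column names are preserved in the file
#' and restored on read.
#'
#' @param series two-column data frame.
#' @param path file path.
#' @param meta optional named list written as '#' headers.
#' @return `write_series` returns `path` invisibly; `read_series` a tibble
#'   with the file's metadata as attribute `meta`.
#' @export
write_series <- function(series, path, meta = list()) {
  stopifnot(ncol(series) == 2L)
  con <- file(path, "w"); on.exit(close(con))
  write_header(con, meta)
  writeLines(paste(names(series), collapse = "\t"), con)
  writeLines(paste(num_fmt(series[[1]]), num_fmt(series[[2]]), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) abort_pc("empty series file: ", path)
  body <- which(!grepl("^#", lines))
  if (length(body) < 2L) abort_pc("series file has no data rows: ", path)
  cols <- strsplit(lines[body[1]], "\t")[[1]]
  if (length(cols) != 2L) abort_pc("expected two columns at line ", body[1])
  rows <- strsplit(lines[body[-1]], "\t")
  bad <- which(lengths(rows) != 2L)
  if (length(bad)) abort_pc("malformed series row at line ", body[-1][bad[1]])
  out <- tibble::tibble(parse_num(vapply(rows, `[[`, "", 1L), cols[1], body[2]),
                        parse_num(vapply(rows, `[[`, "", 2L), cols[2], body[2]))
  names(out) <- cols
  attr(out, "meta") <- read_header(lines)
  out
}

#' Read an ionic solution recipe
#'
#' Lines of `species<TAB>mM` after optional '#' headers (`pH`,
#' `temperature_C`); resolved against the shared dissociation and mobility
#' tables via [solution_composition()].
#'
#' @param path file path.
#' @param pH,temperature_C overrides for values not present in the header.
#' @return a [solution_composition()].
#' @export
read_solution <- function(path, pH = NULL, temperature_C = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) abort_pc("empty solution file: ", path)
  meta <- read_header(lines)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  rows <- strsplit(lines[body], "\t")
  bad <- which(lengths(rows) != 2L)
  if (length(bad)) abort_pc("malformed solution row at line ", body[bad[1]])
  comp <- tibble::tibble(species = vapply(rows, `[[`, "", 1L),
                         mM = parse_num(vapply(rows, `[[`, "", 2L), "mM", body[1]))
  pH <- pH %||% as.numeric(meta$pH %||% NA)
  if (is.na(pH)) abort_pc("solution pH missing (header or argument)")
  temperature_C <- temperature_C %||% as.numeric(meta$temperature_C %||% 25)
  solution_composition(comp, pH = pH, temperature_C = temperature_C)
}

#' Read a nested key-value configuration file
#'
#' YAML-based structured configuration (scheme definitions, protocols, fit
#' settings).
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_pc("config file not found: ", path)
  yaml::read_yaml(path)
}
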