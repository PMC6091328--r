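#' Plain-text configuration serialization
#'
#' Writes and reads flat `key: value` text files for the package's
#' parameter objects, so runs can be stamped with, and rebuilt from, a
#' human-readable config.  Values are written with full precision;
#' numeric-looking values are parsed back to numbers.
#'
#' @param x named list (or one of the package's parameter objects) with
#'   scalar fields
#' @param path file to write / read
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a named list with numerics parsed
#' @examples
#' f <- tempfile()
#' write_config(membrane_params(), f)
#' read_config(f)$gbar_Na
#' @export
write_config <- function(x, path) {
  x <- unclass(x)
  stopifnot(is.list(x), !is.null(names(x)), all(lengths(x) == 1))
  vals <- vapply(x, function(v)
    if (is.numeric(v)) format(v, digits = 17) else as.character(v),
    character(1))
  writeLines(paste0(names(x), ": ", vals), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  m <- regmatches(lines, regexpr(":", lines), invert = TRUE)
  keys <- trimws(vapply(m, `[`, character(1), 1))
  vals <- trimws(vapply(m, `[`, character(1), 2))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

#' Build a stimulus specification from config keys
#'
#' Maps the flat keys `stimulus.kind`, `stimulus.amplitude_mV`,
#' `stimulus.frequency_kHz`, `stimulus.sigma_mV`, `stimulus.phase_rad`
#' (as produced by [write_config()] on a named list) to a
#' [stimulus_spec()].  Missing keys take the spec defaults.
#'
#' @param conf named list, e.g. from [read_config()]
#' @return a `stimulus_spec`
#' @examples
#' stimulus_from_config(list("stimulus.kind" = "gwn",
#'                           "stimulus.sigma_mV" = 10))
#' @export
stimulus_from_config <- function(conf) {
  pick <- function(key, default) {
    if (!is.null(conf[[key]])) conf[[key]] else default
  }
  stimulus_spec(kind = as.character(pick("stimulus.kind", "none")),
                A = as.numeric(pick("stimulus.amplitude_mV", 0)),
                f = as.numeric(pick("stimulus.frequency_kHz", 25)),
                sigma_N = as.numeric(pick("stimulus.sigma_mV", 0)),
                phase = as.numeric(pick("stimulus.phase_rad", 0)))
}
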