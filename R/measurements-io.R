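#' Read / write measurement sets as CSV
#'
#' Columns `flow_Lmin` and `dp_cmH2O` (plus any extras); the restrictor
#' diameter travels in a `#`-prefixed header comment so a file is
#' self-describing.
#'
#' @param data A measurement tibble (e.g. from [gen_bench_measurements()]).
#' @param path File path.
#' @return `path` (write) or a tibble with attribute `diameter` (read).
#' @export
write_measurements_csv <- function(data, path) {
  d <- attr(data, "diameter") %||% NA_real_
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# diameter_mm: %s",
                     if (is.na(d)) "NA" else format(d)), con)
  utils::write.csv(as.data.frame(data), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  hdr <- readLines(path, n = 5)
  dline <- grep("^#\\s*diameter_mm:", hdr, value = TRUE)
  d <- if (length(dline) == 1L) {
    suppressWarnings(as.numeric(sub(".*:", "", dline)))
  } else {
    NA_real_
  }
  dat <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  if (!all(c("flow_Lmin", "dp_cmH2O") %in% names(dat))) {
    stop_config("path", "CSV needs columns `flow_Lmin` and `dp_cmH2O`")
  }
  attr(dat, "diameter") <- d
  dat
}

#' Serialize a power-law model to JSON
#'
#' @param model A [powerlaw_model()].
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly (or the JSON string).
#' @export
write_powerlaw_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "powerlaw_model"))
  x <- list(
    k_a_cmH2O_per_Lmin2 = model$k_a, m_a = model$m_a,
    k_b_cmH2O_per_Lmin = model$k_b, m_b = model$m_b
  )
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
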