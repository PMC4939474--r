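#' Read and write FCS curves
#'
#' Curves are stored as a two-column CSV (`lag_s`, `g`) with full
#' double-precision (17 significant digits), plus an optional JSON sidecar
#' `<path>.meta.json` carrying the curve metadata (`sample_id`, `ph`,
#' `buffer_name`, `buffer_conc_M`, `mean_intensity_cps`). A write/read round
#' trip reproduces the curve exactly.
#'
#' @param curve A curve tibble with columns `lag`, `g` and optional metadata
#'   columns (`curve_id`, `sample_id`, `ph`, `buffer_name`, `buffer_conc`,
#'   `mean_intensity`).
#' @param path CSV file path.
#' @return `read_fcs_curve()` returns a curve tibble; a missing sidecar gives
#'   empty metadata with a warning. `write_fcs_curve()` returns `path`
#'   invisibly.
#' @export
write_fcs_curve <- function(curve, path) {
  curve <- tibble::as_tibble(curve)
  stopifnot(all(c("lag", "g") %in% names(curve)))
  lines <- c("lag_s,g",
             paste(sprintf("%.17g", curve$lag), sprintf("%.17g", curve$g),
                   sep = ","))
  writeLines(lines, path)
  meta_cols <- intersect(c("curve_id", "sample_id", "ph", "buffer_name",
                           "buffer_conc", "mean_intensity"), names(curve))
  if (length(meta_cols) > 0) {
    meta <- as.list(curve[1, meta_cols])
    names(meta)[names(meta) == "buffer_conc"] <- "buffer_conc_M"
    names(meta)[names(meta) == "mean_intensity"] <- "mean_intensity_cps"
    jsonlite::write_json(meta, sidecar_path(path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_fcs_curve
#' @export
read_fcs_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1 || !identical(trimws(lines[1]), "lag_s,g")) {
    stop("missing `lag_s,g` header in ", path, call. = FALSE)
  }
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2)
  if (length(bad) > 0) {
    stop("malformed row(s) at line(s) ", paste(bad + 1, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  lag <- as.numeric(vapply(parts, `[[`, "", 1))
  g <- as.numeric(vapply(parts, `[[`, "", 2))
  nn <- which(!is.finite(lag) | !is.finite(g))
  if (length(nn) > 0) {
    stop("non-numeric or non-finite value(s) at line(s) ",
         paste(nn + 1, collapse = ", "), " in ", path, call. = FALSE)
  }
  if (length(lag) > 1 && any(diff(lag) <= 0)) {
    stop("lag times are not strictly increasing in ", path, call. = FALSE)
  }
  out <- tibble::tibble(lag = lag, g = g)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    names(meta)[names(meta) == "buffer_conc_M"] <- "buffer_conc"
    names(meta)[names(meta) == "mean_intensity_cps"] <- "mean_intensity"
    for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  } else {
    warning("no metadata sidecar for ", path, "; curve loaded without metadata",
            call. = FALSE)
  }
  out
}

sidecar_path <- function(path) paste0(path, ".meta.json")
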