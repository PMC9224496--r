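## File-format contracts shared by the modules: long-format CSV for OD
## series (time_s, wavelength_nm, od) with a JSON dosimetry sidecar,
## YAML/JSON reaction schemes, CSV yield profiles and peak lists. UTF-8,
## comma separators, '.' decimal throughout.

SCHEMA_VERSION <- "1"

#' Read and write transient series
#'
#' Long CSV with header `time_s,wavelength_nm,od` plus a JSON sidecar holding
#' `dose_gy`, `path_cm` (and optionally `density`, `seed`).
#'
#' @param series A [transient_series()].
#' @param path CSV path; the sidecar is `<path>.json` unless given.
#' @param meta_path Sidecar JSON path.
#' @param extra Extra named fields for the sidecar (e.g. the seed).
#' @return `read_series()` a [transient_series()]; `write_series()` the CSV
#'   path, invisibly.
#' @name series_io
NULL

#' @rdname series_io
#' @export
write_series <- function(series, path,
                         meta_path = paste0(path, ".json"), extra = list()) {
  stopifnot(inherits(series, "transient_series"))
  long <- data.frame(
    time_s = rep(series$times, each = length(series$grid)),
    wavelength_nm = rep(series$grid, times = length(series$times)),
    od = as.vector(t(series$od)))
  utils::write.csv(long, path, row.names = FALSE)
  meta <- c(list(schema_version = SCHEMA_VERSION, dose_gy = series$dose,
                 path_cm = series$path, density = series$density), extra)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname series_io
#' @export
read_series <- function(path, meta_path = paste0(path, ".json")) {
  long <- utils::read.csv(path)
  stopifnot(all(c("time_s", "wavelength_nm", "od") %in% names(long)))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  times <- sort(unique(long$time_s))
  grid <- sort(unique(long$wavelength_nm))
  od <- matrix(NA_real_, length(times), length(grid))
  od[cbind(match(long$time_s, times), match(long$wavelength_nm, grid))] <-
    long$od
  if (anyNA(od)) stop("read_series: incomplete time/wavelength grid",
                      call. = FALSE)
  transient_series(grid, times, od, dose = meta$dose_gy, path = meta$path_cm,
                   density = if (is.null(meta$density)) 1.0 else meta$density)
}

#' Read and write yield profiles
#'
#' Wide CSV: first column `time_s`, one column per species, G in umol J^-1.
#'
#' @param profile A `"yield_profile"` or `"yield_fit"`.
#' @param path CSV path.
#' @return `read_profile()` a `"yield_profile"`; `write_profile()` the path,
#'   invisibly.
#' @name profile_io
NULL

#' @rdname profile_io
#' @export
write_profile <- function(profile, path) {
  g <- if (inherits(profile, "yield_fit")) coef(profile) else profile$g
  out <- data.frame(time_s = profile$times, g, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname profile_io
#' @export
read_profile <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  stopifnot(names(tab)[1] == "time_s")
  yield_profile(tab$time_s, as.matrix(tab[, -1, drop = FALSE]))
}

#' Read and write reaction schemes
#'
#' YAML (or JSON) document with keys `species`, `fixed`, `initial` (named
#' map, M) and `reactions` (list of `{reactants, products, k, label}`).
#'
#' @param scheme A [reaction_scheme()].
#' @param path File path; `.json` selects JSON, anything else YAML.
#' @return `read_scheme()` a [reaction_scheme()]; `write_scheme()` the path,
#'   invisibly.
#' @name scheme_io
NULL

#' @rdname scheme_io
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "reaction_scheme"))
  doc <- list(schema_version = SCHEMA_VERSION,
              species = scheme$species,
              fixed = scheme$fixed,
              initial = as.list(scheme$initial[scheme$initial > 0]),
              reactions = lapply(scheme$reactions, function(r) {
                list(reactants = r$reactants, products = r$products,
                     k = r$k, label = r$label)
              }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' @rdname scheme_io
#' @export
read_scheme <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rx <- lapply(doc$reactions, function(r) {
    reaction(unlist(r$reactants), unlist(r$products), r$k,
             if (is.null(r$label)) "" else r$label)
  })
  reaction_scheme(unlist(doc$species), rx,
                  initial = unlist(doc$initial),
                  fixed = if (is.null(doc$fixed)) character()
                          else unlist(doc$fixed))
}

#' Read an LC-MS peak list
#'
#' CSV with header `mz,intensity` (extra columns preserved).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_peaklist <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("mz", "intensity") %in% names(tab))) {
    stop("read_peaklist: need columns mz,intensity", call. = FALSE)
  }
  tab
}
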