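#' @keywords internal
"_PACKAGE"

## Transient species resolved in the spectral analysis.  aS pools the two
## alpha-(alkylthio)alkyl isomers: their reference spectra are not
## distinguishable, so the library carries a single entry.
SPECIES_IDS <- c("HOS", "aC1", "aC2", "aS", "SS", "SN", "SO")

#' Absorption band of a transient species
#'
#' A single Gaussian-in-wavelength absorption band, parameterised by its
#' position, peak molar absorption coefficient and full width at half maximum.
#'
#' @param lambda_max Band centre, nm (> 0).
#' @param eps_max Molar absorption coefficient at the centre, M^-1 cm^-1 (>= 0).
#' @param fwhm Full width at half maximum, nm (> 0). Default 70 nm, typical of
#'   the broad visible bands of sulfur-centred radicals.
#' @return An object of class `"band"`.
#' @export
band <- function(lambda_max, eps_max, fwhm = 70) {
  stopifnot(is.numeric(lambda_max), is.numeric(eps_max), is.numeric(fwhm))
  if (lambda_max <= 0) stop("band: lambda_max must be positive", call. = FALSE)
  if (eps_max < 0) stop("band: eps_max must be non-negative", call. = FALSE)
  if (fwhm <= 0) stop("band: fwhm must be positive", call. = FALSE)
  structure(list(lambda_max = lambda_max, eps_max = eps_max, fwhm = fwhm),
            class = "band")
}

#' Sample a band on a wavelength grid
#'
#' Evaluates the Gaussian profile
#' \deqn{\varepsilon(\lambda) = \varepsilon_{max}
#'   \exp\{-4\ln 2\,(\lambda-\lambda_{max})^2 / \mathrm{fwhm}^2\}.}
#'
#' @param band A [band()] object.
#' @param grid Numeric vector of wavelengths, nm.
#' @return Numeric vector of molar absorption coefficients, M^-1 cm^-1.
#' @export
sample_band <- function(band, grid) {
  stopifnot(inherits(band, "band"), is.numeric(grid))
  band$eps_max * exp(-4 * log(2) * (grid - band$lambda_max)^2 / band$fwhm^2)
}

#' Reference spectrum of one transient species
#'
#' Sum of one or more Gaussian bands sampled on a shared wavelength grid, or a
#' tabulated curve interpolated linearly onto the grid (zero outside the
#' tabulated range). Tabulated curves take precedence over bands.
#'
#' @param species_id One of `"HOS"`, `"aC1"`, `"aC2"`, `"aS"`, `"SS"`,
#'   `"SN"`, `"SO"`.
#' @param bands List of [band()] objects (>= 1 unless `curve` given).
#' @param grid Strictly ascending wavelengths, nm.
#' @param curve Optional data frame with columns `wavelength_nm`, `eps`.
#' @return An object of class `"reference_spectrum"` with elements
#'   `species_id`, `bands`, `grid`, `eps`.
#' @export
reference_spectrum <- function(species_id, bands = list(), grid, curve = NULL) {
  species_id <- match.arg(species_id, SPECIES_IDS)
  if (any(diff(grid) <= 0)) {
    stop("reference_spectrum: grid must be strictly ascending", call. = FALSE)
  }
  if (is.null(curve)) {
    if (length(bands) < 1) {
      stop("reference_spectrum: need at least one band or a tabulated curve",
           call. = FALSE)
    }
    eps <- Reduce(`+`, lapply(bands, sample_band, grid = grid))
  } else {
    stopifnot(all(c("wavelength_nm", "eps") %in% names(curve)))
    if (any(curve$eps < 0)) {
      stop("reference_spectrum: tabulated eps must be non-negative",
           call. = FALSE)
    }
    eps <- stats::approx(curve$wavelength_nm, curve$eps, xout = grid,
                         yleft = 0, yright = 0, rule = 2)$y
    eps[grid < min(curve$wavelength_nm) | grid > max(curve$wavelength_nm)] <- 0
    bands <- list()
  }
  structure(list(species_id = species_id, bands = bands, grid = grid,
                 eps = eps),
            class = "reference_spectrum")
}

#' Library of reference spectra on a shared grid
#'
#' @param spectra List of [reference_spectrum()] objects sharing one grid.
#' @return An object of class `"spectrum_library"`: a named list of spectra
#'   plus the shared `grid`.
#' @export
spectrum_library <- function(spectra) {
  ids <- vapply(spectra, `[[`, character(1), "species_id")
  if (anyDuplicated(ids)) {
    stop("spectrum_library: duplicate species ids", call. = FALSE)
  }
  grids <- lapply(spectra, `[[`, "grid")
  if (length(spectra) > 1 &&
      !all(vapply(grids[-1], identical, logical(1), grids[[1]]))) {
    stop("spectrum_library: all spectra must share one grid", call. = FALSE)
  }
  names(spectra) <- ids
  structure(list(entries = spectra, grid = grids[[1]]),
            class = "spectrum_library")
}

## (lambda_max, eps_max[, fwhm]) of the seven transients; two bands for aC1.
## aC2 is given a wider default band than HOS: both peak at 340 nm, and with
## identical Gaussian shapes the regression basis would be exactly singular,
## which the measured reference spectra are not.
DEFAULT_BANDS <- list(
  HOS = list(c(340, 3400)),
  aC1 = list(c(270, 6200), c(370, 1800)),
  aC2 = list(c(340, 2000, 150)),
  aS  = list(c(290, 3000)),
  SS  = list(c(480, 6880)),
  SN  = list(c(390, 4500)),
  SO  = list(c(400, 3000))
)

#' Default reference-spectrum library
#'
#' Builds the seven-species library used in the spectral resolutions: the HO*
#' sulfur adduct (HOS), the backbone and N-methyl carbon radicals (aC1, aC2),
#' the pooled alpha-(alkylthio)alkyl radical (aS), the intermolecular
#' two-centre three-electron S-S dimer radical cation (SS), and the cyclic
#' S-N and S-O three-electron species (SN, SO). Band positions and peak molar
#' absorption coefficients are the measured values; band shapes are Gaussian
#' stand-ins with a common default width.
#'
#' @param grid Strictly ascending wavelengths, nm; should cover the 270-700 nm
#'   observation window. Default `seq(270, 700, by = 2)`.
#' @param fwhm Default full width at half maximum, nm, for bands without
#'   their own width (aC2 defaults to 150 nm; see the methods vignette).
#' @return A [spectrum_library()].
#' @examples
#' lib <- default_library()
#' lib$entries$HOS$eps[lib$grid == 340]  # 3400
#' @export
default_library <- function(grid = seq(270, 700, by = 2), fwhm = 70) {
  if (any(diff(grid) <= 0)) {
    stop("default_library: grid must be strictly ascending", call. = FALSE)
  }
  spectra <- lapply(names(DEFAULT_BANDS), function(id) {
    bs <- lapply(DEFAULT_BANDS[[id]], function(p) {
      band(p[[1]], p[[2]], if (length(p) > 2) p[[3]] else fwhm)
    })
    reference_spectrum(id, bs, grid)
  })
  spectrum_library(spectra)
}

#' Basis matrix of a library
#'
#' @param library A [spectrum_library()].
#' @param species Character vector of species to include (default all).
#' @param grid Optional target grid; the library is interpolated onto it
#'   (linear, zero outside the library grid).
#' @return Matrix `[wavelength x species]` of molar absorption coefficients.
#' @export
library_matrix <- function(library, species = names(library$entries),
                           grid = NULL) {
  stopifnot(inherits(library, "spectrum_library"))
  missing <- setdiff(species, names(library$entries))
  if (length(missing)) {
    stop("library_matrix: unknown species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cols <- lapply(species, function(id) {
    e <- library$entries[[id]]
    if (is.null(grid)) e$eps
    else stats::approx(e$grid, e$eps, xout = grid, yleft = 0, yright = 0)$y
  })
  m <- do.call(cbind, cols)
  colnames(m) <- species
  rownames(m) <- NULL
  m
}

#' Read and write spectrum libraries
#'
#' Two on-disk dialects are supported. JSON: an object mapping species id to a
#' list of `{lambda_max, eps_max, fwhm}` band records. CSV (long): header
#' `species,lambda_max,eps_max,fwhm`. A tabulated-curve CSV with header
#' `species,wavelength_nm,eps` is also accepted by `read_library()`.
#'
#' @param path File path; format chosen by extension (`.json` else CSV).
#' @param grid Grid on which to sample the loaded library.
#' @param library A [spectrum_library()] built from bands.
#' @return `read_library()` a [spectrum_library()]; `write_library()` the path,
#'   invisibly.
#' @name library_io
NULL

#' @rdname library_io
#' @export
read_library <- function(path, grid = seq(270, 700, by = 2)) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    spectra <- lapply(names(raw), function(id) {
      if (!id %in% SPECIES_IDS) {
        stop("read_library: unknown species id '", id, "'", call. = FALSE)
      }
      bs <- lapply(raw[[id]], function(b) {
        band(b$lambda_max, b$eps_max, if (is.null(b$fwhm)) 70 else b$fwhm)
      })
      reference_spectrum(id, bs, grid)
    })
    return(spectrum_library(spectra))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("species", "wavelength_nm", "eps") %in% names(tab))) {
    spectra <- lapply(split(tab, tab$species), function(d) {
      if (!d$species[1] %in% SPECIES_IDS) {
        stop("read_library: unknown species id '", d$species[1], "'",
             call. = FALSE)
      }
      reference_spectrum(d$species[1], grid = grid,
                         curve = d[order(d$wavelength_nm), ])
    })
    return(spectrum_library(spectra))
  }
  if (!all(c("species", "lambda_max", "eps_max") %in% names(tab))) {
    stop("read_library: unrecognised library file schema", call. = FALSE)
  }
  if (is.null(tab$fwhm)) tab$fwhm <- 70
  spectra <- lapply(split(tab, tab$species), function(d) {
    if (!d$species[1] %in% SPECIES_IDS) {
      stop("read_library: unknown species id '", d$species[1], "'",
           call. = FALSE)
    }
    bs <- Map(band, d$lambda_max, d$eps_max, d$fwhm)
    reference_spectrum(d$species[1], bs, grid)
  })
  spectrum_library(spectra)
}

#' @rdname library_io
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "spectrum_library"))
  for (e in library$entries) {
    if (length(e$bands) == 0) {
      stop("write_library: tabulated spectra cannot be written as bands",
           call. = FALSE)
    }
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- lapply(library$entries, function(e) {
      lapply(e$bands, function(b) {
        list(lambda_max = b$lambda_max, eps_max = b$eps_max, fwhm = b$fwhm)
      })
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- do.call(rbind, lapply(library$entries, function(e) {
      do.call(rbind, lapply(e$bands, function(b) {
        data.frame(species = e$species_id, lambda_max = b$lambda_max,
                   eps_max = b$eps_max, fwhm = b$fwhm)
      }))
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}
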