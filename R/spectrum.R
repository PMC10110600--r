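#' Wavelength-indexed spectrum
#'
#' The universal data carrier of the package: one physical quantity sampled
#' on an ascending wavelength grid in nanometres. Stored as a plain
#' `data.frame` with columns `wavelength_nm` and `value` and class
#' `"spectrum"`, so all of base R and the tidyverse work on it unchanged.
#'
#' @param wavelength_nm numeric vector of wavelengths (nm). Must be finite
#'   and strictly ascending after sorting; duplicated wavelengths are an
#'   error.
#' @param value numeric vector of the same length; must be finite.
#' @param quantity optional character tag naming the physical quantity
#'   (e.g. `"R_d"`, `"counts"`, `"epsilon_L_per_mol_cm"`).
#' @return A `spectrum` data.frame, sorted by ascending wavelength.
#' @examples
#' s <- spectrum(seq(400, 700, 10), exp(-seq(400, 700, 10) / 500))
#' head(s)
#' @export
spectrum <- function(wavelength_nm, value, quantity = NULL) {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) == 0L) {
    stop("spectrum: empty wavelength grid", call. = FALSE)
  }
  if (length(wavelength_nm) != length(value)) {
    stop("spectrum: wavelength and value lengths differ", call. = FALSE)
  }
  if (!all(is.finite(wavelength_nm)) || !all(is.finite(value))) {
    stop("spectrum: non-finite entries", call. = FALSE)
  }
  ord <- order(wavelength_nm)
  wavelength_nm <- wavelength_nm[ord]
  value <- value[ord]
  if (anyDuplicated(wavelength_nm)) {
    stop("spectrum: duplicated wavelengths", call. = FALSE)
  }
  out <- data.frame(wavelength_nm = wavelength_nm, value = value)
  class(out) <- c("spectrum", "data.frame")
  if (!is.null(quantity)) attr(out, "quantity") <- quantity
  out
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' @export
print.spectrum <- function(x, ...) {
  q <- attr(x, "quantity")
  cat(sprintf(
    "<spectrum%s: %d points, %.6g-%.6g nm>\n",
    if (is.null(q)) "" else paste0(" ", q), nrow(x),
    min(x$wavelength_nm), max(x$wavelength_nm)
  ))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("# ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Interpolate a spectrum onto a new wavelength grid
#'
#' Linear interpolation; requesting wavelengths outside the tabulated range
#' is an error unless `rule = 2` (constant extrapolation) is chosen.
#'
#' @param s a [spectrum()].
#' @param wavelength_nm target grid (nm).
#' @param rule as in [stats::approx()]: 1 errors outside the range, 2
#'   extends the end values.
#' @return numeric vector of interpolated values.
#' @export
interp_spectrum <- function(s, wavelength_nm, rule = 1) {
  stopifnot(is_spectrum(s))
  if (rule == 1 &&
      (min(wavelength_nm) < min(s$wavelength_nm) - 1e-9 ||
       max(wavelength_nm) > max(s$wavelength_nm) + 1e-9)) {
    stop("interp_spectrum: requested wavelengths outside tabulated range",
         call. = FALSE)
  }
  if (nrow(s) == 1L) return(rep(s$value, length(wavelength_nm)))
  stats::approx(s$wavelength_nm, s$value, xout = wavelength_nm,
                rule = 2)$y
}

#' Trapezoidal band integral of a spectrum
#'
#' Integrates `value` (optionally times a weight function of wavelength)
#' over `[lo, hi]` nm by the trapezoidal rule on the native grid, with the
#' band endpoints included exactly (interpolated if they fall between grid
#' points).
#'
#' @param s a [spectrum()].
#' @param lo,hi band limits in nm.
#' @param weight optional function of wavelength applied pointwise before
#'   integration (e.g. `identity` for photon weighting by lambda).
#' @return scalar integral value.
#' @export
band_integral <- function(s, lo, hi, weight = NULL) {
  stopifnot(is_spectrum(s), lo < hi)
  w <- s$wavelength_nm
  if (lo < min(w) - 1e-9 || hi > max(w) + 1e-9) {
    stop("band_integral: band outside tabulated grid", call. = FALSE)
  }
  inside <- w > lo & w < hi
  grid <- unique(sort(c(lo, w[inside], hi)))
  v <- stats::approx(w, s$value, xout = grid, rule = 2)$y
  if (!is.null(weight)) v <- v * weight(grid)
  sum(diff(grid) * (v[-1] + v[-length(v)]) / 2)
}

trapz_ <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Read a spectrum from a two-column CSV file
#'
#' Expects a header line and two numeric columns (wavelength in nm, value).
#' Descending-wavelength files are accepted and reversed with a warning;
#' non-numeric rows raise a parse error that names the offending line.
#'
#' @param path file path.
#' @param quantity optional quantity tag stored on the result.
#' @return a [spectrum()].
#' @export
read_spectrum <- function(path, quantity = NULL) {
  if (!file.exists(path)) stop("read_spectrum: no such file: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("read_spectrum: ", path, ": empty or malformed file",
         call. = FALSE)
  }
  wl <- suppressWarnings(as.numeric(raw[[1]]))
  vv <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(!is.finite(wl) | !is.finite(vv))
  if (length(bad)) {
    stop(sprintf("read_spectrum: %s: non-numeric value at data line %d",
                 path, bad[1]), call. = FALSE)
  }
  if (all(diff(wl) < 0)) {
    warning("read_spectrum: ", path,
            ": descending wavelength grid reversed")
    wl <- rev(wl)
    vv <- rev(vv)
  }
  if (any(diff(wl) <= 0)) {
    stop("read_spectrum: ", path, ": wavelength grid is not monotone",
         call. = FALSE)
  }
  spectrum(wl, vv, quantity = quantity)
}

#' Write a spectrum to a two-column CSV file
#'
#' Values are written with 9 significant digits so that a write/read round
#' trip is bit-identical for values representable at that precision.
#'
#' @param s a [spectrum()].
#' @param path output file path.
#' @param value_name header name for the value column.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, value_name = "value") {
  stopifnot(is_spectrum(s))
  lines <- c(
    paste0("wavelength_nm,", value_name),
    sprintf("%.9g,%.9g", s$wavelength_nm, s$value)
  )
  writeLines(lines, path)
  invisible(path)
}
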