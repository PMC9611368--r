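#' Antoine-type vapour pressure record
#'
#' Stores the coefficients of a saturation vapour-pressure correlation together
#' with the dialect that fixes its functional form and units. Supported
#' dialects:
#' \describe{
#'   \item{\code{"log10_bar_K"}}{\eqn{\log_{10} P[\mathrm{bar}] = A - B/(T[\mathrm{K}] + C)}.
#'     The canonical internal form; every record is converted to it before
#'     evaluation.}
#'   \item{\code{"log10_mmHg_C"}}{\eqn{\log_{10} P[\mathrm{mmHg}] = A - B/(C + t[\mathrm{^\circ C}])},
#'     the classic handbook dialect.}
#'   \item{\code{"CC2"}}{two-parameter Clausius--Clapeyron form
#'     \eqn{\log_{10} P[\mathrm{bar}] = A - B/T[\mathrm{K}]} (C must be 0), used
#'     for records fitted through two data points only.}
#' }
#'
#' @param A,B,C Dialect-dependent coefficients. For \code{"CC2"}, \code{C}
#'   must be 0.
#' @param dialect One of \code{"log10_bar_K"}, \code{"log10_mmHg_C"},
#'   \code{"CC2"}.
#' @param t_min_K,t_max_K Validity range of the correlation, kelvin.
#' @param source Free-text provenance of the coefficients.
#' @return An object of class \code{antoine_record}.
#' @export
#' @examples
#' # classic water correlation, 1-100 degC
#' antoine_record(8.07131, 1730.63, 233.426, "log10_mmHg_C", 274.15, 373.15)
antoine_record <- function(A, B, C = 0, dialect = "log10_bar_K",
                           t_min_K, t_max_K, source = "") {
  dialect <- match.arg(dialect, c("log10_bar_K", "log10_mmHg_C", "CC2"))
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C),
            length(A) == 1L, length(B) == 1L, length(C) == 1L)
  if (dialect == "CC2" && C != 0)
    stop("CC2 dialect requires C = 0", call. = FALSE)
  if (!is.numeric(t_min_K) || !is.numeric(t_max_K) || t_min_K >= t_max_K)
    stop("invalid validity range: need t_min_K < t_max_K", call. = FALSE)
  structure(
    list(A = A, B = B, C = C, dialect = dialect,
         t_min_K = t_min_K, t_max_K = t_max_K, source = as.character(source)),
    class = "antoine_record")
}

# offset between log10(P/bar) and log10(P/mmHg): 1 bar = 750.0617 mmHg
.LOG10_MMHG_PER_BAR <- log10(1e5 / 133.3224)

#' Convert an Antoine record between dialects
#'
#' Conversions between the supported log10 forms are exact affine maps of the
#' coefficients (no refitting): pressures evaluated before and after agree to
#' machine precision. Converting to \code{"CC2"} is only possible when the
#' canonical C coefficient is exactly 0.
#'
#' @param record An \code{antoine_record}.
#' @param to Target dialect.
#' @return An \code{antoine_record} in the target dialect.
#' @export
convert_antoine <- function(record, to = "log10_bar_K") {
  stopifnot(inherits(record, "antoine_record"))
  to <- match.arg(to, c("log10_bar_K", "log10_mmHg_C", "CC2"))
  # first to canonical bar/K form
  can <- switch(record$dialect,
    log10_bar_K  = record,
    CC2          = antoine_record(record$A, record$B, 0, "log10_bar_K",
                                  record$t_min_K, record$t_max_K, record$source),
    log10_mmHg_C = antoine_record(record$A - .LOG10_MMHG_PER_BAR, record$B,
                                  record$C - 273.15, "log10_bar_K",
                                  record$t_min_K, record$t_max_K, record$source))
  switch(to,
    log10_bar_K = can,
    CC2 = {
      if (abs(can$C) > .Machine$double.eps)
        stop("cannot express a record with C != 0 in the CC2 dialect",
             call. = FALSE)
      antoine_record(can$A, can$B, 0, "CC2", can$t_min_K, can$t_max_K,
                     can$source)
    },
    log10_mmHg_C = antoine_record(can$A + .LOG10_MMHG_PER_BAR, can$B,
                                  can$C + 273.15, "log10_mmHg_C",
                                  can$t_min_K, can$t_max_K, can$source))
}

#' Saturation vapour pressure of a compound
#'
#' Evaluates the compound's Antoine-type record after conversion to the
#' canonical \code{log10_bar_K} form and returns the pressure in pascal.
#' Outside the record's validity range the correlation is extrapolated and the
#' result is flagged; below the cryogenic cutoff the pressure is taken as
#' exactly 0 (every species is treated as fully condensable there, matching
#' liquid-nitrogen-trap operation).
#'
#' @param compound A \code{compound} object (see [compound()]).
#' @param temperature Temperature(s), kelvin.
#' @param cryo_cutoff_K Temperature below which the saturation pressure is
#'   returned as 0 Pa. Default 153.15 K (-120 degC).
#' @return Numeric vector of pressures in Pa, with attribute \code{"status"}:
#'   a character vector, per temperature, one of \code{"ok"},
#'   \code{"extrapolated"} (outside the tabulated range) or \code{"cutoff"}
#'   (below the cryogenic cutoff, pressure 0).
#' @export
#' @examples
#' w <- water_compound()
#' vapor_pressure(w, 283.15)  # ~1221 Pa
vapor_pressure <- function(compound, temperature, cryo_cutoff_K = 153.15) {
  stopifnot(inherits(compound, "compound"))
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0))
    stop("temperature must be finite and > 0 K", call. = FALSE)
  rec <- convert_antoine(compound$antoine, "log10_bar_K")
  p <- 1e5 * 10^(rec$A - rec$B / (temperature + rec$C))
  status <- rep("ok", length(temperature))
  outside <- temperature < rec$t_min_K | temperature > rec$t_max_K
  status[outside] <- "extrapolated"
  below <- temperature < cryo_cutoff_K
  p[below] <- 0
  status[below] <- "cutoff"
  if (any(!is.finite(p)))
    stop(sprintf("non-finite vapour pressure for compound '%s'",
                 compound$name), call. = FALSE)
  structure(p, status = status)
}
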