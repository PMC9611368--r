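#' Convert a dilute ppm (mass) profile to mole fractions
#'
#' Water is the implicit balance species: a profile of aroma concentrations in
#' ppm by mass is completed with water to 1e6 ppm and converted to mole
#' fractions, which sum to 1 to machine precision.
#'
#' @param concentrations_ppm Named numeric vector, ppm by mass per aroma
#'   (may be empty). Must not include \code{"water"}.
#' @param compounds Compound panel resolving every name (and \code{"water"}).
#' @return Named numeric vector of mole fractions including \code{"water"}.
#' @export
#' @examples
#' panel <- sardine_fixture()$compounds
#' ppm_to_mole_fraction(c("1-penten-3-ol" = 0.100), panel)
ppm_to_mole_fraction <- function(concentrations_ppm, compounds) {
  if (length(concentrations_ppm) &&
      (is.null(names(concentrations_ppm)) || any(!nzchar(names(concentrations_ppm)))))
    stop("concentrations must be a named vector", call. = FALSE)
  if ("water" %in% names(concentrations_ppm))
    stop("water is the implicit balance species; do not list it", call. = FALSE)
  total <- sum(concentrations_ppm)
  if (total >= 1e6) stop("ppm concentrations must sum to < 1e6", call. = FALSE)
  mw_w <- lookup_compound(compounds, "water")$mw_g_mol
  mol <- c(water = (1e6 - total) / mw_w)
  for (nm in names(concentrations_ppm)) {
    mw <- lookup_compound(compounds, nm)$mw_g_mol
    mol[nm] <- concentrations_ppm[[nm]] / mw
  }
  mol / sum(mol)
}

#' Mass flux to molar flux
#'
#' @param mass_flux_g_m2_h Mass flux, g/(m2 h).
#' @param mw_g_mol Molecular weight, g/mol.
#' @return Molar flux, mol/(m2 s).
#' @export
mass_to_molar_flux <- function(mass_flux_g_m2_h, mw_g_mol) {
  stopifnot(all(mass_flux_g_m2_h >= 0), all(mw_g_mol > 0))
  mass_flux_g_m2_h / mw_g_mol / 3600
}

#' Molar flux to mass flux
#'
#' Exact inverse of [mass_to_molar_flux()].
#'
#' @param molar_flux_mol_m2_s Molar flux, mol/(m2 s).
#' @param mw_g_mol Molecular weight, g/mol.
#' @return Mass flux, g/(m2 h).
#' @export
molar_to_mass_flux <- function(molar_flux_mol_m2_s, mw_g_mol) {
  stopifnot(all(molar_flux_mol_m2_s >= 0), all(mw_g_mol > 0))
  molar_flux_mol_m2_s * mw_g_mol * 3600
}

#' Permeate-side mole fractions from component fluxes
#'
#' @param fluxes Named numeric vector of molar fluxes, mol/(m2 s); at least
#'   one must be positive.
#' @return Named mole fractions summing to 1.
#' @export
permeate_mole_fractions <- function(fluxes) {
  if (!length(fluxes) || all(fluxes <= 0) || any(fluxes < 0))
    stop("need non-negative fluxes with at least one positive", call. = FALSE)
  fluxes / sum(fluxes)
}

#' Separation factor against water
#'
#' Enrichment of a compound between feed and permeate, measured against
#' water: \eqn{\beta_i = (y_i/y_w)/(x_i/x_w)}. In the dilute regime of these
#' streams this agrees with the binary form to well below 0.01\%.
#'
#' @param feed_x Named feed mole fractions (must include \code{water}).
#' @param permeate_y Named permeate mole fractions (must include \code{water}).
#' @param compound_name Compound to evaluate.
#' @return Dimensionless separation factor.
#' @export
separation_factor <- function(feed_x, permeate_y, compound_name) {
  for (v in list(feed_x, permeate_y))
    if (!all(c(compound_name, "water") %in% names(v)))
      stop("feed and permeate compositions must name the compound and water",
           call. = FALSE)
  if (feed_x[[compound_name]] <= 0 || feed_x[["water"]] <= 0 ||
      permeate_y[["water"]] <= 0)
    stop("separation factor undefined: zero denominator composition",
         call. = FALSE)
  (permeate_y[[compound_name]] / permeate_y[["water"]]) /
    (feed_x[[compound_name]] / feed_x[["water"]])
}

#' Membrane permeability from flux and driving force
#'
#' Solution-diffusion normalisation of a measured flux:
#' \deqn{L_i = J_i \,\delta / (x_i \gamma_i^\infty p_{v,i}(T_{feed}) - y_i\, p_{perm})}
#' with \eqn{\delta} the membrane (active-layer) thickness. Because the
#' thickness is often unknown, [permeance()] offers the thickness-free ratio
#' \eqn{L_i/\delta}.
#'
#' @param molar_flux Measured flux, mol/(m2 s).
#' @param feed_x Feed-side mole fraction of the compound.
#' @param gamma_inf Infinite-dilution activity coefficient.
#' @param p_v_feed Saturation vapour pressure at the feed temperature, Pa.
#' @param permeate_y Permeate-side mole fraction of the compound.
#' @param p_perm Permeate (downstream) pressure, Pa.
#' @param thickness_m Membrane active-layer thickness, m.
#' @return Permeability, mol/(m s Pa).
#' @export
permeability <- function(molar_flux, feed_x, gamma_inf, p_v_feed,
                         permeate_y, p_perm, thickness_m) {
  stopifnot(thickness_m > 0, molar_flux >= 0)
  permeance(molar_flux, feed_x, gamma_inf, p_v_feed, permeate_y, p_perm) *
    thickness_m
}

#' Membrane permeance (thickness-free permeability)
#'
#' \eqn{L_i/\delta = J_i / (x_i \gamma_i^\infty p_{v,i}(T_{feed}) - y_i p_{perm})},
#' mol/(m2 s Pa).
#'
#' @inheritParams permeability
#' @return Permeance, mol/(m2 s Pa).
#' @export
permeance <- function(molar_flux, feed_x, gamma_inf, p_v_feed,
                      permeate_y, p_perm) {
  driving <- feed_x * gamma_inf * p_v_feed - permeate_y * p_perm
  if (any(driving <= 0 & molar_flux > 0))
    stop(paste("non-positive partial-pressure driving force:",
               "thermodynamically inconsistent inputs"), call. = FALSE)
  out <- molar_flux
  out[molar_flux > 0] <- molar_flux[molar_flux > 0] / driving[molar_flux > 0]
  out
}

#' Permeate stream entering a condenser train
#'
#' @param water_flow Molar flow of water vapour, mol/s.
#' @param aroma_flows Named numeric vector of aroma molar flows, mol/s
#'   (may be empty).
#' @param inert_flow Molar flow of non-condensable (inert) gas, mol/s.
#' @param total_pressure Total (permeate) pressure, Pa.
#' @return Object of class \code{permeate_stream}.
#' @export
permeate_stream <- function(water_flow, aroma_flows = numeric(0),
                            inert_flow = 0, total_pressure) {
  if (length(aroma_flows) && (is.null(names(aroma_flows)) ||
                              any(!nzchar(names(aroma_flows)))))
    stop("aroma_flows must be a named vector", call. = FALSE)
  stopifnot(water_flow >= 0, inert_flow >= 0, all(aroma_flows >= 0),
            total_pressure > 0)
  structure(
    list(water_flow = water_flow, aroma_flows = aroma_flows,
         inert_flow = inert_flow, total_pressure = total_pressure),
    class = "permeate_stream")
}

#' @export
print.permeate_stream <- function(x, ...) {
  cat(sprintf(
    "<permeate_stream> %.4g mol/s water, %d aroma(s) (%.4g mol/s), %.4g mol/s inert @ %.4g Pa\n",
    x$water_flow, length(x$aroma_flows), sum(x$aroma_flows), x$inert_flow,
    x$total_pressure))
  invisible(x)
}

#' Assemble a permeate stream from flux measurements
#'
#' Converts per-compound fluxes to molar flows on a given membrane area. The
#' water flow is either given directly (\code{water_flux_g_m2_h}) or derived
#' as total minus aromas (\code{total_flux_g_m2_h}).
#'
#' @param measurements Data frame with columns \code{compound},
#'   \code{feed_ppm}, \code{flux_value}, \code{flux_unit} (one of
#'   \code{"g_m2_h"}, \code{"mol_m2_s"}).
#' @param compounds Compound panel.
#' @param total_flux_g_m2_h Total permeate mass flux, g/(m2 h); mutually
#'   exclusive with \code{water_flux_g_m2_h}.
#' @param water_flux_g_m2_h Water mass flux, g/(m2 h).
#' @param inert_flow_mol_s Inert-gas molar flow through the train, mol/s.
#' @param p_perm_Pa Permeate pressure, Pa.
#' @param membrane_area_m2 Membrane area, m2.
#' @return A [permeate_stream()].
#' @export
build_permeate_stream <- function(measurements, compounds,
                                  total_flux_g_m2_h = NULL,
                                  water_flux_g_m2_h = NULL,
                                  inert_flow_mol_s = 0,
                                  p_perm_Pa, membrane_area_m2) {
  stopifnot(membrane_area_m2 > 0)
  measurements <- validate_measurements(measurements)
  if (is.null(total_flux_g_m2_h) == is.null(water_flux_g_m2_h))
    stop("give exactly one of total_flux_g_m2_h or water_flux_g_m2_h",
         call. = FALSE)
  aroma_J <- molar_fluxes(measurements, compounds)   # mol/(m2 s)
  if (!is.null(total_flux_g_m2_h)) {
    mass_aromas <- sum(vapply(names(aroma_J), function(nm)
      molar_to_mass_flux(aroma_J[[nm]], lookup_compound(compounds, nm)$mw_g_mol),
      numeric(1)))
    if (mass_aromas >= total_flux_g_m2_h)
      stop("aroma mass fluxes exceed the total permeate flux", call. = FALSE)
    water_flux_g_m2_h <- total_flux_g_m2_h - mass_aromas
  }
  water_J <- mass_to_molar_flux(water_flux_g_m2_h,
                                lookup_compound(compounds, "water")$mw_g_mol)
  permeate_stream(water_flow = water_J * membrane_area_m2,
                  aroma_flows = aroma_J * membrane_area_m2,
                  inert_flow = inert_flow_mol_s,
                  total_pressure = p_perm_Pa)
}

# normalise a measurements table; returns the validated data.frame
validate_measurements <- function(measurements) {
  req <- c("compound", "feed_ppm", "flux_value", "flux_unit")
  if (!is.data.frame(measurements) || !all(req %in% names(measurements)))
    stop("measurements must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (nrow(measurements) == 0L)
    stop("measurements table is empty", call. = FALSE)
  if (!all(measurements$flux_unit %in% c("g_m2_h", "mol_m2_s")))
    stop("flux_unit must be 'g_m2_h' or 'mol_m2_s'", call. = FALSE)
  if (any(measurements$flux_value <= 0) || any(measurements$feed_ppm <= 0))
    stop("fluxes and feed concentrations must be positive", call. = FALSE)
  if (anyDuplicated(measurements$compound))
    stop("duplicate compound in measurements", call. = FALSE)
  measurements
}

# per-compound molar fluxes in mol/(m2 s) from a measurements table
molar_fluxes <- function(measurements, compounds) {
  J <- numeric(nrow(measurements))
  for (i in seq_len(nrow(measurements))) {
    mw <- lookup_compound(compounds, measurements$compound[i])$mw_g_mol
    J[i] <- if (measurements$flux_unit[i] == "g_m2_h")
      mass_to_molar_flux(measurements$flux_value[i], mw)
    else measurements$flux_value[i]
  }
  names(J) <- measurements$compound
  J
}

#' Pervaporation performance metrics
#'
#' Computes, per measured aroma, the molar flux, the separation factor against
#' water and the permeability/permeance, from feed concentrations (ppm), the
#' measured fluxes and the water flux.
#'
#' @inheritParams build_permeate_stream
#' @param T_feed_K Feed temperature, K (vapour pressures for the driving force
#'   are evaluated here).
#' @param thickness_m Membrane active-layer thickness, m (for permeability;
#'   permeance is reported regardless).
#' @return Data frame with one row per aroma: \code{compound},
#'   \code{molar_flux_mol_m2_s}, \code{separation_factor},
#'   \code{permeance_mol_m2_s_Pa}, \code{permeability_mol_m_s_Pa}. When a
#'   compound's measured feed concentration and flux imply a non-positive
#'   partial-pressure driving force (thermodynamically inconsistent inputs),
#'   its permeance/permeability are reported as \code{NA} with a warning;
#'   fluxes and separation factors are unaffected.
#' @export
pervap_metrics <- function(measurements, compounds,
                           total_flux_g_m2_h = NULL, water_flux_g_m2_h = NULL,
                           p_perm_Pa, T_feed_K = 333.15, thickness_m = 1e-6) {
  measurements <- validate_measurements(measurements)
  aroma_J <- molar_fluxes(measurements, compounds)
  if (is.null(total_flux_g_m2_h) == is.null(water_flux_g_m2_h))
    stop("give exactly one of total_flux_g_m2_h or water_flux_g_m2_h",
         call. = FALSE)
  mw_w <- lookup_compound(compounds, "water")$mw_g_mol
  if (!is.null(total_flux_g_m2_h)) {
    mass_aromas <- sum(vapply(names(aroma_J), function(nm)
      molar_to_mass_flux(aroma_J[[nm]], lookup_compound(compounds, nm)$mw_g_mol),
      numeric(1)))
    water_flux_g_m2_h <- total_flux_g_m2_h - mass_aromas
  }
  water_J <- mass_to_molar_flux(water_flux_g_m2_h, mw_w)
  feed_ppm <- stats::setNames(measurements$feed_ppm, measurements$compound)
  feed_x <- ppm_to_mole_fraction(feed_ppm, compounds)
  y <- permeate_mole_fractions(c(water = water_J, aroma_J))
  out <- data.frame(compound = names(aroma_J),
                    molar_flux_mol_m2_s = unname(aroma_J),
                    stringsAsFactors = FALSE)
  out$separation_factor <- vapply(out$compound, function(nm)
    separation_factor(feed_x, y, nm), numeric(1))
  out$permeance_mol_m2_s_Pa <- vapply(out$compound, function(nm) {
    cp <- lookup_compound(compounds, nm)
    pv <- as.numeric(vapor_pressure(cp, T_feed_K))
    tryCatch(
      permeance(aroma_J[[nm]], feed_x[[nm]], cp$gamma_inf, pv, y[[nm]],
                p_perm_Pa),
      error = function(e) {
        warning(sprintf("%s: %s (permeability reported as NA)", nm,
                        conditionMessage(e)), call. = FALSE)
        NA_real_
      })
  }, numeric(1))
  out$permeability_mol_m_s_Pa <- out$permeance_mol_m2_s_Pa * thickness_m
  rownames(out) <- NULL
  out
}
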