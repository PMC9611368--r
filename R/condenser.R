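#' Condenser specification
#'
#' @param temperature_K Condenser temperature, kelvin (> 0).
#' @param index 1-based position in the series.
#' @return Object of class \code{condenser_spec}.
#' @export
condenser_spec <- function(temperature_K, index = 1L) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0,
            index >= 1L)
  structure(list(temperature_K = temperature_K, index = as.integer(index)),
            class = "condenser_spec")
}

#' Celsius to kelvin
#' @param t_C Temperature(s) in degrees Celsius.
#' @return Temperature(s) in kelvin.
#' @export
C_to_K <- function(t_C) t_C + 273.15

clamp01 <- function(x) pmin(pmax(x, 0), 1)  # x first so names survive

#' Equilibrium condensed fraction of water in a partial condenser
#'
#' With a non-condensable carrier gas at total pressure \eqn{p_{perm}}, the
#' fraction of the incoming water vapour that condenses at temperature T is
#' \deqn{f_w = 1 - \frac{n_{inert}}{n_{w0}}\,
#'       \frac{p_{vw}(T)}{p_{perm} - p_{vw}(T)}}
#' clamped to [0, 1]. The carrier gas sets the floor on condensation: with no
#' inert gas every condensable condenses completely at any temperature where
#' its saturation pressure is below the total pressure.
#'
#' @param stream A [permeate_stream()].
#' @param temperature_K Condenser temperature, K.
#' @param compounds Compound panel (resolves \code{"water"}).
#' @param cryo_cutoff_K Passed to [vapor_pressure()].
#' @return Fraction in [0, 1] with attribute \code{"status"}: \code{"ok"}, or
#'   \code{"water_noncondensing"} when \eqn{p_{vw}(T) \ge p_{perm}} (no
#'   equilibrium condensation possible; 0 is returned).
#' @export
water_condensed_fraction <- function(stream, temperature_K, compounds,
                                     cryo_cutoff_K = 153.15) {
  stopifnot(inherits(stream, "permeate_stream"), stream$water_flow > 0)
  pvw <- as.numeric(vapor_pressure(lookup_compound(compounds, "water"),
                                   temperature_K, cryo_cutoff_K))
  if (pvw >= stream$total_pressure)
    return(structure(0, status = "water_noncondensing"))
  f <- 1 - (stream$inert_flow / stream$water_flow) *
    pvw / (stream$total_pressure - pvw)
  structure(clamp01(f), status = "ok")
}

#' Equilibrium condensed fraction of an aroma in a partial condenser
#'
#' \deqn{f_a = 1 - \frac{n_{inert}}{n_{a0}}\,
#'       \frac{x_a \gamma_a^\infty p_{v,a}(T)}{p_{perm} - p_{vw}(T)}}
#' clamped to [0, 1], where \eqn{x_a} is the mole fraction of the aroma in the
#' condensate. The closed form is an approximation valid in the dilute
#' aqueous-condensate regime; [solve_condenser()] closes it by fixed-point
#' iteration on the condensate composition.
#'
#' @inheritParams water_condensed_fraction
#' @param x_condensate Mole fraction of the aroma in the condensate.
#' @param compound_name Aroma name.
#' @return Fraction in [0, 1] (attribute \code{"status"} as in
#'   [water_condensed_fraction()]).
#' @export
aroma_condensed_fraction <- function(stream, temperature_K, x_condensate,
                                     compound_name, compounds,
                                     cryo_cutoff_K = 153.15) {
  stopifnot(inherits(stream, "permeate_stream"))
  pvw <- as.numeric(vapor_pressure(lookup_compound(compounds, "water"),
                                   temperature_K, cryo_cutoff_K))
  if (pvw >= stream$total_pressure)
    return(structure(0, status = "water_noncondensing"))
  cp <- lookup_compound(compounds, compound_name)
  pva <- as.numeric(vapor_pressure(cp, temperature_K, cryo_cutoff_K))
  n_a <- stream$aroma_flows[[compound_name]]
  if (is.null(n_a) || n_a <= 0)
    stop(sprintf("stream carries no flow of '%s'", compound_name),
         call. = FALSE)
  f <- 1 - (stream$inert_flow / n_a) * x_condensate * cp$gamma_inf * pva /
    (stream$total_pressure - pvw)
  structure(clamp01(f), status = "ok")
}

#' Solve one condenser stage
#'
#' Solves the coupled equilibrium/material-balance system for a single
#' partial condenser: the water fraction follows directly from the carrier-gas
#' balance, while the aroma fractions and the condensate mole fractions they
#' depend on are closed by fixed-point iteration, initialised at "everything
#' condenses". Each sweep solves the per-aroma balance exactly at the current
#' total condensate flow (where it is linear), so the iteration stays stable
#' even for strongly-excluded volatiles. Convergence is declared when the
#' condensate mole-fraction vector changes by less than \code{tol} (max
#' absolute change).
#'
#' The inert gas passes through entirely; the outlet stream keeps the inlet
#' pressure. Species conservation (inlet = condensed + outlet) holds to
#' machine precision by construction.
#'
#' @inheritParams water_condensed_fraction
#' @param spec A [condenser_spec()].
#' @param tol Fixed-point tolerance on the condensate mole fractions.
#' @param max_iter Maximum fixed-point iterations.
#' @return Object of class \code{condenser_result}: list with
#'   \code{condensed_fraction} (named, water + aromas),
#'   \code{condensate_mole_fractions}, \code{condensate_mass_flow_kg_s},
#'   \code{outlet} (a \code{permeate_stream}), \code{validity} (one of
#'   \code{"valid"}, \code{"water_noncondensing"}, \code{"extrapolated_pv"}),
#'   \code{iterations}, \code{temperature_K}, \code{index}.
#' @export
solve_condenser <- function(stream, spec, compounds, tol = 1e-12,
                            max_iter = 200L, cryo_cutoff_K = 153.15) {
  stopifnot(inherits(stream, "permeate_stream"),
            inherits(spec, "condenser_spec"))
  T_K <- spec$temperature_K
  p <- stream$total_pressure
  aromas <- names(stream$aroma_flows)
  for (nm in aromas) lookup_compound(compounds, nm)  # fail early on unknowns

  pv_w <- vapor_pressure(lookup_compound(compounds, "water"), T_K,
                         cryo_cutoff_K)
  pv_a <- vapply(aromas, function(nm)
    as.numeric(vapor_pressure(lookup_compound(compounds, nm), T_K,
                              cryo_cutoff_K)), numeric(1))
  statuses <- c(attr(pv_w, "status"),
                vapply(aromas, function(nm)
                  attr(vapor_pressure(lookup_compound(compounds, nm), T_K,
                                      cryo_cutoff_K), "status"), character(1)))
  extrapolated <- any(statuses != "ok")
  pvw <- as.numeric(pv_w)

  mk_result <- function(f_w, f_a, validity, iterations) {
    n <- c(water = stream$water_flow, stream$aroma_flows)
    f <- c(water = f_w, f_a)[names(n)]
    cond <- f * n
    x <- if (sum(cond) > 0) cond / sum(cond) else cond * 0
    mw <- vapply(names(n), function(nm)
      lookup_compound(compounds, nm)$mw_g_mol, numeric(1))
    outlet <- permeate_stream(
      water_flow = stream$water_flow * (1 - f[["water"]]),
      aroma_flows = stream$aroma_flows * (1 - f[aromas]),
      inert_flow = stream$inert_flow,
      total_pressure = p)
    structure(
      list(condensed_fraction = f,
           condensate_mole_fractions = x,
           condensate_mass_flow_kg_s = sum(cond * mw) / 1000,
           outlet = outlet,
           validity = validity,
           iterations = iterations,
           temperature_K = T_K,
           index = spec$index),
      class = "condenser_result")
  }

  if (pvw >= p) {
    f_a0 <- stats::setNames(rep(0, length(aromas)), aromas)
    return(mk_result(0, f_a0, "water_noncondensing", 0L))
  }

  f_w <- clamp01(1 - (stream$inert_flow / stream$water_flow) * pvw / (p - pvw))
  gam <- vapply(aromas, function(nm)
    lookup_compound(compounds, nm)$gamma_inf, numeric(1))
  n_a <- stream$aroma_flows
  denom <- p - pvw

  # Fixed point on the condensate mole-fraction vector, initialised at
  # "everything condenses". Substituting x_a = f_a n_a / n_tot into the
  # closed form makes it linear in f_a at fixed total condensate flow n_tot,
  # so each sweep solves f_a = 1/(1 + q_a) exactly (q_a >= 0, hence f_a is
  # always in (0, 1] and the [0, 1] clamp of the raw form never binds) and
  # only n_tot -- dominated by the water term -- is iterated. This keeps the
  # strongly-excluded aromas (q_a >> 1) from destabilising the iteration.
  f_a <- stats::setNames(rep(1, length(aromas)), aromas)
  f_a[n_a == 0] <- 0
  iterations <- 0L
  if (length(aromas)) {
    x_prev <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      iterations <- it
      cond <- c(f_w * stream$water_flow, f_a * n_a)
      tot <- sum(cond)
      if (tot <= 0) { converged <- TRUE; break }
      x <- cond / tot
      q <- stream$inert_flow * gam * pv_a / (denom * tot)
      f_new <- clamp01(1 / (1 + q))
      f_new[n_a == 0] <- 0
      f_a <- f_new
      if (!is.null(x_prev) && max(abs(x - x_prev)) < tol) {
        converged <- TRUE
        break
      }
      x_prev <- x
    }
    if (!converged) {
      cond <- c(f_w * stream$water_flow, f_a * n_a)
      resid <- max(abs(cond / sum(cond) - x_prev))
      stop(sprintf(
        "condenser fixed point did not converge in %d iterations (last residual %.3g)",
        max_iter, resid), call. = FALSE)
    }
  }
  validity <- if (extrapolated) "extrapolated_pv" else "valid"
  mk_result(f_w, f_a, validity, iterations)
}

#' @export
print.condenser_result <- function(x, ...) {
  cat(sprintf("<condenser_result> stage %d @ %.2f K (%s), %d iteration(s)\n",
              x$index, x$temperature_K, x$validity, x$iterations))
  print(round(x$condensed_fraction, 6))
  invisible(x)
}

#' Run a cascade of condensers in series
#'
#' Each condenser receives the vapour outlet of the previous one. Per-compound
#' conservation across the whole cascade holds to machine precision.
#'
#' @inheritParams solve_condenser
#' @param specs List of [condenser_spec()]s, in series order (their
#'   \code{index} fields are overwritten by position).
#' @return Object of class \code{cascade_result}: \code{per_condenser} (list
#'   of \code{condenser_result}) and \code{overall_recovery}, a matrix
#'   (compound x stage) of the fraction of the *original* permeate captured in
#'   each stage, with a final \code{vapour_out} column.
#' @export
run_cascade <- function(stream, specs, compounds, ...) {
  stopifnot(length(specs) >= 1L)
  n0 <- c(water = stream$water_flow, stream$aroma_flows)
  per <- vector("list", length(specs))
  cur <- stream
  rec <- matrix(0, nrow = length(n0), ncol = length(specs) + 1L,
                dimnames = list(names(n0),
                                c(paste0("condenser_", seq_along(specs)),
                                  "vapour_out")))
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    spec$index <- k
    res <- solve_condenser(cur, spec, compounds, ...)
    per[[k]] <- res
    n_in <- c(water = cur$water_flow, cur$aroma_flows)
    rec[, k] <- ifelse(n0 > 0, (res$condensed_fraction * n_in)[names(n0)] / n0, 0)
    cur <- res$outlet
  }
  n_end <- c(water = cur$water_flow, cur$aroma_flows)
  rec[, length(specs) + 1L] <- ifelse(n0 > 0, n_end[names(n0)] / n0, 0)
  structure(list(per_condenser = per, overall_recovery = rec,
                 inlet = stream),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> %d condenser stage(s)\n",
              length(x$per_condenser)))
  print(round(x$overall_recovery, 6))
  invisible(x)
}

#' Condensed fraction versus condenser temperature
#'
#' Evaluates the first-condenser condensed fraction of every compound in the
#' stream over a temperature grid (the model analogue of a
#' fraction-versus-temperature condensation curve).
#'
#' @inheritParams solve_condenser
#' @param T_grid_K Ascending temperatures, K.
#' @return Data frame with columns \code{temperature_K}, \code{compound},
#'   \code{condensed_fraction}, \code{validity}.
#' @export
condensation_curve <- function(stream, T_grid_K, compounds, ...) {
  stopifnot(length(T_grid_K) >= 1L, !is.unsorted(T_grid_K))
  rows <- lapply(T_grid_K, function(T_K) {
    res <- solve_condenser(stream, condenser_spec(T_K, 1L), compounds, ...)
    data.frame(temperature_K = T_K,
               compound = names(res$condensed_fraction),
               condensed_fraction = unname(res$condensed_fraction),
               validity = res$validity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate the inert-gas ratio against one observed condensed fraction
#'
#' The inert (non-condensable) gas flow is rarely measurable directly, but the
#' condensed fraction of any one compound at a known condenser temperature
#' pins it down: the fraction is monotone decreasing in the inert ratio, so a
#' bisection recovers \eqn{n_{inert}/n_{w0}} from a single observation.
#'
#' @inheritParams solve_condenser
#' @param compound_name Compound whose condensed fraction was observed.
#' @param observed_fraction Observed condensed fraction in (0, 1).
#' @param temperature_K Condenser temperature of the observation, K.
#' @param tol Absolute tolerance on the matched fraction.
#' @param max_iter Maximum bisection steps.
#' @return List with \code{inert_ratio} (\eqn{n_{inert}/n_{w0}}),
#'   \code{inert_flow_mol_s}, \code{stream} (the input stream with the
#'   calibrated inert flow), \code{achieved_fraction} and \code{iterations}.
#' @export
calibrate_inert_ratio <- function(stream, compound_name, observed_fraction,
                                  temperature_K, compounds,
                                  tol = 1e-10, max_iter = 200L) {
  stopifnot(observed_fraction > 0, observed_fraction < 1)
  frac_at <- function(r) {
    s <- stream
    s$inert_flow <- r * stream$water_flow
    res <- solve_condenser(s, condenser_spec(temperature_K, 1L), compounds)
    if (res$validity == "water_noncondensing")
      stop("water cannot condense at the calibration temperature",
           call. = FALSE)
    res$condensed_fraction[[compound_name]]
  }
  lo <- 0
  hi <- 1
  while (frac_at(hi) > observed_fraction) {
    hi <- hi * 2
    if (hi > 1e9)
      stop("calibration failed: observed fraction unattainable", call. = FALSE)
  }
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    mid <- (lo + hi) / 2
    f <- frac_at(mid)
    if (abs(f - observed_fraction) < tol) break
    if (f > observed_fraction) lo <- mid else hi <- mid
  }
  r <- (lo + hi) / 2
  out_stream <- stream
  out_stream$inert_flow <- r * stream$water_flow
  list(inert_ratio = r, inert_flow_mol_s = out_stream$inert_flow,
       stream = out_stream, achieved_fraction = frac_at(r),
       iterations = iterations)
}
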