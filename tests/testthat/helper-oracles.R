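# Independent oracles and small constructors used across the suite.

# Full isothermal-flash oracle (no dilute approximation): every species'
# partial pressure is equated to x_i * gamma_i * p_v,i via the Rachford-Rice
# equation, with the inert gas as a pseudo-species of very large K. This is
# the reference the closed-form condenser solution is checked against.
rr_flash <- function(stream, T_K, compounds, K_inert = 1e12) {
  nms <- c("water", names(stream$aroma_flows))
  n <- c(water = stream$water_flow, stream$aroma_flows)
  gam <- vapply(nms, function(nm) compounds[[nm]]$gamma_inf, numeric(1))
  pv <- vapply(nms, function(nm)
    as.numeric(vapor_pressure(compounds[[nm]], T_K)), numeric(1))
  K <- c(gam * pv / stream$total_pressure, inert = K_inert)
  z <- c(n, inert = stream$inert_flow)
  z <- z / sum(z)
  rr <- function(V) sum(z * (K - 1) / (1 + V * (K - 1)))
  eps <- 1e-13
  V <- if (rr(1 - eps) >= 0) 1
       else if (rr(eps) <= 0) 0
       else stats::uniroot(rr, c(eps, 1 - eps), tol = 1e-15)$root
  vap_share <- V * K / (1 + V * (K - 1))
  f <- 1 - vap_share
  stats::setNames(f[seq_along(nms)], nms)
}

# analytic CC2 test compound: p_v(T) = p_ref at T_ref, Clausius-Clapeyron
# slope b (so expected pressures are known in closed form)
cc2_compound <- function(name, gamma_inf, T_ref, p_ref_Pa, b = 2500,
                         mw = 100, family = "other",
                         threshold = NA_real_, off = FALSE) {
  A <- log10(p_ref_Pa / 1e5) + b / T_ref
  compound(name, family, mw,
           antoine_record(A, b, 0, "CC2", 150, 500, "test fit"),
           gamma_inf, threshold, off)
}

# small dilute test system: water + three aromas of contrasting volatility
dilute_test_system <- function(inert_ratio = 0.01, p_perm = 1500,
                               water_flow = 1e-4) {
  compounds <- list(
    water = water_compound(),
    lightA = cc2_compound("lightA", 50, 283.15, 500),
    midB = cc2_compound("midB", 5000, 283.15, 40),
    heavyC = cc2_compound("heavyC", 20000, 283.15, 2))
  stream <- permeate_stream(
    water_flow = water_flow,
    aroma_flows = c(lightA = 5e-9, midB = 2e-9, heavyC = 1e-9),
    inert_flow = inert_ratio * water_flow,
    total_pressure = p_perm)
  list(compounds = compounds, stream = stream)
}

# random dilute stream + panel for property sweeps (seeded by caller)
random_system <- function() {
  n_ar <- sample(1:5, 1)
  nms <- sprintf("a%d", seq_len(n_ar))
  compounds <- c(list(water = water_compound()),
                 stats::setNames(lapply(seq_len(n_ar), function(i)
                   cc2_compound(nms[i], 10^stats::runif(1, 1, 5), 283.15,
                                10^stats::runif(1, -1, 3))), nms))
  water_flow <- 10^stats::runif(1, -5, -3)
  stream <- permeate_stream(
    water_flow = water_flow,
    aroma_flows = stats::setNames(10^stats::runif(n_ar, -10, -8), nms),
    inert_flow = 10^stats::runif(1, -4, -1.3) * water_flow,
    # keep p_perm above p_vw over the 250-290 K sweeps these systems feed,
    # so water is always condensable (the non-condensing branch has its own
    # dedicated tests)
    total_pressure = stats::runif(1, 2500, 5000))
  list(compounds = compounds, stream = stream)
}
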