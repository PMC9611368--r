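#' Concentration of a compound in a condensate
#'
#' Mass of the compound condensed per mass of total condensate, in mg/kg.
#'
#' @param result A \code{condenser_result} from [solve_condenser()].
#' @param compound_name Compound to evaluate.
#' @param compounds Compound panel.
#' @return Concentration, mg/kg of condensate.
#' @export
condensate_concentration <- function(result, compound_name, compounds) {
  stopifnot(inherits(result, "condenser_result"))
  if (result$condensate_mass_flow_kg_s <= 0)
    stop("empty condensate: concentration undefined", call. = FALSE)
  if (is.null(result$condensed_fraction[[compound_name]]))
    stop(sprintf("'%s' not present in this condenser result", compound_name),
         call. = FALSE)
  x <- result$condensate_mole_fractions
  mw_all <- vapply(names(x), function(nm)
    lookup_compound(compounds, nm)$mw_g_mol, numeric(1))
  tot_mol_s <- result$condensate_mass_flow_kg_s * 1000 / sum(x * mw_all)
  condensed_mol_s <- x[[compound_name]] * tot_mol_s
  mw <- lookup_compound(compounds, compound_name)$mw_g_mol
  mass_g_s <- condensed_mol_s * mw
  (mass_g_s / (result$condensate_mass_flow_kg_s * 1000)) * 1e6
}

#' Off-flavour / quality screen of a condensate
#'
#' Compares the condensate concentration of every aroma against its olfactive
#' threshold (when one is tabulated). Concentrations in mg/kg are compared
#' directly against thresholds in mg/L under the documented unit-density
#' assumption for the water-dominated condensate (error below 0.1\% at these
#' dilutions). The comparison is a strict inequality: a concentration exactly
#' at the threshold is reported as not below.
#'
#' @param cascade A \code{cascade_result} from [run_cascade()].
#' @param compounds Compound panel.
#' @param condenser_index Which condensate to screen (default the first).
#' @return Object of class \code{quality_report}: a list with \code{table}
#'   (per-aroma data frame: concentration, threshold, below_threshold,
#'   off_flavour, recovery per condenser) and \code{condenser_index}.
#' @export
quality_report <- function(cascade, compounds, condenser_index = 1L) {
  stopifnot(inherits(cascade, "cascade_result"),
            condenser_index >= 1L,
            condenser_index <= length(cascade$per_condenser))
  res <- cascade$per_condenser[[condenser_index]]
  aromas <- setdiff(names(res$condensed_fraction), "water")
  conc <- vapply(aromas, function(nm)
    if (res$condensate_mass_flow_kg_s > 0)
      condensate_concentration(res, nm, compounds) else 0, numeric(1))
  thr <- vapply(aromas, function(nm)
    lookup_compound(compounds, nm)$odour_threshold_mg_L, numeric(1))
  off <- vapply(aromas, function(nm)
    lookup_compound(compounds, nm)$off_flavour, logical(1))
  below <- ifelse(is.na(thr), NA, conc < thr)  # strict comparison
  tab <- data.frame(compound = aromas,
                    concentration_mg_kg = unname(conc),
                    odour_threshold_mg_L = unname(thr),
                    below_threshold = unname(below),
                    off_flavour = unname(off),
                    stringsAsFactors = FALSE)
  rec <- cascade$overall_recovery[aromas, , drop = FALSE]
  structure(list(table = tab, recovery = rec,
                 condenser_index = condenser_index),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> condensate of condenser %d\n",
              x$condenser_index))
  tab <- x$table
  tab$concentration_mg_kg <- signif(tab$concentration_mg_kg, 4)
  print(tab, row.names = FALSE)
  off <- x$table[x$table$off_flavour & !is.na(x$table$below_threshold), ]
  if (nrow(off)) {
    ok <- all(off$below_threshold)
    cat(if (ok) "All off-flavours below their olfactive thresholds.\n"
        else "Off-flavour(s) at or above their olfactive threshold.\n")
  }
  invisible(x)
}
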