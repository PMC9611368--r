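#' Physical-property record for one compound
#'
#' Immutable record bundling everything the condensation model needs about a
#' species: molecular weight, an Antoine-type vapour-pressure record, the
#' infinite-dilution activity coefficient in water, and (optionally) an odour
#' threshold with an off-flavour flag.
#'
#' @param name Compound name (unique key in a panel).
#' @param family One of \code{"alcohol"}, \code{"aldehyde"}, \code{"ketone"},
#'   \code{"water"}, \code{"other"}.
#' @param mw_g_mol Molecular weight, g/mol (> 0).
#' @param antoine An [antoine_record()].
#' @param gamma_inf Infinite-dilution activity coefficient in the aqueous
#'   condensate (dimensionless, >= 1 for the hydrophobic aromas modelled;
#'   water uses 1).
#' @param odour_threshold_mg_L Olfactive perception threshold, mg/L, or
#'   \code{NA} when unknown.
#' @param off_flavour Logical; whether the compound degrades sensory quality.
#' @return Object of class \code{compound}.
#' @export
compound <- function(name, family, mw_g_mol, antoine, gamma_inf,
                     odour_threshold_mg_L = NA_real_, off_flavour = FALSE) {
  family <- match.arg(family,
                      c("alcohol", "aldehyde", "ketone", "water", "other"))
  stopifnot(is.character(name), nzchar(name), inherits(antoine, "antoine_record"))
  if (!is.numeric(mw_g_mol) || mw_g_mol <= 0)
    stop(sprintf("compound '%s': molecular weight must be > 0", name),
         call. = FALSE)
  if (!is.numeric(gamma_inf) || gamma_inf < 1)
    stop(sprintf("compound '%s': gamma_inf must be >= 1", name), call. = FALSE)
  if (!is.na(odour_threshold_mg_L) && odour_threshold_mg_L <= 0)
    stop(sprintf("compound '%s': odour threshold must be > 0 when present",
                 name), call. = FALSE)
  structure(
    list(name = name, family = family, mw_g_mol = mw_g_mol, antoine = antoine,
         gamma_inf = gamma_inf, odour_threshold_mg_L = odour_threshold_mg_L,
         off_flavour = isTRUE(off_flavour)),
    class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s (%s), MW %.2f g/mol, gamma_inf %.3g%s\n",
              x$name, x$family, x$mw_g_mol, x$gamma_inf,
              if (x$off_flavour) ", off-flavour" else ""))
  invisible(x)
}

#' Reference water record
#'
#' Water with the classic Antoine correlation (mmHg/degC dialect, fitted over
#' 1-100 degC) and unit activity coefficient. Used as the balance species of
#' every stream and as the condensate solvent.
#'
#' @return A \code{compound}.
#' @export
water_compound <- function() {
  compound("water", "water", 18.015,
           antoine_record(8.07131, 1730.63, 233.426, "log10_mmHg_C",
                          274.15, 373.15,
                          "Antoine correlation fitted to steam tables, 1-100 C"),
           gamma_inf = 1)
}

#' Load a compound property table
#'
#' Reads a panel of compounds from CSV or JSON matching the documented schema
#' (columns \code{name, family, mw_g_mol, antoine_A, antoine_B, antoine_C,
#' antoine_dialect, t_min_K, t_max_K, gamma_inf, odour_threshold_mg_L,
#' off_flavour} and optionally \code{source}). Every record is validated;
#' duplicate names are rejected.
#'
#' @param path Path to a \code{.csv} or \code{.json} file.
#' @return Named list of \code{compound} objects (a compound panel). An empty
#'   file yields an empty list.
#' @export
load_compound_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0L) return(structure(list(), names = character()))
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  }
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  required <- c("name", "family", "mw_g_mol", "antoine_A", "antoine_B",
                "antoine_C", "antoine_dialect", "t_min_K", "t_max_K",
                "gamma_inf")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("compound table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicate compound name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  if (!"odour_threshold_mg_L" %in% names(df))
    df$odour_threshold_mg_L <- NA_real_
  if (!"off_flavour" %in% names(df)) df$off_flavour <- FALSE
  if (!"source" %in% names(df)) df$source <- ""
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    rec <- tryCatch(
      antoine_record(row$antoine_A, row$antoine_B, row$antoine_C,
                     row$antoine_dialect, row$t_min_K, row$t_max_K,
                     row$source),
      error = function(e) stop(sprintf("row %d ('%s'): %s", i, row$name,
                                       conditionMessage(e)), call. = FALSE))
    out[[i]] <- tryCatch(
      compound(row$name, row$family, row$mw_g_mol, rec, row$gamma_inf,
               if (is.na(row$odour_threshold_mg_L)) NA_real_
               else row$odour_threshold_mg_L,
               isTRUE(as.logical(row$off_flavour))),
      error = function(e) stop(sprintf("row %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
  }
  names(out) <- df$name
  out
}

# resolve a compound by name from a panel (named list of compound objects)
lookup_compound <- function(compounds, name) {
  cp <- compounds[[name]]
  if (is.null(cp))
    stop(sprintf("unknown compound '%s' (not in the property panel)", name),
         call. = FALSE)
  cp
}
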