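#' Integrate the volumetric CO2 evolution rate over time
#'
#' The rate trace is averaged between sequential data points and summed
#' over the period (trapezoidal rule):
#' `sum 0.5 (q_i + q_{i+1}) (t_{i+1} - t_i)`. Negative rates are allowed:
#' net CO2 evolution can be negative while anaplerotic carboxylation
#' (anaerobic succinate formation) fixes more CO2 than is released.
#'
#' @param time Strictly increasing times, h.
#' @param q_co2 Volumetric CO2 evolution rates, C-mol L-1 h-1.
#' @return Integrated CO2, C-mol L-1.
#' @examples
#' integrate_co2(c(0, 1), c(0, 2))  # 1.0
#' @export
integrate_co2 <- function(time, q_co2) {
  if (length(time) < 2)
    .stopf("need at least 2 points to integrate a rate trace")
  if (length(time) != length(q_co2))
    .stopf("time and q_co2 must have equal length")
  if (any(diff(time) <= 0))
    .stopf("time must be strictly increasing")
  sum(0.5 * (q_co2[-length(q_co2)] + q_co2[-1]) * diff(time))
}

#' Close the carbon balance of a fermentation
#'
#' Converts the net changes of glucose, biomass and organic acids plus
#' the integrated CO2 evolution into C-mol per litre and reports the
#' closure as C-mol of products per C-mol of glucose consumed. Carbon per
#' species: glucose 6, lactate 3, succinate 4, acetate 2 C per molecule;
#' biomass carbon as a constant dry-mass fraction (default 51.4 %) at
#' 12.011 g per C-mol.
#'
#' @param trace A [fermentation_trace]; the `co2_evolution_Cmol_L_h`
#'   column, if present, is integrated with [integrate_co2()].
#' @param carbon_content_biomass Carbon mass fraction of dry biomass.
#' @param normalize `"consumed"` divides by glucose consumed over the
#'   window (supports partial-consumption windows); `"initial"` divides
#'   by the initial glucose supply (the initial carbon source as 100 %).
#' @param until Optional time (h); the balance is closed over
#'   `[t_start, until]`.
#' @return An object of class `carbon_ledger`: C-mol L-1 entries
#'   `glucose_consumed`, `biomass`, `lactate`, `succinate`, `acetate`,
#'   `co2`, the per-species `fractions` (C-mol per C-mol of the
#'   denominator) and the `closure`.
#' @examples
#' tr <- simulate_fermentation(process_scenario(
#'   cv_biomass = 0, cv_metabolite = 0, cv_DO = 0))
#' close_balance(tr)$closure  # 1 by construction
#' @export
close_balance <- function(trace, carbon_content_biomass = .BIOMASS_C_FRACTION,
                          normalize = c("consumed", "initial"),
                          until = NULL) {
  stopifnot(inherits(trace, "fermentation_trace"))
  normalize <- match.arg(normalize)
  df <- as.data.frame(trace)
  if (!is.null(until)) df <- df[df$time_h <= until, , drop = FALSE]
  if (nrow(df) < 2) .stopf("need at least 2 samples to close a balance")
  n <- nrow(df)

  consumed_g <- df$glucose_g_L[1] - df$glucose_g_L[n]
  if (consumed_g <= 0) .stopf("no glucose consumed over the window")
  glucose_cmol <- consumed_g * .NC[["glucose"]] / .MM[["glucose"]]
  biomass_cmol <- (df$biomass_gDCW_L[n] - df$biomass_gDCW_L[1]) *
    carbon_content_biomass / .C_MOLAR_MASS
  prod_cmol <- vapply(.PRODUCTS, function(p) {
    col <- paste0(p, "_g_L")
    (df[[col]][n] - df[[col]][1]) * .NC[[p]] / .MM[[p]]
  }, numeric(1))
  co2_cmol <- if (all(is.finite(df$co2_evolution_Cmol_L_h)))
    integrate_co2(df$time_h, df$co2_evolution_Cmol_L_h) else 0

  den <- switch(normalize,
                consumed = glucose_cmol,
                initial = df$glucose_g_L[1] * .NC[["glucose"]] / .MM[["glucose"]])
  entries <- c(biomass = biomass_cmol, prod_cmol, co2 = co2_cmol)
  structure(list(glucose_consumed = glucose_cmol,
                 biomass = biomass_cmol,
                 lactate = prod_cmol[["lactate"]],
                 succinate = prod_cmol[["succinate"]],
                 acetate = prod_cmol[["acetate"]],
                 co2 = co2_cmol,
                 fractions = entries / den,
                 closure = sum(entries) / den,
                 normalize = normalize,
                 co2_method = "trapezoidal rule over Q_CO2"),
            class = "carbon_ledger")
}

#' @export
print.carbon_ledger <- function(x, ...) {
  cat("Carbon ledger (C-mol L-1):\n")
  for (nm in c("glucose_consumed", "biomass", "lactate", "succinate",
               "acetate", "co2"))
    cat(sprintf("  %-17s %9.5f\n", nm, x[[nm]]))
  cat(sprintf("  closure: %.4f C-mol per C-mol glucose (%s; CO2 by %s)\n",
              x$closure, x$normalize, x$co2_method))
  invisible(x)
}
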