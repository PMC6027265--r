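#' Default phase parameters of the triple-phase reference process
#'
#' Phase-wise specific growth rates, biomass yields and product yields of
#' the *C. glutamicum* triple-phase batch fermentation (aerobic,
#' microaerobic, anaerobic). Growth rates are in h-1, `Y_XS` in g CDW per
#' g glucose, product yields in mol product per mol glucose.
#'
#' @return A data frame with one row per phase and columns `phase`, `mu`,
#'   `Y_XS`, `Y_PS_lactate`, `Y_PS_succinate`, `Y_PS_acetate`.
#' @examples
#' default_phase_params()
#' @export
default_phase_params <- function() {
  data.frame(
    phase          = c("aerobic", "microaerobic", "anaerobic"),
    mu             = c(0.40, 0.21, 0.09),
    Y_XS           = c(0.52, 0.29, 0.16),
    Y_PS_lactate   = c(0.03, 0.49, 1.39),
    Y_PS_succinate = c(0.00, 0.22, 0.37),
    Y_PS_acetate   = c(0.00, 0.31, 0.13),
    stringsAsFactors = FALSE
  )
}

#' Define a triple-phase fermentation scenario
#'
#' A scenario bundles everything the synthetic-process generator needs:
#' piecewise-constant phase stoichiometry, initial state, the aeration-stop
#' time that starts the anaerobic phase, the sampling grid, relative noise
#' levels and a seed. The defaults reproduce the reference triple-phase
#' batch process (10 L working volume, 60 g glucose L-1, anaerobic switch
#' after 11 h of cultivation, starting biomass 0.4 g CDW L-1).
#'
#' Within each phase, biomass grows exponentially at the phase `mu`,
#' glucose consumption follows `Y_XS`, and products accumulate with the
#' molar yields `Y_PS_*`. The boundary between the aerobic and the
#' microaerobic phase is placed where a noise-free product concentration
#' first crosses `product_threshold` (the operational definition of
#' organic-acid onset); the anaerobic phase starts at
#' `anaerobic_switch_time`. CO2 evolution is the carbon residual of the
#' phase stoichiometry, so the noise-free carbon balance closes at exactly
#' 1.00 C-mol per C-mol glucose.
#'
#' @param phase_params Data frame as returned by [default_phase_params()].
#'   May contain one, two or three rows (aerobic, microaerobic, anaerobic
#'   in that order); later phases are only entered if their boundary
#'   occurs.
#' @param X0 Initial biomass, g CDW L-1.
#' @param S0 Initial glucose, g L-1.
#' @param V Working volume, L (carried as metadata; the balance is
#'   volumetric).
#' @param anaerobic_switch_time Time of the aeration stop, h; `NA` for a
#'   scenario without an anaerobic phase.
#' @param sampling_grid Strictly increasing sampling times, h.
#' @param cv_biomass,cv_metabolite,cv_DO Relative standard deviations of
#'   the multiplicative lognormal observation noise (each between 0 and
#'   0.5).
#'   `cv_metabolite` applies to glucose, the organic acids and the CO2
#'   evolution rate.
#' @param kla_surrogate Descriptive decay parameter (1/h) shaping the
#'   dissolved-oxygen trace; not a mechanistic oxygen transfer model.
#' @param do_zero_time Time (h) at which the DO trace reaches 0 % of
#'   saturation; must lie before the microaerobic onset.
#' @param product_threshold Detection threshold (g L-1) used to place the
#'   aerobic/microaerobic boundary of the noise-free model.
#' @param seed Integer seed for the observation noise.
#' @return An object of class `process_scenario`.
#' @seealso [simulate_fermentation()]
#' @examples
#' sc <- process_scenario(cv_biomass = 0, cv_metabolite = 0, cv_DO = 0)
#' tr <- simulate_fermentation(sc)
#' head(tr)
#' @export
process_scenario <- function(phase_params = default_phase_params(),
                             X0 = 0.4, S0 = 60, V = 10,
                             anaerobic_switch_time = 11,
                             sampling_grid = seq(0, 14, by = 0.25),
                             cv_biomass = 0.03, cv_metabolite = 0.03,
                             cv_DO = 0.03,
                             kla_surrogate = 0.5, do_zero_time = 5,
                             product_threshold = 0.10, seed = 1L) {
  stopifnot(is.data.frame(phase_params), nrow(phase_params) >= 1)
  need <- c("mu", "Y_XS", "Y_PS_lactate", "Y_PS_succinate", "Y_PS_acetate")
  miss <- setdiff(need, names(phase_params))
  if (length(miss))
    .stopf("phase_params lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(phase_params$mu < 0))
    .stopf("phase-specific growth rates must be >= 0")
  if (any(phase_params[need[-1]] < 0))
    .stopf("yields must be >= 0")
  if (any(phase_params$mu > 0 & phase_params$Y_XS <= 0))
    .stopf("a growing phase (mu > 0) needs Y_XS > 0")
  if (any(diff(sampling_grid) <= 0) || length(sampling_grid) < 2)
    .stopf("sampling_grid must be strictly increasing with >= 2 points")
  for (cv in c(cv_biomass, cv_metabolite, cv_DO))
    if (cv < 0 || cv > 0.5) .stopf("cv values must lie in [0, 0.5]")
  if (X0 <= 0 || S0 <= 0 || V <= 0)
    .stopf("X0, S0 and V must be positive")
  if (!is.na(anaerobic_switch_time) &&
      anaerobic_switch_time <= sampling_grid[1])
    .stopf("anaerobic_switch_time must lie after the first sampling time")
  structure(
    list(phase_params = phase_params, X0 = X0, S0 = S0, V = V,
         anaerobic_switch_time = anaerobic_switch_time,
         sampling_grid = sampling_grid,
         noise = list(cv_biomass = cv_biomass,
                      cv_metabolite = cv_metabolite, cv_DO = cv_DO),
         kla_surrogate = kla_surrogate, do_zero_time = do_zero_time,
         product_threshold = product_threshold, seed = seed),
    class = "process_scenario"
  )
}

#' @export
print.process_scenario <- function(x, ...) {
  cat("Triple-phase process scenario\n")
  cat(sprintf("  X0 = %.3g g CDW L-1, S0 = %.3g g L-1, V = %.3g L\n",
              x$X0, x$S0, x$V))
  cat(sprintf("  anaerobic switch at %s h; %d sampling points (%g-%g h)\n",
              format(x$anaerobic_switch_time), length(x$sampling_grid),
              min(x$sampling_grid), max(x$sampling_grid)))
  cat(sprintf("  noise cv: biomass %.3g, metabolite %.3g, DO %.3g; seed %d\n",
              x$noise$cv_biomass, x$noise$cv_metabolite, x$noise$cv_DO,
              x$seed))
  cat("  phase parameters:\n")
  print(x$phase_params, row.names = FALSE)
  invisible(x)
}

## CO2 carbon residual of a phase, C-mol CO2 per mol glucose:
## 6 C-mol in minus biomass carbon minus product carbon.
## Negative values mean net CO2 fixation (anaerobic succinate formation
## consumes CO2 through anaplerotic carboxylation).
.co2_residual <- function(p) {
  biomass_c <- if (p$mu > 0 || p$Y_XS > 0)
    p$Y_XS * .MM[["glucose"]] * .BIOMASS_C_FRACTION / .C_MOLAR_MASS else 0
  prod_c <- p$Y_PS_lactate * .NC[["lactate"]] +
    p$Y_PS_succinate * .NC[["succinate"]] +
    p$Y_PS_acetate * .NC[["acetate"]]
  .NC[["glucose"]] - biomass_c - prod_c
}
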