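#' Fit phase-wise kinetics of a triple-phase fermentation
#'
#' The central model fit of the package: segments a fermentation trace
#' into the aerobic, microaerobic and anaerobic windows
#' ([segment_phases()]) and estimates, per phase, the specific growth
#' rate `mu` (semi-logarithmic regression with R-squared window
#' maximization, [fit_growth_rate()]), the biomass yield `Y_X/S` and the
#' three product yields `Y_P/S` ([fit_yield()]), and the specific
#' substrate uptake rate `q_S = mu / Y_X/S` with Gaussian error
#' propagation ([compute_qs()]).
#'
#' @param trace A [fermentation_trace].
#' @param product_threshold Organic-acid onset threshold, g L-1.
#' @param min_points Minimal sub-window size for the growth-rate search.
#' @param t_anaer Optional explicit anaerobic start time, h.
#' @return An object of class `phase_kinetics` with components
#'   `segmentation`, `estimates` (a list per phase of `kinetic_estimate`
#'   objects) and `trace`. Supported methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `simulate`, `plot`.
#' @examples
#' tr <- simulate_fermentation(process_scenario(seed = 11))
#' fit <- fit_phase_kinetics(tr)
#' print(fit)
#' coef(fit)
#' @export
fit_phase_kinetics <- function(trace, product_threshold = 0.10,
                               min_points = 4, t_anaer = NULL) {
  seg <- segment_phases(trace, product_threshold, t_anaer)
  phases <- c("aerobic", "microaerobic", "anaerobic")
  est <- list()
  for (ph in phases) {
    w <- seg[[ph]]
    if (is.null(w)) next
    idx <- .window_idx(trace, w)
    if (length(idx) < 3) {
      .warnf("phase %s has only %d samples; skipped", ph, length(idx))
      next
    }
    win <- range(trace$time_h[idx])
    e <- list()
    e$mu <- tryCatch(fit_growth_rate(trace, win, min_points),
                     error = function(err) NULL)
    e$Y_XS <- tryCatch(fit_yield(trace, win, "biomass"),
                       error = function(err) NULL)
    for (p in .PRODUCTS)
      e[[paste0("Y_PS_", p)]] <- tryCatch(
        fit_yield(trace, win, "product", p), error = function(err) NULL)
    if (!is.null(e$mu) && !is.null(e$Y_XS) && e$Y_XS$value > 0)
      e$q_S <- compute_qs(e$mu, e$Y_XS)
    for (nm in names(e)) if (!is.null(e[[nm]])) e[[nm]]$phase <- ph
    est[[ph]] <- e
  }
  structure(list(segmentation = seg, estimates = est, trace = trace,
                 call = match.call()),
            class = "phase_kinetics")
}

#' @export
coef.phase_kinetics <- function(object, ...) {
  qs <- c("mu", "Y_XS", "Y_PS_lactate", "Y_PS_succinate", "Y_PS_acetate",
          "q_S")
  phases <- names(object$estimates)
  out <- matrix(NA_real_, length(phases), length(qs),
                dimnames = list(phases, qs))
  for (ph in phases)
    for (q in qs)
      if (!is.null(object$estimates[[ph]][[q]]))
        out[ph, q] <- object$estimates[[ph]][[q]]$value
  out
}

#' Phase summary table of a kinetics fit
#'
#' @param object A `phase_kinetics` fit.
#' @param digits Decimals for the report convention (rounding half up);
#'   use `NULL` for full precision.
#' @param ... Unused.
#' @return `summary()` returns a data frame with one row per phase and
#'   `value +- stderr` pairs for every estimated quantity.
#' @export
summary.phase_kinetics <- function(object, digits = 2, ...) {
  qs <- c("mu", "Y_XS", "q_S", "Y_PS_lactate", "Y_PS_succinate",
          "Y_PS_acetate")
  rows <- lapply(names(object$estimates), function(ph) {
    e <- object$estimates[[ph]]
    vals <- lapply(qs, function(q) {
      if (is.null(e[[q]])) c(NA_real_, NA_real_)
      else c(e[[q]]$value, e[[q]]$stderr)
    })
    v <- unlist(vals)
    if (!is.null(digits)) v <- .round_half_up(v, digits)
    stats::setNames(as.data.frame(t(v)),
                    as.vector(rbind(qs, paste0(qs, "_sd"))))
  })
  out <- cbind(phase = names(object$estimates), do.call(rbind, rows))
  rownames(out) <- NULL
  structure(out, class = c("phase_kinetics_summary", "data.frame"),
            segmentation = object$segmentation)
}

#' @export
print.phase_kinetics_summary <- function(x, ...) {
  cat("Phase-wise kinetic estimates (value +- SD):\n")
  fmt <- function(v, s) ifelse(is.na(v), "-",
                               sprintf("%.2f +- %.2f", v, s))
  df <- data.frame(
    phase = x$phase,
    `mu_1_h` = fmt(x$mu, x$mu_sd),
    `Y_XS_g_g` = fmt(x$Y_XS, x$Y_XS_sd),
    `q_S_g_g_h` = fmt(x$q_S, x$q_S_sd),
    `Y_lac_mol_mol` = fmt(x$Y_PS_lactate, x$Y_PS_lactate_sd),
    `Y_suc_mol_mol` = fmt(x$Y_PS_succinate, x$Y_PS_succinate_sd),
    `Y_ace_mol_mol` = fmt(x$Y_PS_acetate, x$Y_PS_acetate_sd),
    check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.phase_kinetics <- function(x, ...) {
  print(x$segmentation)
  print(summary(x))
  invisible(x)
}

## noise-free model reconstruction from the fitted parameters, using the
## observed state at each phase start as initial condition
.fitted_model <- function(object) {
  tr <- object$trace
  est <- object$estimates
  phases <- names(est)
  seg <- object$segmentation
  pieces <- lapply(phases, function(ph) {
    w <- seg[[ph]]
    idx <- .window_idx(tr, w)
    e <- est[[ph]]
    list(phase = ph, t0 = tr$time_h[idx[1]], t1 = w[2],
         X0 = tr$biomass_gDCW_L[idx[1]], S0 = tr$glucose_g_L[idx[1]],
         P0 = sapply(.PRODUCTS, function(p) tr[[paste0(p, "_g_L")]][idx[1]]),
         mu = if (!is.null(e$mu)) e$mu$value else 0,
         Y_XS = if (!is.null(e$Y_XS)) e$Y_XS$value else NA_real_,
         Y_PS = sapply(.PRODUCTS, function(p) {
           k <- paste0("Y_PS_", p)
           if (!is.null(e[[k]])) e[[k]]$value else 0
         }))
  })
  pieces
}

#' @export
predict.phase_kinetics <- function(object, newdata = NULL, ...) {
  times <- if (is.null(newdata)) object$trace$time_h
           else if (is.data.frame(newdata)) newdata$time_h else newdata
  pieces <- .fitted_model(object)
  out <- data.frame(time_h = times, biomass_gDCW_L = NA_real_,
                    glucose_g_L = NA_real_, lactate_g_L = NA_real_,
                    succinate_g_L = NA_real_, acetate_g_L = NA_real_)
  for (k in seq_along(pieces)) {
    pc <- pieces[[k]]
    last <- k == length(pieces)
    sel <- times >= pc$t0 & (times < pc$t1 | (last & times <= pc$t1))
    if (!any(sel)) next
    X <- pc$X0 * exp(pc$mu * (times[sel] - pc$t0))
    dS <- if (pc$mu > 0 && is.finite(pc$Y_XS) && pc$Y_XS > 0)
      (X - pc$X0) / pc$Y_XS else 0
    out$biomass_gDCW_L[sel] <- X
    out$glucose_g_L[sel] <- pc$S0 - dS
    for (p in .PRODUCTS)
      out[[paste0(p, "_g_L")]][sel] <- pc$P0[[p]] +
        pc$Y_PS[[p]] * (dS / .MM[["glucose"]]) * .MM[[p]]
  }
  out
}

#' @export
residuals.phase_kinetics <- function(object, ...) {
  obs <- as.data.frame(object$trace)
  fit <- predict(object)
  cols <- c("biomass_gDCW_L", "glucose_g_L", "lactate_g_L",
            "succinate_g_L", "acetate_g_L")
  res <- obs[cols] - fit[cols]
  cbind(time_h = obs$time_h, res)
}

#' Simulate new traces from a fitted phase-kinetics model
#'
#' Builds a [process_scenario()] from the fitted phase parameters (initial
#' state and switch time taken from the underlying trace) and draws new
#' noisy traces from it.
#'
#' @param object A `phase_kinetics` fit.
#' @param nsim Number of traces.
#' @param seed Integer seed.
#' @param cv Relative noise level applied to all observation channels.
#' @param ... Unused.
#' @return A list of `nsim` [fermentation_trace] objects.
#' @export
simulate.phase_kinetics <- function(object, nsim = 1, seed = 1L,
                                    cv = 0.03, ...) {
  co <- coef(object)
  pp <- data.frame(phase = rownames(co), mu = co[, "mu"],
                   Y_XS = co[, "Y_XS"],
                   Y_PS_lactate = co[, "Y_PS_lactate"],
                   Y_PS_succinate = co[, "Y_PS_succinate"],
                   Y_PS_acetate = co[, "Y_PS_acetate"],
                   stringsAsFactors = FALSE)
  pp[is.na(pp)] <- 0
  tr <- object$trace
  lapply(seq_len(nsim), function(i) {
    sc <- process_scenario(
      phase_params = pp, X0 = tr$biomass_gDCW_L[1], S0 = tr$glucose_g_L[1],
      anaerobic_switch_time = object$segmentation$anaerobic[1],
      sampling_grid = tr$time_h,
      cv_biomass = cv, cv_metabolite = cv, cv_DO = cv,
      product_threshold = object$segmentation$product_threshold,
      seed = seed + i - 1L)
    simulate_fermentation(sc)
  })
}

#' @export
plot.phase_kinetics <- function(x, ...) {
  tr <- x$trace
  fit <- predict(x)
  old <- graphics::par(mar = c(4, 4, 1, 4))
  on.exit(graphics::par(old))
  graphics::plot(tr$time_h, tr$glucose_g_L, pch = 1, col = "grey30",
                 xlab = "time (h)", ylab = "concentration (g/L)",
                 ylim = c(0, max(tr$glucose_g_L) * 1.05), ...)
  graphics::lines(fit$time_h, fit$glucose_g_L, col = "grey30")
  cols <- c(lactate = "firebrick", succinate = "steelblue",
            acetate = "darkgreen")
  for (p in .PRODUCTS) {
    graphics::points(tr$time_h, tr[[paste0(p, "_g_L")]], pch = 2,
                     col = cols[[p]])
    graphics::lines(fit$time_h, fit[[paste0(p, "_g_L")]], col = cols[[p]])
  }
  graphics::points(tr$time_h, tr$biomass_gDCW_L, pch = 16)
  graphics::lines(fit$time_h, fit$biomass_gDCW_L)
  for (b in c(x$segmentation$aerobic[2], x$segmentation$anaerobic[1]))
    graphics::abline(v = b, lty = 2, col = "grey60")
  graphics::legend("topright", bty = "n", pch = c(16, 1, 2, 2, 2),
                   col = c("black", "grey30", cols),
                   legend = c("biomass", "glucose", .PRODUCTS))
  invisible(x)
}
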