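## ---- kinetic_estimate ------------------------------------------------------

.kinetic_estimate <- function(name, value, stderr, units, phase = NA_character_,
                              fit_window = c(NA_real_, NA_real_),
                              n_points = NA_integer_, r_squared = NA_real_) {
  structure(list(name = name, value = value, stderr = stderr, units = units,
                 phase = phase, fit_window = fit_window,
                 n_points = n_points, r_squared = r_squared),
            class = "kinetic_estimate")
}

#' @export
print.kinetic_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4g +- %.3g %s", x$name, x$value, x$stderr, x$units))
  if (!is.na(x$phase)) cat(sprintf("  [%s]", x$phase))
  if (!any(is.na(x$fit_window)))
    cat(sprintf("  (window %.3g-%.3g h, n = %d, R2 = %.4f)",
                x$fit_window[1], x$fit_window[2], x$n_points, x$r_squared))
  cat("\n")
  invisible(x)
}

## ---- phase segmentation ----------------------------------------------------

#' Segment a fermentation trace into the three oxygen phases
#'
#' The microaerobic phase starts at the first time any organic acid
#' (lactate, succinate or acetate) exceeds `product_threshold`, with
#' linear interpolation between the bracketing samples — the operational
#' definition of oxygen limitation by organic-acid onset. The anaerobic
#' phase starts at the `aeration_stop` event (or an explicit `t_anaer`).
#' Windows are half-open: a sample exactly on a boundary belongs to the
#' later phase.
#'
#' @param trace A [fermentation_trace].
#' @param product_threshold Onset threshold, g L-1.
#' @param t_anaer Anaerobic start time, h; defaults to the trace's
#'   `aeration_stop` event. Required if no such event is present.
#' @return An object of class `phase_segmentation`: a list with elements
#'   `aerobic`, `microaerobic` (possibly `NULL`), `anaerobic`, each a
#'   `c(start, end)` pair in h, plus the rules that produced each
#'   boundary.
#' @examples
#' tr <- simulate_fermentation(process_scenario(seed = 3))
#' segment_phases(tr)
#' @export
segment_phases <- function(trace, product_threshold = 0.10, t_anaer = NULL) {
  stopifnot(inherits(trace, "fermentation_trace"))
  tt <- trace$time_h
  if (is.null(t_anaer)) {
    ev <- attr(trace, "events")
    hit <- if (!is.null(ev)) ev$time[ev$label == "aeration_stop"] else numeric(0)
    if (!length(hit))
      .stopf("no aeration_stop event in the trace: supply t_anaer explicitly")
    t_anaer <- hit[1]
  }

  ## earliest interpolated threshold crossing over the three products
  t_micro <- NA_real_
  for (prod in .PRODUCTS) {
    y <- trace[[paste0(prod, "_g_L")]]
    above <- which(y > product_threshold)
    if (!length(above)) next
    i <- above[1]
    tc <- if (i == 1) tt[1] else {
      tt[i - 1] + (product_threshold - y[i - 1]) / (y[i] - y[i - 1]) *
        (tt[i] - tt[i - 1])
    }
    if (is.na(t_micro) || tc < t_micro) t_micro <- tc
  }
  if (!is.na(t_micro) && t_micro >= t_anaer) t_micro <- NA_real_

  t0 <- tt[1]; t1 <- tt[length(tt)]
  if (is.na(t_micro)) {
    .warnf("no product exceeds %.3g g/L while aerated: empty microaerobic window",
           product_threshold)
    seg <- list(aerobic = c(t0, t_anaer), microaerobic = NULL,
                anaerobic = c(t_anaer, t1))
  } else {
    seg <- list(aerobic = c(t0, t_micro), microaerobic = c(t_micro, t_anaer),
                anaerobic = c(t_anaer, t1))
  }
  seg$t_micro_rule <- sprintf(
    "first organic acid > %.3g g/L (linear interpolation)", product_threshold)
  seg$t_anaer_rule <- "aeration_stop event"
  seg$product_threshold <- product_threshold
  ## sample counts per phase (half-open windows)
  seg$n_per_phase <- vapply(seg[c("aerobic", "microaerobic", "anaerobic")],
                            function(w) {
                              if (is.null(w)) return(0L)
                              sum(tt >= w[1] & (tt < w[2] | w[2] == t1))
                            }, integer(1))
  if (any(seg$n_per_phase[c(1, 3)] < 3))
    .warnf("fewer than 3 samples in a phase window; estimates will be unreliable")
  class(seg) <- "phase_segmentation"
  seg
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("Phase segmentation (h):\n")
  for (ph in c("aerobic", "microaerobic", "anaerobic")) {
    w <- x[[ph]]
    if (is.null(w)) cat(sprintf("  %-12s (empty)\n", ph))
    else cat(sprintf("  %-12s [%6.3f, %6.3f)  n = %d\n", ph, w[1], w[2],
                     x$n_per_phase[[ph]]))
  }
  cat("  rules:", x$t_micro_rule, "/", x$t_anaer_rule, "\n")
  invisible(x)
}

## indices of trace samples inside a window; half-open unless the window
## end coincides with the last sample time
.window_idx <- function(trace, window, closed_end = NULL) {
  tt <- trace$time_h
  if (is.null(closed_end)) closed_end <- window[2] >= tt[length(tt)]
  if (closed_end) which(tt >= window[1] & tt <= window[2])
  else which(tt >= window[1] & tt < window[2])
}

## ---- growth rate: semi-log regression with R2-maximizing window search ----

#' Estimate the specific growth rate by semi-logarithmic regression
#'
#' Fits `ln(biomass) ~ time` and locates the exponential growth phase
#' inside `window` by an R-squared maximization strategy over contiguous
#' sample sub-windows. Two operationalizations are available:
#'
#' * `method = "guarded"` (default): start from the full window and trim
#'   to a sub-window only when the sub-window's line fits significantly
#'   better, judged by a nested F-test on the excluded points
#'   (Bonferroni-corrected across candidate sub-windows, level `alpha`).
#'   On data that are exponential throughout, the full window is kept
#'   (up to the test level) and the slope estimate is unbiased; genuine
#'   breakpoints (lag phase, phase transitions) are trimmed away because
#'   the deviation of the excluded points is then overwhelming.
#' * `method = "exhaustive"`: return the sub-window with the literally
#'   maximal R-squared (ties within 1e-12 broken by more points, then
#'   the earlier start). Note that on noisy single-phase data this
#'   selection systematically favours windows where noise steepens the
#'   slope and therefore overestimates `mu`; it is provided for
#'   comparison.
#'
#' Sub-windows containing non-positive biomass are excluded.
#'
#' @param trace A [fermentation_trace].
#' @param window `c(t0, t1)` in h; samples with `t0 <= time <= t1` are
#'   candidates.
#' @param min_points Minimal number of samples per sub-window (>= 2).
#' @param method Window-search variant, see above.
#' @param alpha Test level of the trimming guard.
#' @return A `kinetic_estimate` with the slope as `mu` (h-1), its
#'   regression standard error, the selected window, `n_points` and
#'   `r_squared`.
#' @examples
#' tr <- simulate_fermentation(process_scenario(
#'   cv_biomass = 0, cv_metabolite = 0, cv_DO = 0))
#' fit_growth_rate(tr, window = c(0, 5), min_points = 4)
#' @export
fit_growth_rate <- function(trace, window, min_points = 4,
                            method = c("guarded", "exhaustive"),
                            alpha = 0.001) {
  stopifnot(inherits(trace, "fermentation_trace"), min_points >= 2)
  method <- match.arg(method)
  idx <- which(trace$time_h >= window[1] & trace$time_h <= window[2])
  x <- trace$time_h[idx]
  b <- trace$biomass_gDCW_L[idx]
  ok <- is.finite(b) & b > 0
  if (sum(ok) < min_points)
    .stopf("fewer than %d samples with positive biomass in [%.3g, %.3g]",
           min_points, window[1], window[2])

  ## restrict to contiguous runs of positive biomass
  runs <- rle(ok)
  pos <- cumsum(c(1, runs$lengths))
  best <- NULL
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r] || runs$lengths[r] < min_points) next
    lo <- pos[r]; hi <- pos[r + 1] - 1
    cand <- if (method == "exhaustive")
      .search_exhaustive(x[lo:hi], log(b[lo:hi]), min_points)
    else
      .search_guarded(x[lo:hi], log(b[lo:hi]), min_points, alpha)
    if (is.null(cand)) next
    cand$i <- cand$i + lo - 1L
    cand$j <- cand$j + lo - 1L
    if (is.null(best) || cand$r2 > best$r2 + 1e-12 ||
        (abs(cand$r2 - best$r2) <= 1e-12 &&
         (cand$j - cand$i) > (best$j - best$i)))
      best <- cand
  }
  if (is.null(best))
    .stopf("no contiguous sub-window of %d positive-biomass samples in [%.3g, %.3g]",
           min_points, window[1], window[2])
  .kinetic_estimate("mu", best$slope, best$se, "1/h",
                    fit_window = c(x[best$i], x[best$j]),
                    n_points = best$j - best$i + 1L, r_squared = best$r2)
}

## regression statistics of window [i, j] from cumulative sums, O(1) each
.win_env <- function(xs, ys) {
  list(cx = cumsum(xs), cy = cumsum(ys), cxx = cumsum(xs^2),
       cyy = cumsum(ys^2), cxy = cumsum(xs * ys))
}

## vectorized over j; returns slope, sse, r2, se for windows [i, js]
.win_stats <- function(env, i, js) {
  at <- function(cs) cs[js] - if (i > 1) cs[i - 1] else 0
  nn <- js - i + 1
  Sx <- at(env$cx); Sy <- at(env$cy)
  Sxx <- at(env$cxx); Syy <- at(env$cyy); Sxy <- at(env$cxy)
  sxx <- Sxx - Sx^2 / nn
  syy <- pmax(Syy - Sy^2 / nn, 0)
  sxy <- Sxy - Sx * Sy / nn
  slope <- sxy / sxx
  sse <- pmax(syy - slope * sxy, 0)
  r2 <- ifelse(syy <= .Machine$double.eps * (abs(Syy) + 1), 1,
               pmin(1 - sse / syy, 1))
  se <- ifelse(nn > 2, sqrt(sse / pmax(nn - 2, 1) / sxx), 0)
  list(n = nn, slope = slope, sse = sse, r2 = r2, se = se)
}

.search_exhaustive <- function(xs, ys, min_points) {
  m <- length(xs)
  env <- .win_env(xs, ys)
  best <- NULL
  tol <- 1e-12
  for (i in 1:(m - min_points + 1)) {
    js <- (i + min_points - 1):m
    st <- .win_stats(env, i, js)
    for (k in seq_along(js)) {
      cand <- list(i = i, j = js[k], slope = st$slope[k], se = st$se[k],
                   r2 = st$r2[k])
      if (is.null(best) || cand$r2 > best$r2 + tol ||
          (abs(cand$r2 - best$r2) <= tol &&
           ((cand$j - cand$i) > (best$j - best$i) ||
            ((cand$j - cand$i) == (best$j - best$i) && cand$i < best$i))))
        best <- cand
    }
  }
  best
}

## iterative trimming: keep the current window unless some sub-window's
## line fits the retained points significantly better than the current
## line fits all of them (nested F-test on the excluded points,
## Bonferroni-corrected across candidates)
.search_guarded <- function(xs, ys, min_points, alpha) {
  m <- length(xs)
  env <- .win_env(xs, ys)
  cur <- c(1L, m)
  repeat {
    n_cur <- cur[2] - cur[1] + 1L
    st_cur <- .win_stats(env, cur[1], cur[2])
    if (n_cur <= min_points) break
    ## enumerate strict sub-windows with >= max(min_points, 3) points
    msz <- max(min_points, 3L)
    hit <- NULL
    n_cand <- 0L
    for (i in cur[1]:(cur[2] - msz + 1L)) {
      js <- (i + msz - 1L):cur[2]
      js <- js[!(i == cur[1] & js == cur[2])]
      if (!length(js)) next
      st <- .win_stats(env, i, js)
      df2 <- st$n - 2
      keep <- df2 >= 1
      n_cand <- n_cand + sum(keep)
      Fst <- ((st_cur$sse - st$sse) / (n_cur - st$n)) / (st$sse / df2)
      Fst[st$sse == 0 & st_cur$sse > 0] <- Inf
      Fst[st_cur$sse <= st$sse] <- 0
      p <- stats::pf(Fst, n_cur - st$n, df2, lower.tail = FALSE)
      p[is.infinite(Fst)] <- 0
      for (k in seq_along(js)) {
        if (!keep[k]) next
        cand <- list(i = i, j = js[k], p = p[k], n = st$n[k])
        if (is.null(hit) || cand$p < hit$p ||
            (cand$p == hit$p && (cand$n > hit$n ||
                                 (cand$n == hit$n && cand$i < hit$i))))
          hit <- cand
      }
    }
    if (is.null(hit) || hit$p * n_cand >= alpha) break
    cur <- c(hit$i, hit$j)
  }
  st <- .win_stats(env, cur[1], cur[2])
  list(i = cur[1], j = cur[2], slope = st$slope, se = st$se, r2 = st$r2)
}

## ---- yields ---------------------------------------------------------------

#' Estimate a biomass or product yield from a fermentation window
#'
#' Estimates `Y_X/S` (g CDW per g glucose) or `Y_P/S` (mol product per
#' mol glucose) by linear regression of the numerator concentration
#' versus the glucose concentration within the window; the yield is the
#' slope magnitude. Because both concentrations carry roughly relative
#' measurement error, ordinary least squares is attenuated when the
#' regressor's spread is small compared to its absolute level
#' (errors-in-variables); the regression is therefore oriented onto
#' whichever of the two variables has the larger relative spread
#' (`sd/mean`), and the slope is inverted when glucose ends up as the
#' response, with a second-order ratio bias correction on the inversion.
#' Both orientations are identical on noise-free data. Product slopes
#' are converted from g/g to mol/mol via the molar masses.
#'
#' @param trace A [fermentation_trace].
#' @param window `c(t0, t1)` in h.
#' @param numerator `"biomass"` or `"product"`.
#' @param product_name For `numerator = "product"`: `"lactate"`,
#'   `"succinate"` or `"acetate"`.
#' @return A `kinetic_estimate` (`Y_XS` in g g-1 or `Y_PS_<product>` in
#'   mol mol-1) with standard error and R-squared.
#' @examples
#' tr <- fermentation_trace(time = 0:2, biomass = c(0.4, 5.6, 10.8),
#'                          glucose = c(60, 50, 40))
#' fit_yield(tr, c(0, 2), "biomass")  # 10.4 / 20 = 0.52
#' @export
fit_yield <- function(trace, window,
                      numerator = c("biomass", "product"),
                      product_name = NULL) {
  stopifnot(inherits(trace, "fermentation_trace"))
  numerator <- match.arg(numerator)
  if (numerator == "product") {
    if (is.null(product_name) || !product_name %in% .PRODUCTS)
      .stopf("product_name must be one of %s", paste(.PRODUCTS, collapse = ", "))
    ycol <- paste0(product_name, "_g_L")
    name <- paste0("Y_PS_", product_name)
    units <- "mol mol-1"
    molfac <- .MM[["glucose"]] / .MM[[product_name]]
  } else {
    ycol <- "biomass_gDCW_L"
    name <- "Y_XS"
    units <- "g g-1"
    molfac <- 1
  }
  idx <- which(trace$time_h >= window[1] & trace$time_h <= window[2])
  if (length(idx) < 3)
    .stopf("need >= 3 samples in the window for a yield regression")
  s <- trace$glucose_g_L[idx]
  u <- trace[[ycol]][idx]
  if (stats::var(s) == 0)
    .stopf("glucose is constant in the window; yield undefined")
  if (stats::var(u) == 0) {
    ## nothing formed while glucose changes: yield is exactly zero
    return(.kinetic_estimate(name, 0, 0, units,
                             fit_window = range(trace$time_h[idx]),
                             n_points = length(idx), r_squared = NA_real_))
  }
  n <- length(idx)
  suu <- sum((u - mean(u))^2)
  sus <- sum((u - mean(u)) * (s - mean(s)))
  sss <- sum((s - mean(s))^2)
  ## orient onto the variable with the larger relative spread
  rel_spread_u <- sqrt(suu / (n - 1)) / abs(mean(u))
  rel_spread_s <- sqrt(sss / (n - 1)) / abs(mean(s))
  if (rel_spread_s >= rel_spread_u) {
    ## numerator ~ glucose: yield = |slope| directly
    slope <- sus / sss
    sse <- max(suu - slope * sus, 0)
    r2 <- 1 - sse / suu
    se_slope <- sqrt(sse / (n - 2) / sss)
    y_gg <- abs(slope)
    rel <- if (y_gg > 0) se_slope / y_gg else 0
  } else {
    ## glucose ~ numerator: yield = 1/|slope|, ratio-bias corrected
    slope <- sus / suu
    sse <- max(sss - slope * sus, 0)
    r2 <- if (sss > 0) 1 - sse / sss else NA_real_
    se_slope <- sqrt(sse / (n - 2) / suu)
    if (slope == 0)
      .stopf("glucose does not respond to %s in the window; yield undefined",
             name)
    rel <- se_slope / abs(slope)
    y_gg <- (1 / abs(slope)) / (1 + rel^2)
  }
  value <- y_gg * molfac
  .kinetic_estimate(name, value, value * rel, units,
                    fit_window = range(trace$time_h[idx]),
                    n_points = n, r_squared = min(max(r2, 0), 1))
}

## ---- specific substrate uptake --------------------------------------------

#' Biomass-specific substrate consumption rate with error propagation
#'
#' `q_S = mu / Y_X/S`, with the standard error from Gaussian error
#' propagation: `sigma_q = sqrt((sigma_mu / Y)^2 + (mu sigma_Y / Y^2)^2)`.
#'
#' @param mu,yxs `kinetic_estimate` objects (or numeric `c(value, stderr)`
#'   pairs) for the growth rate and the biomass yield; `yxs` must be
#'   positive.
#' @return A `kinetic_estimate` for `q_S` in g g-1 h-1.
#' @examples
#' q <- compute_qs(c(0.40, 0.01), c(0.52, 0.04))
#' round(c(q$value, q$stderr), 2)  # 0.77 0.06
#' @export
compute_qs <- function(mu, yxs) {
  as_pair <- function(e) {
    if (inherits(e, "kinetic_estimate")) c(e$value, e$stderr)
    else if (is.numeric(e) && length(e) == 2) e
    else .stopf("expected a kinetic_estimate or c(value, stderr)")
  }
  m <- as_pair(mu); y <- as_pair(yxs)
  if (y[1] <= 0) .stopf("Y_X/S must be > 0 to compute q_S")
  value <- m[1] / y[1]
  stderr <- sqrt((m[2] / y[1])^2 + (m[1] * y[2] / y[1]^2)^2)
  phase <- if (inherits(mu, "kinetic_estimate")) mu$phase else NA_character_
  .kinetic_estimate("q_S", value, stderr, "g g-1 h-1", phase = phase)
}
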