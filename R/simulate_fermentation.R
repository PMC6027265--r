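#' Simulate a triple-phase batch fermentation
#'
#' Generates noisy observations of a piecewise-exponential batch process
#' on the scenario's sampling grid. Within each phase biomass grows
#' exponentially at the phase-specific rate; glucose consumption follows
#' the biomass yield, the organic acids follow their molar product yields,
#' and CO2 evolution is the carbon residual of the phase stoichiometry so
#' that the noise-free carbon balance closes at exactly 1.00 C-mol per
#' C-mol glucose at every time point. The dissolved-oxygen column is a
#' descriptive monotone decay reaching 0 % before the microaerobic onset.
#'
#' Phase boundaries of the generating model: the aerobic phase ends when a
#' noise-free product concentration first crosses the scenario's
#' `product_threshold` (organic-acid onset); the anaerobic phase starts at
#' `anaerobic_switch_time` (the aeration stop). Both boundaries, together
#' with the generating parameters, are carried in the trace's `truth`
#' attribute.
#'
#' The emitted CO2 evolution rate column is defined such that trapezoidal
#' integration over the sampling grid ([integrate_co2()]) reproduces the
#' model's cumulative CO2 exactly. In the anaerobic phase the net rate is
#' negative when anaplerotic carboxylation (succinate formation) fixes
#' more CO2 than decarboxylating reactions release.
#'
#' Observation noise is multiplicative, lognormal and mean-one with the
#' scenario's phase-independent cv values; it perturbs observations only,
#' never the underlying state.
#'
#' @param scenario A [process_scenario()].
#' @return A [fermentation_trace] with attributes `events` (the aeration
#'   stop), `truth` (true boundaries, phase parameters, scenario) and
#'   `clipped` (logical, `TRUE` if any noisy value had to be clipped).
#' @examples
#' tr <- simulate_fermentation(process_scenario(seed = 7))
#' attr(tr, "truth")$t_micro
#' @export
simulate_fermentation <- function(scenario) {
  stopifnot(inherits(scenario, "process_scenario"))
  pp <- scenario$phase_params
  grid <- scenario$sampling_grid
  t_end <- max(grid)
  t_anaer <- scenario$anaerobic_switch_time
  if (nrow(pp) < 3) t_anaer <- NA_real_   # no anaerobic phase defined

  ## --- aerobic -> microaerobic boundary: first noise-free threshold
  ## crossing of any product within phase 1 --------------------------------
  p1 <- as.list(pp[1, ])
  t_micro <- NA_real_
  if (nrow(pp) >= 2 && p1$mu > 0) {
    for (prod in .PRODUCTS) {
      y <- p1[[paste0("Y_PS_", prod)]]
      if (y <= 0) next
      ## product(t) = y * MM_p * (X(t) - X0) / (Y_XS * MM_glc) crosses theta
      Xc <- scenario$X0 + scenario$product_threshold * p1$Y_XS *
        .MM[["glucose"]] / (y * .MM[[prod]])
      tc <- log(Xc / scenario$X0) / p1$mu
      if (is.finite(tc) && tc > grid[1] && (is.na(t_micro) || tc < t_micro))
        t_micro <- tc
    }
  }
  if (!is.na(t_micro) && !is.na(t_anaer) && t_micro >= t_anaer)
    t_micro <- NA_real_   # onset never happens while aerated
  if (!is.na(t_micro) && t_micro >= t_end) t_micro <- NA_real_

  ## --- phase schedule: (start time, parameter row) ------------------------
  starts <- grid[1]
  rows <- 1L
  if (!is.na(t_micro)) { starts <- c(starts, t_micro); rows <- c(rows, 2L) }
  if (!is.na(t_anaer) && t_anaer < t_end) {
    starts <- c(starts, t_anaer)
    rows <- c(rows, nrow(pp))   # anaerobic row even if micro never started
  }
  ends <- c(starts[-1], t_end)

  ## --- propagate the noise-free state through the phases ------------------
  state <- list(X = scenario$X0, S = scenario$S0,
                P = setNames(numeric(3), .PRODUCTS), C = 0)
  ## closed-form state within phase k at time t (t >= starts[k])
  eval_phase <- function(state0, pr, t0, t) {
    X <- state0$X * exp(pr$mu * (t - t0))
    dS <- if (pr$mu > 0) (X - state0$X) / pr$Y_XS else rep(0, length(t))
    dSmol <- dS / .MM[["glucose"]]
    P <- sapply(.PRODUCTS, function(p)
      state0$P[[p]] + pr[[paste0("Y_PS_", p)]] * dSmol * .MM[[p]])
    if (is.null(dim(P))) P <- matrix(P, nrow = length(t),
                                     dimnames = list(NULL, .PRODUCTS))
    cres <- .co2_residual(pr)
    list(X = X, S = state0$S - dS, P = P, C = state0$C + cres * dSmol,
         rate = cres * pr$mu * X / (pr$Y_XS * .MM[["glucose"]]))
  }

  n <- length(grid)
  X <- S <- C <- rate <- numeric(n)
  P <- matrix(0, n, 3, dimnames = list(NULL, .PRODUCTS))
  for (k in seq_along(starts)) {
    pr <- as.list(pp[rows[k], ])
    idx <- which(grid >= starts[k] & grid <= ends[k])
    if (k < length(starts)) idx <- setdiff(idx, which(grid >= ends[k]))
    if (length(idx)) {
      ev <- eval_phase(state, pr, starts[k], grid[idx])
      X[idx] <- ev$X; S[idx] <- ev$S; P[idx, ] <- ev$P
      C[idx] <- ev$C; rate[idx] <- ev$rate
    }
    ## advance state to the end of this phase
    ev_end <- eval_phase(state, pr, starts[k], ends[k])
    state <- list(X = ev_end$X, S = ev_end$S,
                  P = setNames(drop(ev_end$P), .PRODUCTS), C = ev_end$C)
  }

  if (any(S <= 0)) {
    t_exh <- grid[which(S <= 0)[1]]
    where <- if (!is.na(t_anaer) && t_exh < t_anaer)
      "before the anaerobic switch" else "before the end of the grid"
    .stopf("glucose is exhausted at %.3g h, %s: shorten the sampling grid or raise S0",
           t_exh, where)
  }

  ## --- DO: descriptive shifted-exponential decay hitting 0 at do_zero_time
  k0 <- scenario$kla_surrogate
  tz <- scenario$do_zero_time
  DO <- ifelse(grid >= tz, 0,
               100 * (exp(-k0 * grid) - exp(-k0 * tz)) / (1 - exp(-k0 * tz)))

  ## --- CO2 rate column defined so the trapezoidal sum is exact ------------
  ## q[1] = instantaneous rate; 0.5*(q[i]+q[i+1])*dt[i] == C[i+1]-C[i]
  q <- numeric(n)
  q[1] <- rate[1]
  dt <- diff(grid)
  for (i in seq_len(n - 1)) q[i + 1] <- 2 * (C[i + 1] - C[i]) / dt[i] - q[i]

  ## --- observation noise ---------------------------------------------------
  cvs <- scenario$noise
  obs <- .with_seed(scenario$seed, {
    list(X = .lognoise(X, cvs$cv_biomass),
         S = .lognoise(S, cvs$cv_metabolite),
         P = apply(P, 2, .lognoise, cv = cvs$cv_metabolite),
         q = .lognoise(q, cvs$cv_metabolite),
         DO = pmin(100, .lognoise(DO, cvs$cv_DO)))
  })
  clipped <- any(unlist(obs[c("X", "S", "P")]) < 0)
  obs$X <- pmax(obs$X, 0); obs$S <- pmax(obs$S, 0); obs$P <- pmax(obs$P, 0)

  events <- if (!is.na(t_anaer))
    data.frame(time = t_anaer, label = "aeration_stop",
               stringsAsFactors = FALSE) else NULL
  out <- fermentation_trace(
    time = grid, biomass = obs$X, glucose = obs$S,
    lactate = obs$P[, "lactate"], succinate = obs$P[, "succinate"],
    acetate = obs$P[, "acetate"], DO = obs$DO, co2_rate = obs$q,
    events = events)
  attr(out, "truth") <- list(t_micro = t_micro, t_anaer = t_anaer,
                             phase_params = pp, scenario = scenario,
                             co2_cumulative = C)
  attr(out, "clipped") <- clipped
  if (clipped) .warnf("noisy concentrations below 0 were clipped at 0")
  out
}
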