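.TRACE_COLS <- c("time_h", "biomass_gDCW_L", "glucose_g_L", "lactate_g_L",
                 "succinate_g_L", "acetate_g_L", "DO_pct",
                 "co2_evolution_Cmol_L_h")

#' Construct a fermentation trace from process observations
#'
#' Assembles time-indexed process observations (biomass, glucose, organic
#' acids, optionally dissolved oxygen and the volumetric CO2 evolution
#' rate) plus labelled events into the container the kinetics and balance
#' functions operate on. Biomass may be supplied as OD600 together with a
#' CDW/OD conversion coefficient alpha (see [od_alpha()]).
#'
#' @param time Sampling times, h, strictly increasing.
#' @param biomass Biomass, g CDW L-1, or OD600 if `od_alpha_value` is given.
#' @param glucose,lactate,succinate,acetate Concentrations, g L-1.
#' @param DO Dissolved oxygen, percent of saturation (optional).
#' @param co2_rate Volumetric CO2 evolution rate, C-mol L-1 h-1 (optional;
#'   may be negative under net CO2 fixation).
#' @param events Data frame with columns `time` (h) and `label`
#'   (e.g. `"aeration_stop"`), or `NULL`.
#' @param od_alpha_value If not `NULL`, `biomass` is interpreted as OD600
#'   and multiplied by this coefficient (g CDW L-1 per OD unit).
#' @return A data frame of class `fermentation_trace` with the canonical
#'   columns `time_h`, `biomass_gDCW_L`, `glucose_g_L`, `lactate_g_L`,
#'   `succinate_g_L`, `acetate_g_L`, `DO_pct`, `co2_evolution_Cmol_L_h`
#'   and an `events` attribute.
#' @examples
#' tr <- fermentation_trace(time = 0:3, biomass = 0.4 * exp(0.4 * 0:3),
#'                          glucose = c(60, 59, 57.5, 55.3))
#' @export
fermentation_trace <- function(time, biomass, glucose,
                               lactate = 0, succinate = 0, acetate = 0,
                               DO = NA_real_, co2_rate = NA_real_,
                               events = NULL, od_alpha_value = NULL) {
  n <- length(time)
  if (n < 2 || any(diff(time) <= 0))
    .stopf("time must be strictly increasing with >= 2 points")
  if (!is.null(od_alpha_value)) {
    if (od_alpha_value <= 0) .stopf("the OD conversion alpha must be > 0")
    biomass <- biomass * od_alpha_value
  }
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else x
  df <- data.frame(
    time_h = time,
    biomass_gDCW_L = rep_n(biomass),
    glucose_g_L = rep_n(glucose),
    lactate_g_L = rep_n(lactate),
    succinate_g_L = rep_n(succinate),
    acetate_g_L = rep_n(acetate),
    DO_pct = rep_n(DO),
    co2_evolution_Cmol_L_h = rep_n(co2_rate)
  )
  conc <- df[c("biomass_gDCW_L", "glucose_g_L", "lactate_g_L",
               "succinate_g_L", "acetate_g_L")]
  if (any(unlist(conc) < 0, na.rm = TRUE))
    .stopf("concentrations must be >= 0")
  if (!is.null(events)) {
    stopifnot(is.data.frame(events), all(c("time", "label") %in% names(events)))
  }
  structure(df, events = events,
            class = c("fermentation_trace", "data.frame"))
}

#' @export
print.fermentation_trace <- function(x, ...) {
  tr <- attr(x, "truth")
  cat(sprintf("Fermentation trace: %d samples, %.3g-%.3g h\n",
              nrow(x), min(x$time_h), max(x$time_h)))
  ev <- attr(x, "events")
  if (!is.null(ev) && nrow(ev))
    cat("  events:", paste(sprintf("%s @ %.3g h", ev$label, ev$time),
                           collapse = ", "), "\n")
  if (!is.null(tr))
    cat(sprintf("  synthetic; true boundaries: microaerobic %.4g h, anaerobic %s h\n",
                tr$t_micro, format(tr$t_anaer)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...", nrow(x) - 4, "more rows\n")
  invisible(x)
}

#' Write / read a fermentation trace as tidy CSV
#'
#' `write_fermentation_trace()` writes the canonical columns plus an
#' `event` column (event label at matching times, empty otherwise). For a
#' synthetic trace the ground truth (boundaries, generating parameters) is
#' written to a JSON sidecar `<path>.truth.json`.
#' `read_fermentation_trace()` reverses both.
#'
#' @param trace A `fermentation_trace`.
#' @param path CSV file path.
#' @return `read_fermentation_trace()` returns a `fermentation_trace`;
#'   `write_fermentation_trace()` returns `path` invisibly.
#' @export
write_fermentation_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  ev <- attr(trace, "events")
  df$event <- ""
  if (!is.null(ev) && nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      i <- which.min(abs(df$time_h - ev$time[k]))
      df$event[i] <- ev$label[k]
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  tr <- attr(trace, "truth")
  if (!is.null(tr)) {
    side <- list(t_micro = tr$t_micro, t_anaer = tr$t_anaer,
                 phase_params = tr$phase_params)
    jsonlite::write_json(side, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns")
  }
  invisible(path)
}

#' @rdname write_fermentation_trace
#' @export
read_fermentation_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ev <- NULL
  if ("event" %in% names(df)) {
    has <- !is.na(df$event) & df$event != ""
    if (any(has)) ev <- data.frame(time = df$time_h[has], label = df$event[has],
                                   stringsAsFactors = FALSE)
    df$event <- NULL
  }
  out <- fermentation_trace(
    time = df$time_h, biomass = df$biomass_gDCW_L, glucose = df$glucose_g_L,
    lactate = df$lactate_g_L, succinate = df$succinate_g_L,
    acetate = df$acetate_g_L, DO = df$DO_pct,
    co2_rate = df$co2_evolution_Cmol_L_h, events = ev)
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    tr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    tr$phase_params <- as.data.frame(tr$phase_params)
    attr(out, "truth") <- tr
  }
  out
}
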