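## polynomial rolling hash over the deparsed config; enough to
## fingerprint a run (stays within exact double integer range)
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble a pipeline run configuration
#'
#' Exactly one of `scenario` (simulate the process) or `trace` (analyze
#' measured data) must be given. Optional components switch on the
#' corresponding report sections.
#'
#' @param scenario A [process_scenario()] or `NULL`.
#' @param trace A [fermentation_trace] or `NULL`.
#' @param expression An [expression_truth()] (simulated on the fly) or an
#'   [expression_matrix], or `NULL`.
#' @param rna_content A record data frame (see [simulate_rna_content()])
#'   or `NULL`.
#' @param m_hi,m_lo,a_min DE cutoff thresholds.
#' @param pseudocount TPM offset for log2 ratios.
#' @param product_threshold Organic-acid onset threshold, g L-1.
#' @param min_points Minimal growth-rate sub-window size.
#' @param seed Integer seed (re-seeds a scenario/truth that carries none).
#' @param outdir Optional output directory for report files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, trace = NULL, expression = NULL,
                       rna_content = NULL,
                       m_hi = 1.50, m_lo = -1.50, a_min = 1.00,
                       pseudocount = 1, product_threshold = 0.10,
                       min_points = 4, seed = 1L, outdir = NULL) {
  if (is.null(scenario) == is.null(trace))
    .stopf("exactly one of scenario or trace must be supplied")
  for (th in c(m_hi, m_lo, a_min, pseudocount, product_threshold))
    if (!is.finite(th)) .stopf("thresholds must be finite")
  if (m_lo >= m_hi) .stopf("m_lo must be below m_hi")
  structure(list(scenario = scenario, trace = trace,
                 expression = expression, rna_content = rna_content,
                 thresholds = list(m_hi = m_hi, m_lo = m_lo, a_min = a_min,
                                   pseudocount = pseudocount,
                                   product_threshold = product_threshold,
                                   min_points = min_points),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Run the triple-phase analysis pipeline end to end
#'
#' Simulate (or take) a fermentation trace, fit the phase kinetics,
#' close the carbon balance, and — when expression and RNA-content
#' inputs are configured — call differential expression phase-wise,
#' partition the calls into the Venn regions, summarize by COG class,
#' screen the regulators and fit the RNA/growth-rate regression. Under a
#' fixed seed the whole bundle is a pure function of the configuration.
#'
#' @param config A [run_config()].
#' @return An object of class `oxyshift_report`: a list with
#'   `phase_summary` (report-rounded table), `kinetics`
#'   (the [fit_phase_kinetics()] object), `carbon`, `de` (calls, venn,
#'   cog, regulators, sample correlation) and `cellphys`, plus the
#'   `config_hash` and `seed`. If `config$outdir` is set, CSV/TSV/JSON
#'   files are written there.
#' @examples
#' rep <- run_pipeline(run_config(scenario = process_scenario(seed = 5)))
#' rep$phase_summary
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds

  trace <- config$trace
  if (is.null(trace)) {
    sc <- config$scenario
    if (is.null(sc$seed)) sc$seed <- config$seed
    trace <- simulate_fermentation(sc)
  }

  kin <- fit_phase_kinetics(trace, product_threshold = th$product_threshold,
                            min_points = th$min_points)
  carbon <- close_balance(trace)

  de <- NULL
  ex <- config$expression
  if (!is.null(ex)) {
    em <- if (inherits(ex, "expression_truth")) simulate_expression(ex) else ex
    pc <- phase_calls(em, pseudocount = th$pseudocount,
                      m_hi = th$m_hi, m_lo = th$m_lo, a_min = th$a_min)
    venn <- venn_partition(pc$aerobic, pc$microaerobic, pc$anaerobic)
    cog <- if ("cog_class" %in% names(em$annotation))
      cog_summary(pc$anaerobic, em$annotation$cog_class) else NULL
    regs <- if ("is_regulator" %in% names(em$annotation))
      regulator_screen(pc$per_sample,
                       em$annotation$gene_id[em$annotation$is_regulator])
      else NULL
    de <- list(expression = em, phase_calls = pc, venn = venn,
               cog_summary = cog, regulator_screen = regs,
               sample_correlation = sample_correlation(em, th$pseudocount),
               n_up_per_phase = vapply(pc[1:3], function(d)
                 sum(d$call == "up"), integer(1)),
               n_down_per_phase = vapply(pc[1:3], function(d)
                 sum(d$call == "down"), integer(1)))
  }

  cellphys <- NULL
  if (!is.null(config$rna_content)) {
    reg <- rna_growth_regression(config$rna_content)
    cellphys <- list(rna_records = config$rna_content,
                     rna_regression = reg)
  }

  report <- structure(
    list(phase_summary = summary(kin), kinetics = kin, carbon = carbon,
         de = de, cellphys = cellphys,
         ## the hash fingerprints the analysis inputs, not the output path
         config_hash = .config_hash(unclass(config)[c(
           "scenario", "trace", "expression", "rna_content", "thresholds",
           "seed")]),
         seed = config$seed),
    class = "oxyshift_report")

  if (!is.null(config$outdir)) .write_report(report, trace, config$outdir)
  report
}

.write_report <- function(report, trace, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(outdir, ...)
  write_fermentation_trace(trace, fp("trace.csv"))
  utils::write.csv(as.data.frame(report$phase_summary),
                   fp("phase_summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = report$seed, config_hash = report$config_hash,
         closure = report$carbon$closure,
         fractions = as.list(report$carbon$fractions)),
    fp("carbon_ledger.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$de)) {
    for (ph in c("aerobic", "microaerobic", "anaerobic"))
      write_ma_tsv(report$de$phase_calls[[ph]],
                   fp(sprintf("ma_%s.tsv", ph)))
    jsonlite::write_json(
      list(up = as.list(report$de$venn$up$regions),
           down = as.list(report$de$venn$down$regions),
           total_altered = report$de$venn$total_altered),
      fp("venn.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(report$de$cog_summary))
      utils::write.table(report$de$cog_summary, fp("cog_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

#' @export
print.oxyshift_report <- function(x, ...) {
  cat(sprintf("Triple-phase pipeline report (seed %d, config %s)\n\n",
              x$seed, x$config_hash))
  print(x$phase_summary)
  cat(sprintf("\nCarbon closure: %.3f C-mol per C-mol glucose\n",
              x$carbon$closure))
  if (!is.null(x$de)) {
    cat(sprintf("DE per phase (up/down): %s\n",
                paste(sprintf("%s %d/%d", names(x$de$n_up_per_phase),
                              x$de$n_up_per_phase, x$de$n_down_per_phase),
                      collapse = ", ")))
    cat(sprintf("Total altered genes: %d\n", x$de$venn$total_altered))
  }
  if (!is.null(x$cellphys))
    cat(sprintf("RNA/growth regression: intercept %.2f +- %.2f fg per cell\n",
                x$cellphys$rna_regression$intercept,
                x$cellphys$rna_regression$stderr_intercept))
  invisible(x)
}
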