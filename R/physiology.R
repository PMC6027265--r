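#' Cellular total-RNA content in fg per cell
#'
#' Converts an isolated total-RNA mass and the number of cells it came
#' from into fg per cell. Cell numbers may be given directly or derived
#' from OD600 and the harvested volume via the correlation that one
#' OD600 unit corresponds to approximately 1e8 cells per mL.
#'
#' @param total_rna_ug Isolated total RNA, micrograms.
#' @param cells_used Cell count, if known directly.
#' @param od600,volume_mL Alternatively, the suspension OD600 and
#'   harvested volume.
#' @param cells_per_od_ml Cells per mL per OD600 unit (default 1e8).
#' @return RNA content, fg per cell (vectorized).
#' @examples
#' rna_per_cell(30, cells_used = 1e9)            # 30 fg per cell
#' rna_per_cell(40, od600 = 10, volume_mL = 2)   # 20 fg per cell
#' @export
rna_per_cell <- function(total_rna_ug, cells_used = NULL, od600 = NULL,
                         volume_mL = NULL, cells_per_od_ml = 1e8) {
  if (is.null(cells_used)) {
    if (is.null(od600) || is.null(volume_mL))
      .stopf("supply cells_used, or od600 together with volume_mL")
    cells_used <- od600 * cells_per_od_ml * volume_mL
  }
  if (any(cells_used <= 0)) .stopf("cell counts must be > 0")
  if (any(total_rna_ug <= 0)) .stopf("RNA masses must be > 0")
  1e9 * total_rna_ug / cells_used   # ug -> fg
}

#' Regress per-cell RNA content on the growth rate
#'
#' Ordinary least squares of RNA per cell (fg) on the specific growth
#' rate; the intercept is the extrapolated zero-growth RNA content with
#' its standard error. By default the first sampling point is excluded
#' from the regression.
#'
#' @param records Data frame with columns `mu` and `rna_per_cell` (e.g.
#'   from [simulate_rna_content()]), optionally `sample_label`.
#' @param exclude Sample labels or integer indices to drop before
#'   fitting; default the first record. Use `NULL` to keep all.
#' @return A list with `slope`, `intercept`, `stderr_intercept`,
#'   `stderr_slope`, `r_squared`, `n`.
#' @examples
#' rec <- simulate_rna_content(cv = 0)
#' rna_growth_regression(rec)$intercept  # 8.8 exactly
#' @export
rna_growth_regression <- function(records, exclude = 1L) {
  stopifnot(is.data.frame(records),
            all(c("mu", "rna_per_cell") %in% names(records)))
  keep <- rep(TRUE, nrow(records))
  if (!is.null(exclude) && length(exclude)) {
    if (is.character(exclude)) {
      if (!"sample_label" %in% names(records))
        .stopf("records has no sample_label column to exclude by")
      keep <- !(records$sample_label %in% exclude)
    } else keep[exclude] <- FALSE
  }
  df <- records[keep, , drop = FALSE]
  if (nrow(df) < 3) .stopf("need >= 3 records after exclusion")
  if (stats::var(df$mu) == 0)
    .stopf("all growth rates equal; regression impossible")
  fit <- stats::lm(rna_per_cell ~ mu, data = df)
  ## suppressed: summary.lm warns about "essentially perfect fit" on the
  ## noise-free collinear inputs the generator can produce
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       stderr_intercept = sm$coefficients[1, 2],
       stderr_slope = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       n = nrow(df))
}

#' Specific enzyme activity from a photometric assay record
#'
#' Beer-Lambert conversion of an absorbance slope (NAD(P)H formation at
#' 340 nm) into volumetric and specific activity. The baseline slope is
#' subtracted from the reaction slope; the net slope (1/min) divided by
#' `extinction_coeff * path_length` gives mM per min in the cuvette,
#' which is rectified by the assay/lysate volume ratio and the lysate
#' dilution. 1 U = 1 umol per min.
#'
#' @param slope_reaction,slope_baseline Absorbance change, 1/min.
#' @param extinction_coeff mM-1 cm-1 (default 6.3, NADPH at 340 nm).
#' @param path_length Cuvette path length, cm.
#' @param assay_volume_mL Total reaction volume in the cuvette, mL.
#' @param lysate_volume_mL Volume of (diluted) lysate added, mL.
#' @param lysate_dilution Fold dilution of the lysate before the assay.
#' @param protein_conc Soluble protein of the undiluted lysate, mg mL-1;
#'   needed for the specific activity.
#' @return A list with `volumetric` (U mL-1 of undiluted lysate) and
#'   `specific` (U mg-1 protein; NA without `protein_conc`).
#' @examples
#' enzyme_activity(0.063, assay_volume_mL = 1, lysate_volume_mL = 0.05,
#'                 lysate_dilution = 10)$volumetric   # 2 U/mL
#' @export
enzyme_activity <- function(slope_reaction, slope_baseline = 0,
                            extinction_coeff = 6.3, path_length = 1,
                            assay_volume_mL, lysate_volume_mL,
                            lysate_dilution = 1, protein_conc = NULL) {
  if (extinction_coeff <= 0) .stopf("extinction coefficient must be > 0")
  if (assay_volume_mL <= 0 || lysate_volume_mL <= 0)
    .stopf("volumes must be > 0")
  if (lysate_dilution < 1) .stopf("lysate_dilution must be >= 1")
  net <- slope_reaction - slope_baseline
  if (net < 0) {
    .warnf("net slope below baseline; activity reported as 0")
    net <- 0
  }
  volumetric <- net * assay_volume_mL * lysate_dilution /
    (extinction_coeff * path_length * lysate_volume_mL)
  specific <- if (is.null(protein_conc)) NA_real_ else {
    if (protein_conc <= 0) .stopf("protein_conc must be > 0")
    volumetric / protein_conc
  }
  list(volumetric = volumetric, specific = specific)
}

#' Intracellular concentration from a neutralized lysate
#'
#' Back-calculates the intracellular titer from the analyte
#' concentration measured in a neutralized whole-culture lysate, the
#' total lysate volume, the biomass that was lysed and the cell volume
#' to biomass ratio (1.95 uL per mg CDW). An optional multiplicative
#' recovery factor represents an internal-standard correction.
#'
#' @param lysate_conc_mM Analyte concentration in the lysate, mM.
#' @param lysate_total_volume_mL Total lysate volume after all additions,
#'   mL.
#' @param biomass_mg_CDW Biomass lysed, mg CDW.
#' @param cell_volume_ratio uL intracellular volume per mg CDW.
#' @param recovery_factor Internal-standard recovery correction
#'   (default 1).
#' @return Intracellular concentration, mM.
#' @examples
#' ## 0.651 mM in 1.5 mL lysate from 3 mg CDW -> ~167 mM intracellular
#' intracellular_concentration(0.651, 1.5, 3)
#' @export
intracellular_concentration <- function(lysate_conc_mM,
                                        lysate_total_volume_mL,
                                        biomass_mg_CDW,
                                        cell_volume_ratio = 1.95,
                                        recovery_factor = 1) {
  if (any(biomass_mg_CDW <= 0)) .stopf("biomass must be > 0")
  if (any(lysate_total_volume_mL <= 0) || cell_volume_ratio <= 0)
    .stopf("volumes must be > 0")
  if (any(lysate_conc_mM < 0)) .stopf("concentrations must be >= 0")
  ## intracellular volume in mL: biomass * ratio * 1e-3
  lysate_conc_mM * recovery_factor * lysate_total_volume_mL /
    (biomass_mg_CDW * cell_volume_ratio * 1e-3)
}
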