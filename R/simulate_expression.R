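#' Define a planted expression ground truth
#'
#' Describes a synthetic gene universe with planted log2-fold structure
#' for the six-sample triple-phase layout: one aerobic reference sample
#' (fold profile identically 0), one further aerobic sample, three
#' microaerobic and one anaerobic sample. By default a set of genes is
#' planted up- and a set downregulated from the microaerobic samples
#' onward, mimicking the early oxygen-limitation response; the effect
#' sizes are drawn uniformly from `effect_range` (log2 units). The
#' default universe size matches the 3002 protein-coding genes of the
#' *C. glutamicum* genome; the default library size (~5e6 read pairs per
#' sample) matches a six-sample MiSeq-scale run.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples (default 6).
#' @param gene_lengths CDS lengths, nt; default lognormal around ~900 nt.
#' @param baseline_abundance Expected TPM-scale abundance per gene;
#'   default lognormal.
#' @param fold_profile Optional gene x sample matrix of log2 shifts
#'   relative to the reference (column 1 must be 0); replaces the default
#'   planting.
#' @param n_up,n_down Numbers of genes planted up/down (ignored when
#'   `fold_profile` is supplied); default 2 % and 8 % of the universe.
#' @param effect_range Range of absolute planted log2-fold changes.
#' @param library_size Expected total counts per sample (scalar or per
#'   sample).
#' @param dispersion Negative-binomial overdispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param cog_classes Pool of COG class labels assigned at random.
#' @param regulator_fraction Fraction of genes flagged as (putative)
#'   regulators (default 159/3002 as in the screened regulator set).
#' @param seed Integer seed.
#' @return An object of class `expression_truth`.
#' @seealso [simulate_expression()]
#' @export
expression_truth <- function(n_genes = 3002, n_samples = 6,
                             gene_lengths = NULL, baseline_abundance = NULL,
                             fold_profile = NULL,
                             n_up = NULL, n_down = NULL,
                             effect_range = c(2, 4),
                             library_size = 5e6, dispersion = 0.05,
                             cog_classes = c("J", "K", "L", "C", "E", "G",
                                             "M", "P", "T", "S"),
                             regulator_fraction = 159 / 3002,
                             seed = 1L) {
  stopifnot(n_genes >= 1, n_samples >= 2, dispersion >= 0)
  .with_seed(seed, {
    if (is.null(gene_lengths))
      gene_lengths <- pmax(90L, round(stats::rlnorm(n_genes, log(900), 0.45)))
    if (is.null(baseline_abundance))
      baseline_abundance <- stats::rlnorm(n_genes, log(50), 1.3)
    if (is.null(fold_profile)) {
      if (is.null(n_up)) n_up <- max(1L, round(0.02 * n_genes))
      if (is.null(n_down)) n_down <- max(1L, round(0.08 * n_genes))
      fold_profile <- matrix(0, n_genes, n_samples)
      if (n_up + n_down > n_genes)
        .stopf("n_up + n_down exceeds n_genes")
      de <- sample.int(n_genes, n_up + n_down)
      eff <- stats::runif(n_up + n_down, effect_range[1], effect_range[2]) *
        rep(c(1, -1), c(n_up, n_down))
      ## response from the microaerobic samples onward (3..n)
      if (n_samples >= 3)
        fold_profile[de, 3:n_samples] <- eff
    }
    cog <- sample(cog_classes, n_genes, replace = TRUE)
    reg <- sample(c(TRUE, FALSE), n_genes, replace = TRUE,
                  prob = c(regulator_fraction, 1 - regulator_fraction))
    NULL
  })
  if (length(gene_lengths) != n_genes ||
      length(baseline_abundance) != n_genes)
    .stopf("gene_lengths and baseline_abundance must have length n_genes")
  if (any(gene_lengths < 1)) .stopf("gene_lengths must be >= 1")
  if (any(baseline_abundance < 0)) .stopf("abundances must be >= 0")
  fold_profile <- as.matrix(fold_profile)
  if (!all(dim(fold_profile) == c(n_genes, n_samples)))
    .stopf("fold_profile must be n_genes x n_samples")
  if (any(fold_profile[, 1] != 0))
    .stopf("the reference sample's fold profile must be identically 0")
  library_size <- rep_len(library_size, n_samples)
  if (any(library_size < 1)) .stopf("library_size must be >= 1")
  structure(
    list(n_genes = n_genes, n_samples = n_samples,
         gene_ids = sprintf("cg%04d", seq_len(n_genes)),
         gene_lengths = as.integer(gene_lengths),
         baseline_abundance = baseline_abundance,
         fold_profile = fold_profile, library_size = library_size,
         dispersion = dispersion, cog_assignment = cog,
         regulator_flags = reg, seed = seed),
    class = "expression_truth")
}

#' Expectation-level TPM of a planted truth
#'
#' The planted relative abundance `baseline * 2^fold`, renormalized per
#' sample to sum to 1e6 — the TPM profile an infinitely deep,
#' dispersion-free library would recover.
#'
#' @param truth An [expression_truth()].
#' @return A gene x sample TPM matrix.
#' @export
expected_tpm <- function(truth) {
  stopifnot(inherits(truth, "expression_truth"))
  w <- truth$baseline_abundance * 2^truth$fold_profile
  tot <- colSums(w)
  if (any(tot == 0)) .stopf("zero total expected abundance in a sample")
  m <- sweep(w, 2, tot, "/") * 1e6
  dimnames(m) <- list(truth$gene_ids, paste0("S", seq_len(truth$n_samples)))
  m
}

#' Simulate an RNA-seq count matrix from a planted truth
#'
#' Draws counts per gene and sample from an overdispersed count
#' distribution (negative binomial; Poisson at dispersion 0) whose
#' expectation is proportional to
#' `baseline_abundance * 2^fold_profile * gene_length`, so that TPM
#' renormalization recovers the planted TPM-scale profile in
#' expectation.
#'
#' @param truth An [expression_truth()].
#' @return An [expression_matrix] with counts, TPM, annotation and
#'   sample phase tags; the `truth` attribute carries the planted
#'   expectation-level TPM, m-values, and the planted calls per sample
#'   and phase under the default cutoff.
#' @examples
#' em <- simulate_expression(expression_truth(n_genes = 100, seed = 2))
#' dim(em$counts)
#' @export
simulate_expression <- function(truth) {
  stopifnot(inherits(truth, "expression_truth"))
  w <- truth$baseline_abundance * 2^truth$fold_profile *
    truth$gene_lengths
  tot <- colSums(w)
  if (any(tot == 0)) .stopf("zero total expected abundance in a sample")
  mu <- sweep(w, 2, tot, "/") %*% diag(truth$library_size)
  counts <- .with_seed(truth$seed, {
    if (truth$dispersion > 0)
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / truth$dispersion),
             nrow(mu), ncol(mu))
    else
      matrix(stats::rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
  })
  labs <- paste0("S", seq_len(truth$n_samples))
  dimnames(counts) <- list(truth$gene_ids, labs)
  annot <- data.frame(gene_id = truth$gene_ids,
                      length_nt = truth$gene_lengths,
                      cog_class = truth$cog_assignment,
                      is_regulator = truth$regulator_flags,
                      stringsAsFactors = FALSE)
  em <- expression_matrix(counts = counts, annotation = annot)

  ## planted calls at expectation level (pseudocount 0, default cutoff)
  etpm <- expected_tpm(truth)
  planted <- lapply(seq_len(truth$n_samples)[-1], function(s) {
    df <- data.frame(gene_id = truth$gene_ids,
                     comparison = paste0(labs[s], "_vs_", labs[1]),
                     m = truth$fold_profile[, s],
                     a = (etpm[, s] + etpm[, 1]) / 2,
                     call = NA_character_, stringsAsFactors = FALSE)
    call_de(df)
  })
  names(planted) <- labs[-1]
  phase_planted <- if (truth$n_samples == 6) list(
    aerobic = planted[[1]],
    microaerobic = phase_call_microaerobic(planted[[2]], planted[[3]],
                                           planted[[4]]),
    anaerobic = planted[[5]]) else NULL
  attr(em, "truth") <- list(expected_tpm = etpm,
                            fold_profile = truth$fold_profile,
                            planted_calls = planted,
                            planted_phase_calls = phase_planted,
                            truth = truth)
  em
}

#' Simulate per-cell RNA content at given growth rates
#'
#' Cellular total-RNA content is generated as mean-one lognormal noise
#' around the linear growth-rate model
#' `rna = intercept + slope * mu` (fg per cell). The default intercept
#' is the zero-growth extrapolation of the triple-phase process
#' (8.8 fg per cell); the default slope spans the observed content range
#' over the process growth rates.
#'
#' @param intercept Zero-growth RNA content, fg per cell (> 0).
#' @param slope fg per cell per (1/h) (>= 0).
#' @param mu_values Growth rates of the sampled states, 1/h; default the
#'   six triple-phase sampling points (two aerobic, three microaerobic,
#'   one anaerobic).
#' @param cv Relative SD of the lognormal noise.
#' @param seed Integer seed.
#' @return A data frame `sample_label`, `mu`, `rna_per_cell` (fg),
#'   `rna_true` (the noise-free model value).
#' @examples
#' simulate_rna_content(cv = 0, seed = 1)
#' @export
simulate_rna_content <- function(intercept = 8.8, slope = 40,
                                 mu_values = c(0.40, 0.40, 0.21, 0.21,
                                               0.21, 0.09),
                                 cv = 0.08, seed = 1L) {
  if (intercept <= 0) .stopf("intercept must be > 0")
  if (slope < 0) .stopf("slope must be >= 0")
  if (cv < 0 || cv > 0.5) .stopf("cv must lie in [0, 0.5]")
  true <- intercept + slope * mu_values
  obs <- .with_seed(seed, .lognoise(true, cv))
  data.frame(sample_label = paste0("S", seq_along(mu_values)),
             mu = mu_values, rna_per_cell = obs, rna_true = true,
             stringsAsFactors = FALSE)
}
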