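## ---- containers ------------------------------------------------------------

.DEFAULT_PHASES6 <- c("aerobic", "aerobic", "microaerobic", "microaerobic",
                      "microaerobic", "anaerobic")

#' Bundle counts/TPM with annotation and sample phase tags
#'
#' @param counts Optional gene x sample count matrix.
#' @param tpm Optional gene x sample TPM matrix; computed from `counts`
#'   and the annotation lengths when absent.
#' @param annotation Data frame with `gene_id`, `length_nt` and optional
#'   `cog_class`, `is_regulator` columns.
#' @param samples Data frame with `label` and `phase` per sample; for six
#'   samples defaults to the aerobic/aerobic/microaerobic x3/anaerobic
#'   layout of the triple-phase sampling scheme.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts = NULL, tpm = NULL, annotation,
                              samples = NULL) {
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "length_nt") %in% names(annotation)))
  if (any(annotation$length_nt < 1)) .stopf("CDS lengths must be >= 1 nt")
  if (is.null(tpm)) {
    if (is.null(counts)) .stopf("supply counts or tpm")
    tpm <- counts_to_tpm(counts, annotation$length_nt)
  }
  if (any(tpm < 0, na.rm = TRUE)) .stopf("negative expression values")
  if (is.null(samples)) {
    lab <- colnames(tpm)
    if (is.null(lab)) lab <- paste0("S", seq_len(ncol(tpm)))
    ph <- if (ncol(tpm) == 6) .DEFAULT_PHASES6 else rep(NA_character_, ncol(tpm))
    samples <- data.frame(label = lab, phase = ph, stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, tpm = tpm, annotation = annotation,
                 samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (%s)\n",
              nrow(x$tpm), ncol(x$tpm),
              if (is.null(x$counts)) "TPM only" else "counts + TPM"))
  cat("  samples:", paste(sprintf("%s[%s]", x$samples$label,
                                  substr(x$samples$phase, 1, 5)),
                          collapse = " "), "\n")
  if (!is.null(attr(x, "truth"))) cat("  synthetic (planted truth attached)\n")
  invisible(x)
}

## ---- TPM -------------------------------------------------------------------

#' Transcripts per million from gene-level counts
#'
#' Per sample: `rate_g = count_g / length_g`;
#' `TPM_g = 1e6 rate_g / sum(rate)`. Lengths are CDS lengths in nt
#' (gene-level CDS quantification; no fragment-length correction).
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @param lengths CDS length per gene, nt (>= 1).
#' @return A TPM matrix with the same dimnames; every column sums to 1e6.
#' @examples
#' counts_to_tpm(cbind(s1 = c(10, 10)), lengths = c(100, 200))
#' @export
counts_to_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    .stopf("lengths must match the number of genes")
  if (any(lengths < 1)) .stopf("CDS lengths must be >= 1 nt")
  if (any(counts < 0)) .stopf("counts must be non-negative")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    .stopf("sample(s) with all-zero counts: %s", paste(bad, collapse = ", "))
  }
  sweep(rate, 2, tot, "/") * 1e6
}

## ---- m/a values and the empirical cutoff ----------------------------------

.tpm_of <- function(x) if (inherits(x, "expression_matrix")) x$tpm else as.matrix(x)

#' Per-gene m- and a-values of a sample versus the reference
#'
#' The signal intensity ratio (m-value) is the log2-fold change
#' `log2((tpm_s + pseudocount) / (tpm_ref + pseudocount))`; the signal
#' intensity (a-value) is the arithmetic mean of the two samples' TPM.
#'
#' @param x An [expression_matrix] or a TPM matrix.
#' @param sample,reference Column labels (or indices) of the comparison.
#' @param pseudocount TPM offset guarding the log ratio for
#'   zero-expression genes; 0 is allowed for strictly positive matrices.
#' @return A data frame `gene_id`, `comparison`, `m`, `a`, `call` (calls
#'   unset, see [call_de()]).
#' @examples
#' tpm <- cbind(S1 = c(10, 8), S2 = c(40, 0))
#' ma_values(tpm, "S2", "S1", pseudocount = 0)[1, ]
#' @export
ma_values <- function(x, sample, reference, pseudocount = 1) {
  tpm <- .tpm_of(x)
  for (s in list(sample, reference))
    if (is.character(s) && !s %in% colnames(tpm))
      .stopf("sample '%s' not found", s)
  ts <- tpm[, sample]
  tr <- tpm[, reference]
  ids <- rownames(tpm)
  if (is.null(ids) && inherits(x, "expression_matrix")) ids <- x$annotation$gene_id
  if (is.null(ids)) ids <- as.character(seq_len(nrow(tpm)))
  data.frame(
    gene_id = ids,
    comparison = paste0(if (is.character(sample)) sample else colnames(tpm)[sample],
                        "_vs_",
                        if (is.character(reference)) reference else colnames(tpm)[reference]),
    m = log2((ts + pseudocount) / (tr + pseudocount)),
    a = (ts + tr) / 2,
    call = NA_character_,
    stringsAsFactors = FALSE)
}

#' Call differential expression with the empirical m/a cutoff
#'
#' Strict inequalities exactly as defined: `up` iff `m > m_hi` and
#' `a > a_min`; `down` iff `m < m_lo` and `a > a_min`;
#' `a <= a_min` yields `excluded_low_signal` regardless of m (results
#' derived from very few reads are excluded); everything else is
#' `unchanged`.
#'
#' @param ma A data frame from [ma_values()] (columns `m`, `a`).
#' @param m_hi,m_lo Log2-fold-change thresholds (default +-1.50).
#' @param a_min Signal threshold in TPM (default 1.00).
#' @return The input with the `call` column filled.
#' @examples
#' ma <- data.frame(m = c(1.5, 3, -2), a = c(10, 0.5, 5))
#' call_de(ma)$call  # unchanged, excluded_low_signal, down
#' @export
call_de <- function(ma, m_hi = 1.50, m_lo = -1.50, a_min = 1.00) {
  stopifnot(all(c("m", "a") %in% names(ma)), m_lo < m_hi)
  call <- rep("unchanged", nrow(ma))
  call[ma$m > m_hi] <- "up"
  call[ma$m < m_lo] <- "down"
  call[ma$a <= a_min] <- "excluded_low_signal"
  ma$call <- call
  ma
}

#' Microaerobic phase call by averaging the three sample comparisons
#'
#' For the microaerobic phase an average value is computed over the three
#' microaerobic samples' comparisons against the aerobic reference: per
#' gene the mean m-value and mean a-value, to which the cutoff is then
#' applied.
#'
#' @param ma_3,ma_4,ma_5 Data frames from [ma_values()] for the three
#'   microaerobic samples, same gene universe.
#' @param ... Passed to [call_de()] (thresholds).
#' @return A called data frame with the averaged `m` and `a`.
#' @export
phase_call_microaerobic <- function(ma_3, ma_4, ma_5, ...) {
  mas <- list(ma_3, ma_4, ma_5)
  ids <- lapply(mas, `[[`, "gene_id")
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    off <- unique(c(setdiff(unlist(ids), Reduce(intersect, ids)),
                    setdiff(Reduce(union, ids), ids[[1]])))
    .stopf("gene universes differ between the three comparisons: %s",
           paste(utils::head(off, 10), collapse = ", "))
  }
  out <- data.frame(
    gene_id = ids[[1]],
    comparison = "microaerobic_vs_reference",
    m = (mas[[1]]$m + mas[[2]]$m + mas[[3]]$m) / 3,
    a = (mas[[1]]$a + mas[[2]]$a + mas[[3]]$a) / 3,
    call = NA_character_,
    stringsAsFactors = FALSE)
  call_de(out, ...)
}

#' Phase-wise differential-expression calls against the aerobic reference
#'
#' Convenience wrapper for the six-sample triple-phase layout: the
#' aerobic phase call is sample 2 vs the reference (sample 1), the
#' microaerobic call averages samples 3-5 ([phase_call_microaerobic()]),
#' the anaerobic call is sample 6.
#'
#' @param x An [expression_matrix] with six samples.
#' @param reference Reference sample label (default the first sample).
#' @param pseudocount Passed to [ma_values()].
#' @param ... Thresholds passed to [call_de()].
#' @return A named list of called data frames
#'   (`aerobic`, `microaerobic`, `anaerobic`) plus `per_sample` (calls
#'   for every non-reference sample).
#' @export
phase_calls <- function(x, reference = NULL, pseudocount = 1, ...) {
  stopifnot(inherits(x, "expression_matrix"))
  labs <- x$samples$label
  if (length(labs) != 6)
    .stopf("phase_calls expects the six-sample triple-phase layout")
  if (is.null(reference)) reference <- labs[1]
  ma <- lapply(labs[-1], function(s)
    call_de(ma_values(x, s, reference, pseudocount), ...))
  names(ma) <- labs[-1]
  list(aerobic = ma[[labs[2]]],
       microaerobic = phase_call_microaerobic(
         ma_values(x, labs[3], reference, pseudocount),
         ma_values(x, labs[4], reference, pseudocount),
         ma_values(x, labs[5], reference, pseudocount), ...),
       anaerobic = ma[[labs[6]]],
       per_sample = ma)
}

## ---- Venn partition --------------------------------------------------------

.venn_regions <- function(A, B, C) {
  u <- union(A, union(B, C))
  inA <- u %in% A; inB <- u %in% B; inC <- u %in% C
  key <- paste0(as.integer(inA), as.integer(inB), as.integer(inC))
  tab <- table(factor(key, levels = c("100", "010", "001", "110",
                                      "101", "011", "111")))
  stats::setNames(as.integer(tab),
                  c("aerobic_only", "microaerobic_only", "anaerobic_only",
                    "aerobic_microaerobic", "aerobic_anaerobic",
                    "microaerobic_anaerobic", "all_three"))
}

#' Partition phase-wise DE calls into the three-set Venn regions
#'
#' For up- and downregulated genes separately, computes the seven
#' disjoint region counts of the aerobic, microaerobic and anaerobic call
#' sets, per-phase totals and the union; genes called up in one phase and
#' down in another appear in both polarity diagrams and are flagged.
#'
#' @param aerobic_calls,microaerobic_calls,anaerobic_calls Called data
#'   frames (see [call_de()]) over one gene universe.
#' @return An object of class `venn_partition` with elements `up` and
#'   `down` (each: `sets`, `regions`, `phase_totals`, `union_size`),
#'   `total_altered` (union over polarities and phases) and
#'   `conflicting_genes`.
#' @export
venn_partition <- function(aerobic_calls, microaerobic_calls,
                           anaerobic_calls) {
  calls <- list(aerobic = aerobic_calls, microaerobic = microaerobic_calls,
                anaerobic = anaerobic_calls)
  ids <- lapply(calls, `[[`, "gene_id")
  if (!all(vapply(ids[-1], function(i) setequal(i, ids[[1]]), logical(1))))
    .warnf("gene universes differ between phases")
  pick <- function(df, what) df$gene_id[df$call == what]
  pol <- lapply(c(up = "up", down = "down"), function(what) {
    sets <- lapply(calls, pick, what = what)
    list(sets = sets,
         regions = .venn_regions(sets$aerobic, sets$microaerobic,
                                 sets$anaerobic),
         phase_totals = vapply(sets, length, integer(1)),
         union_size = length(Reduce(union, sets)))
  })
  all_up <- Reduce(union, pol$up$sets)
  all_down <- Reduce(union, pol$down$sets)
  structure(list(up = pol$up, down = pol$down,
                 total_altered = length(union(all_up, all_down)),
                 conflicting_genes = sort(intersect(all_up, all_down))),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of differentially expressed genes:\n")
  for (pn in c("up", "down")) {
    p <- x[[pn]]
    cat(sprintf("  %-5s totals: aerobic %d, microaerobic %d, anaerobic %d (union %d)\n",
                pn, p$phase_totals[1], p$phase_totals[2], p$phase_totals[3],
                p$union_size))
    cat("        regions:",
        paste(sprintf("%s=%d", names(p$regions), p$regions), collapse = ", "),
        "\n")
  }
  cat(sprintf("  total altered genes: %d", x$total_altered))
  if (length(x$conflicting_genes))
    cat(sprintf(" (%d with opposite polarity across phases)",
                length(x$conflicting_genes)))
  cat("\n")
  invisible(x)
}

## ---- COG summary and regulator screen --------------------------------------

#' Summarize differential expression by COG functional class
#'
#' Per class: gene count, number of altered (up or down) genes, the
#' altered fraction, and mean +- SD of the m-value over the altered
#' subset only (NA when no gene of the class is altered).
#'
#' @param calls A called data frame (see [call_de()]).
#' @param cog Per-gene class labels aligned with `calls` (NA treated as
#'   `"unclassified"`).
#' @return A data frame with one row per class.
#' @export
cog_summary <- function(calls, cog) {
  if (length(cog) != nrow(calls))
    .stopf("cog must provide one class per gene")
  cog <- ifelse(is.na(cog) | cog == "", "unclassified", cog)
  altered <- calls$call %in% c("up", "down")
  out <- do.call(rbind, lapply(sort(unique(cog)), function(cl) {
    sel <- cog == cl
    alt <- sel & altered
    data.frame(
      cog_class = cl,
      n_total = sum(sel),
      n_altered = sum(alt),
      fraction = sum(alt) / sum(sel),
      mean_m_of_altered = if (any(alt)) mean(calls$m[alt]) else NA_real_,
      sd_m_of_altered = if (sum(alt) > 1) stats::sd(calls$m[alt]) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Screen regulator genes for repeated significant responses
#'
#' Over the per-sample comparisons against the aerobic reference,
#' `altered` collects regulators significant (up or down) in at least one
#' comparison; `selected` those with a significant response in more than
#' one condition.
#'
#' @param per_sample_calls Named list of called data frames, one per
#'   non-reference sample.
#' @param regulator_ids Gene ids of the (putative) regulators.
#' @return A list with character vectors `altered` and `selected` and the
#'   per-regulator significance count `n_significant`.
#' @export
regulator_screen <- function(per_sample_calls, regulator_ids) {
  if (!length(regulator_ids)) {
    .warnf("empty regulator list")
    return(list(altered = character(0), selected = character(0),
                n_significant = integer(0)))
  }
  counts <- stats::setNames(integer(length(regulator_ids)), regulator_ids)
  for (df in per_sample_calls) {
    sig <- df$gene_id[df$call %in% c("up", "down")]
    hit <- regulator_ids[regulator_ids %in% sig]
    counts[hit] <- counts[hit] + 1L
  }
  list(altered = names(counts)[counts >= 1],
       selected = names(counts)[counts >= 2],
       n_significant = counts)
}

## ---- sample correlation ----------------------------------------------------

#' Pearson correlation of samples on the log2-TPM scale
#'
#' @param x An [expression_matrix] or TPM matrix.
#' @param pseudocount TPM offset before the log2 transform.
#' @return Sample x sample Pearson correlation matrix of
#'   `log2(TPM + pseudocount)` across genes; diagonal 1; pairs involving
#'   a zero-variance sample are NA.
#' @export
sample_correlation <- function(x, pseudocount = 1) {
  tpm <- .tpm_of(x)
  if (ncol(tpm) < 2) .stopf("need >= 2 samples")
  lt <- log2(tpm + pseudocount)
  v <- apply(lt, 2, stats::var)
  cc <- suppressWarnings(stats::cor(lt))
  cc[v == 0, ] <- NA_real_
  cc[, v == 0] <- NA_real_
  diag(cc) <- 1
  cc
}

## ---- I/O -------------------------------------------------------------------

#' Read and write count/annotation tables
#'
#' `read_counts_tsv()` expects a TSV with a `gene_id` column and one
#' column per sample; `read_annotation_tsv()` a TSV with `gene_id`,
#' `length_nt` and optional `cog_class`, `is_regulator` columns.
#' `write_ma_tsv()` writes a called comparison table.
#'
#' @param path File path.
#' @return `read_counts_tsv()`: a count matrix with gene ids as
#'   rownames. `read_annotation_tsv()`: a data frame.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df)) .stopf("counts TSV needs a gene_id column")
  m <- as.matrix(df[setdiff(names(df), "gene_id")])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' @rdname read_counts_tsv
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "length_nt")
  if (!all(need %in% names(df)))
    .stopf("annotation TSV needs columns: %s", paste(need, collapse = ", "))
  df
}

#' @rdname read_counts_tsv
#' @param ma A called comparison data frame.
#' @export
write_ma_tsv <- function(ma, path) {
  utils::write.table(ma[c("gene_id", "m", "a", "call")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive CDS lengths from a GFF3 annotation
#'
#' Uses the `rtracklayer` package (if installed) to import the GFF3 and
#' returns the CDS length per gene, keyed by the `ID` attribute.
#'
#' @param path GFF3 file path.
#' @return A data frame `gene_id`, `length_nt`.
#' @export
cds_lengths_from_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("BiocGenerics", quietly = TRUE))
    .stopf("cds_lengths_from_gff requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  ids <- as.character(cds$ID)
  w <- tapply(BiocGenerics::width(cds), ids, sum)
  data.frame(gene_id = names(w), length_nt = as.integer(w),
             stringsAsFactors = FALSE, row.names = NULL)
}
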