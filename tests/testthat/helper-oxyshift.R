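## a noise-free reference-process scenario
noise_free_scenario <- function(...) {
  process_scenario(cv_biomass = 0, cv_metabolite = 0, cv_DO = 0, ...)
}

## independent brute-force TPM (per-sample loop, no vectorization shared
## with the implementation)
oracle_tpm <- function(counts, lengths) {
  out <- matrix(NA_real_, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  for (s in seq_len(ncol(counts))) {
    rates <- numeric(nrow(counts))
    for (g in seq_len(nrow(counts))) rates[g] <- counts[g, s] / lengths[g]
    for (g in seq_len(nrow(counts))) out[g, s] <- 1e6 * rates[g] / sum(rates)
  }
  out
}

## independent three-set region counter: enumerate the 8 membership
## patterns per gene
oracle_venn <- function(A, B, C) {
  u <- unique(c(A, B, C))
  pat <- sapply(u, function(g)
    paste0(as.integer(g %in% A), as.integer(g %in% B), as.integer(g %in% C)))
  count <- function(p) sum(pat == p)
  c(aerobic_only = count("100"), microaerobic_only = count("010"),
    anaerobic_only = count("001"), aerobic_microaerobic = count("110"),
    aerobic_anaerobic = count("101"), microaerobic_anaerobic = count("011"),
    all_three = count("111"))
}
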