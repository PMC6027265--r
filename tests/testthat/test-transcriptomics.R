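test_that("TPM normalization matches the definition and a brute-force oracle", {
  ## a single gene always gets the whole million
  expect_equal(unname(counts_to_tpm(cbind(s = 17), lengths = 500)[1, 1]), 1e6)

  ## two genes with equal counts and lengths L, 2L split 2:1
  tpm <- counts_to_tpm(cbind(s = c(10, 10)), lengths = c(100, 200))
  expect_equal(unname(tpm[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  ## random matrix against the independent per-sample reimplementation
  set.seed(11)
  counts <- matrix(rpois(15, 50), 5, 3,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  lens <- c(300, 900, 1500, 600, 1200)
  expect_equal(counts_to_tpm(counts, lens), oracle_tpm(counts, lens),
               tolerance = 1e-9)
  expect_equal(unname(colSums(counts_to_tpm(counts, lens))), rep(1e6, 3),
               tolerance = 1e-3)
})

test_that("TPM rejects invalid input, naming the offending sample", {
  counts <- cbind(good = c(5, 5), empty = c(0, 0))
  expect_error(counts_to_tpm(counts, c(100, 100)), "empty")
  expect_error(counts_to_tpm(cbind(c(1, 2)), c(0, 100)), "length")
  expect_error(counts_to_tpm(cbind(c(-1, 2)), c(100, 100)), "non-negative")
})

test_that("m/a values follow the log-ratio and mean definitions", {
  tpm <- cbind(S1 = c(10, 7, 8), S2 = c(40, 7, 0))
  ma <- ma_values(tpm, "S2", "S1", pseudocount = 0)
  expect_equal(ma$m[1], 2)
  expect_equal(ma$a[1], 25)
  expect_equal(ma$m[2], 0)

  ma1 <- ma_values(tpm, "S2", "S1", pseudocount = 1)
  expect_equal(ma1$m[3], log2(1 / 9), tolerance = 1e-12)
  expect_equal(ma1$a[3], 4)
})

test_that("m-values are antisymmetric for positive matrices at pseudocount 0", {
  set.seed(5)
  tpm <- matrix(rlnorm(60, 3, 1), 20, 3,
                dimnames = list(NULL, c("A", "B", "C")))
  f <- ma_values(tpm, "B", "A", pseudocount = 0)
  r <- ma_values(tpm, "A", "B", pseudocount = 0)
  expect_equal(f$m, -r$m, tolerance = 1e-12)
  expect_equal(f$a, r$a)
})

test_that("the empirical cutoff uses strict inequalities and the signal floor", {
  ma <- data.frame(m = c(1.50, 3.0, -2.0, -1.50, 1.51, 0),
                   a = c(10, 0.5, 5, 10, 1.0001, 1.0))
  out <- call_de(ma)
  expect_equal(out$call, c("unchanged", "excluded_low_signal", "down",
                           "unchanged", "up", "excluded_low_signal"))
})

test_that("increasing m never demotes a call (monotonicity)", {
  set.seed(8)
  rank_of <- function(call) match(call, c("down", "unchanged", "up"))
  ma <- data.frame(m = runif(200, -4, 4), a = runif(200, 1.5, 50))
  for (delta in c(0.3, 1, 2.5)) {
    ma2 <- ma
    ma2$m <- ma$m + delta
    r1 <- rank_of(call_de(ma)$call)
    r2 <- rank_of(call_de(ma2)$call)
    expect_true(all(r2 >= r1))
  }
})

test_that("microaerobic phase calls average m and a before the cutoff", {
  mk <- function(m, a = 10) data.frame(gene_id = paste0("g", seq_along(m)),
                                       comparison = "x_vs_ref", m = m, a = a,
                                       call = NA_character_)
  out <- phase_call_microaerobic(mk(c(2, 4.6, 1.6)), mk(c(2, 0.1, 1.6)),
                                 mk(c(2, 0.1, -4.7)))
  expect_equal(out$m, c(2, 1.6, -0.5), tolerance = 1e-12)
  expect_equal(out$call, c("up", "up", "unchanged"))

  bad <- mk(c(1, 2, 3)); bad$gene_id <- c("g1", "g2", "gX")
  expect_error(phase_call_microaerobic(mk(1:3), mk(1:3), bad), "universes")
})

test_that("Venn regions match exhaustive set algebra", {
  mkcalls <- function(up, down, universe) {
    call <- rep("unchanged", length(universe))
    call[universe %in% up] <- "up"
    call[universe %in% down] <- "down"
    data.frame(gene_id = universe, m = 0, a = 10, call = call)
  }
  uni <- paste0("g", 1:200)

  ## identical sets concentrate in the centre region
  s <- paste0("g", 1:7)
  v <- venn_partition(mkcalls(s, NULL, uni), mkcalls(s, NULL, uni),
                      mkcalls(s, NULL, uni))
  expect_equal(unname(v$up$regions["all_three"]), 7)
  expect_equal(sum(v$up$regions), 7)

  ## pairwise disjoint sets of sizes 1, 2, 3
  v2 <- venn_partition(mkcalls("g1", NULL, uni),
                       mkcalls(c("g2", "g3"), NULL, uni),
                       mkcalls(c("g4", "g5", "g6"), NULL, uni))
  expect_equal(unname(v2$up$regions[c("aerobic_only", "microaerobic_only",
                                      "anaerobic_only")]), c(1, 2, 3))
  expect_equal(v2$up$union_size, 6)

  ## 200 random genes with random phase calls against the 8-pattern oracle
  set.seed(13)
  for (rep in 1:5) {
    calls <- lapply(1:3, function(i) {
      cl <- sample(c("up", "down", "unchanged"), 200, replace = TRUE,
                   prob = c(0.2, 0.3, 0.5))
      data.frame(gene_id = uni, m = 0, a = 10, call = cl)
    })
    v3 <- venn_partition(calls[[1]], calls[[2]], calls[[3]])
    for (pol in c("up", "down")) {
      sets <- lapply(calls, function(d) d$gene_id[d$call == pol])
      expect_equal(v3[[pol]]$regions, oracle_venn(sets[[1]], sets[[2]],
                                                  sets[[3]]))
      ## per-phase totals are conserved by the region partition
      expect_equal(unname(v3[[pol]]$phase_totals),
                   vapply(sets, length, integer(1)))
      reg <- v3[[pol]]$regions
      expect_equal(unname(reg["aerobic_only"] + reg["aerobic_microaerobic"] +
                            reg["aerobic_anaerobic"] + reg["all_three"]),
                   length(sets[[1]]))
    }
  }
})

test_that("COG summary aggregates altered genes per class", {
  calls <- data.frame(gene_id = paste0("g", 1:6),
                      m = c(-3, -3, -3, 2, 0, 1),
                      a = 10,
                      call = c("down", "down", "down", "up", "unchanged",
                               "unchanged"))
  cog <- c("J", "J", "J", "K", "K", NA)
  sm <- cog_summary(calls, cog)
  j <- sm[sm$cog_class == "J", ]
  expect_equal(j$n_altered, 3)
  expect_equal(j$fraction, 1)
  expect_equal(j$mean_m_of_altered, -3)
  expect_equal(j$sd_m_of_altered, 0)
  un <- sm[sm$cog_class == "unclassified", ]
  expect_equal(un$n_altered, 0)
  expect_true(is.na(un$mean_m_of_altered))

  ## randomized group-by against tapply
  set.seed(21)
  n <- 150
  calls2 <- call_de(data.frame(gene_id = paste0("g", 1:n),
                               m = runif(n, -4, 4), a = runif(n, 0.5, 30),
                               call = NA))
  cog2 <- sample(c("J", "K", "L", "C"), n, replace = TRUE)
  sm2 <- cog_summary(calls2, cog2)
  alt <- calls2$call %in% c("up", "down")
  for (cl in unique(cog2)) {
    sel <- cog2 == cl & alt
    expect_equal(sm2$n_altered[sm2$cog_class == cl], sum(sel))
    if (any(sel))
      expect_equal(sm2$mean_m_of_altered[sm2$cog_class == cl],
                   mean(calls2$m[sel]), tolerance = 1e-12)
  }
})

test_that("regulator screen separates single- from multi-condition hits", {
  mk <- function(sig) data.frame(gene_id = paste0("r", 1:5), m = 0, a = 10,
                                 call = ifelse(paste0("r", 1:5) %in% sig,
                                               "up", "unchanged"))
  regs <- paste0("r", 1:5)
  scr <- regulator_screen(list(S3 = mk("r1"), S6 = mk(c("r1", "r2"))), regs)
  expect_setequal(scr$altered, c("r1", "r2"))
  expect_equal(scr$selected, "r1")
  expect_warning(out <- regulator_screen(list(mk("r1")), character(0)),
                 "empty")
  expect_length(out$altered, 0)

  ## 50 synthetic regulators against brute-force enumeration
  set.seed(17)
  regs50 <- paste0("reg", 1:50)
  samples <- lapply(1:5, function(i) {
    sig <- sample(regs50, 12)
    data.frame(gene_id = regs50, m = 0, a = 10,
               call = ifelse(regs50 %in% sig,
                             sample(c("up", "down"), 50, TRUE), "unchanged"))
  })
  scr2 <- regulator_screen(samples, regs50)
  nsig <- sapply(regs50, function(r)
    sum(sapply(samples, function(d)
      d$call[d$gene_id == r] %in% c("up", "down"))))
  expect_setequal(scr2$altered, regs50[nsig >= 1])
  expect_setequal(scr2$selected, regs50[nsig >= 2])
})

test_that("sample correlations behave on log2-TPM", {
  set.seed(3)
  base <- rlnorm(100, 4, 1)
  tpm <- cbind(S1 = base, S2 = base, S3 = base * 2, S4 = rlnorm(100, 4, 1))
  cc <- sample_correlation(tpm, pseudocount = 0)
  expect_equal(cc["S1", "S2"], 1, tolerance = 1e-12)
  expect_equal(cc["S1", "S3"], 1, tolerance = 1e-12)  # pure scaling
  expect_lt(cc["S1", "S4"], 1)

  ## textbook Pearson recomputation for one pair
  l1 <- log2(tpm[, "S1"]); l4 <- log2(tpm[, "S4"])
  r_hand <- sum((l1 - mean(l1)) * (l4 - mean(l4))) /
    sqrt(sum((l1 - mean(l1))^2) * sum((l4 - mean(l4))^2))
  expect_equal(unname(cc["S1", "S4"]), r_hand, tolerance = 1e-12)

  ## zero-variance sample reported as absent, diagonal kept at 1
  tpm0 <- cbind(A = rep(5, 10), B = rlnorm(10))
  cc0 <- sample_correlation(tpm0, pseudocount = 0)
  expect_true(is.na(cc0["A", "B"]))
  expect_equal(unname(diag(cc0)), c(1, 1))
})

test_that("planted differential expression is recovered from counts", {
  truth <- expression_truth(n_genes = 400, seed = 19,
                            baseline_abundance = rlnorm(400, log(200), 0.8))
  em <- simulate_expression(truth)
  pc <- phase_calls(em, pseudocount = 1)
  planted <- attr(em, "truth")$planted_phase_calls

  ## at this depth and abundance the anaerobic planted partition is
  ## recovered with high fidelity from one sampled count matrix
  tab <- table(planted = planted$anaerobic$call == "up" |
                 planted$anaerobic$call == "down",
               called = pc$anaerobic$call == "up" |
                 pc$anaerobic$call == "down")
  f1 <- 2 * tab[2, 2] / (2 * tab[2, 2] + tab[1, 2] + tab[2, 1])
  expect_gt(f1, 0.9)
})

test_that("count and annotation TSVs round-trip", {
  em <- simulate_expression(expression_truth(n_genes = 20, seed = 23))
  d <- tempdir()
  cpath <- file.path(d, "counts.tsv")
  apath <- file.path(d, "annot.tsv")
  write.table(data.frame(gene_id = rownames(em$counts), em$counts,
                         check.names = FALSE),
              cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(em$annotation, apath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  counts <- read_counts_tsv(cpath)
  annot <- read_annotation_tsv(apath)
  expect_equal(counts, em$counts)
  expect_equal(annot$length_nt, em$annotation$length_nt)
  em2 <- expression_matrix(counts = counts, annotation = annot)
  expect_equal(em2$tpm, em$tpm)
  unlink(c(cpath, apath))
})
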