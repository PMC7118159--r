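# Small configurations and file fixtures shared across tests.

# cohorts weighted toward RB1 loss so >= 2 cohorts pass the dosage-DE
# eligibility thresholds (the real analysis selects such cohorts from 31)
rb_heavy_probs <- function(n_cohorts) {
  matrix(rep(c(0.40, 0.10, 0.05, 0.05, 0.40), n_cohorts),
         nrow = n_cohorts, byrow = TRUE,
         dimnames = list(NULL, c("rb1_loss", "cdkn2a_del", "ccnd1_amp",
                                 "cdk4_amp", "none")))
}

small_config <- function(seed = 1L, ...) {
  args <- list(n_cohorts = 2L, n_samples = 80L, arm_genes = 20L,
               rb1_index = 10L, brca2_index = 4L, program_genes = 15L,
               rb_independent_genes = 8L, n_background = 25L,
               decoy_genes = 6L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# two-sided Fisher p by exhaustive hypergeometric enumeration over the
# fixed margins (small-p rule), independent of fisher.test
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  pobs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# textbook two-group log-rank O-E/V statistic
logrank_oe_chi2 <- function(times, events, groups) {
  groups <- as.factor(groups)
  g1 <- levels(groups)[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == g1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# weighted KS running sum written longhand (loop form)
brute_force_es <- function(w, in_set) {
  n <- length(w)
  aw <- abs(w)
  hit_total <- sum(aw[in_set])
  miss_n <- n - sum(in_set)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (in_set[i]) aw[i] / hit_total else -1 / miss_n
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# tiny on-disk cohort for the io tests: 3 genes x 3 samples, one sample
# missing from the clinical table
write_toy_cohort <- function(dir) {
  expr <- file.path(dir, "expr.tsv")
  writeLines(c("gene\tS1\tS2\tS3",
               "RB1\t5.1\t4.2\t6.3",
               "CDKN2A\t2.0\t3.5\t1.1",
               "BG_001\t7.7\t7.8\t7.9"), expr)
  cna <- file.path(dir, "cna.tsv")
  writeLines(c("Hugo_Symbol\tS1\tS2\tS3",
               "RB1\t0\t-1\t-2",
               "CDKN2A\t-2\t0\t0",
               "BG_001\t0\t0\t0"), cna)
  maf <- file.path(dir, "mut.maf")
  writeLines(c("Tumor_Sample_Barcode\tHugo_Symbol\tVariant_Classification",
               "S1\tRB1\tNonsense_Mutation",
               "S2\tBG_001\tSilent",
               "S3\tCDKN2A\tMissense_Mutation"), maf)
  clin <- file.path(dir, "clinical.tsv")
  writeLines(c("sample\tcohort\tsubtype\tdfs_months\tdfs_status\tos_months\tos_status",
               "S1\tTOY\tNA\t12.5\t1\t20\t1",
               "S2\tTOY\tNA\t30\t0\t35\t0"), clin)
  ann <- file.path(dir, "ann.tsv")
  writeLines(c("gene\tchrom\tarm\tstart\tend",
               "RB1\t13\tq\t48303748\t48481890",
               "CDKN2A\t9\tp\t21967752\t21995301",
               "BG_001\t5\tq\t1000\t2000"), ann)
  list(expr = expr, cna = cna, mut = maf, clinical = clin, ann = ann)
}
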