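# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# hand-built cohort: n_loci x n_samples with constant counts unless overridden
toy_cohort <- function(n_loci = 3, n_samples = 4,
                       tumor_a = 15L, tumor_b = 15L,
                       normal_a = 20L, normal_b = 20L,
                       arm = NULL) {
  loci <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(n_loci)),
    chrom = "1",
    pos = seq_len(n_loci) * 100L,
    arm = if (is.null(arm)) rep("1p", n_loci) else arm,
    ref = "A", alt = "G",
    maf = 0.2,
    stringsAsFactors = FALSE)
  samples <- sprintf("S%02d", seq_len(n_samples))
  m <- function(v) matrix(v, n_loci, n_samples)
  ai_cohort(loci, samples, m(tumor_a), m(tumor_b), m(normal_a), m(normal_b))
}

# model-faithful cohort for estimator calibration: complete clonal events so
# the expected tumor B fraction equals pi_true
calibration_config <- function(n_snps, n_samples, coverage_mean, pi_true,
                               seed, theta_true = 100) {
  sim_config(n_snps = n_snps, n_samples = n_samples, snps_per_arm = 1,
             coverage_mean = coverage_mean, het_prob = 1, event_rate = 1,
             promoted_fraction = 1, pi_true = pi_true, delta_true = 0,
             phi_true = 0.5, theta_true = theta_true, purity = 1,
             promotion = "expected", seed = seed)
}

# fully null cohort: no events, no technical bias
null_config <- function(n_snps, n_samples, coverage_mean, seed,
                        snps_per_arm = 10, theta_true = 100) {
  sim_config(n_snps = n_snps, n_samples = n_samples,
             snps_per_arm = snps_per_arm, coverage_mean = coverage_mean,
             het_prob = 1, event_rate = 0, pi_true = 0.5, delta_true = 0,
             phi_true = 0.5, theta_true = theta_true, purity = 1, seed = seed)
}

# counts data frame for one SNP from a cohort row (het samples only)
snp_counts <- function(cohort, i) {
  het <- cohort$is_het[i, ]
  data.frame(tumor_a = cohort$tumor_a[i, het],
             tumor_b = cohort$tumor_b[i, het],
             normal_a = cohort$normal_a[i, het],
             normal_b = cohort$normal_b[i, het])
}

# mean tumor BAF over heterozygous entries
het_tumor_baf_mean <- function(cohort) {
  tb <- cohort$tumor_b[cohort$is_het]
  ta <- cohort$tumor_a[cohort$is_het]
  mean(tb / (ta + tb))
}
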