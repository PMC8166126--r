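# Downstream statistics on the selection calls: deleteriousness enrichment,
# case/control allele-frequency shifts, gene-dependency skew, and resampled
# fraction comparisons across significance strata.

#' Classify a variant as deleterious
#'
#' Deleterious iff the CADD-style score is strictly greater than 10.
#'
#' @param cadd numeric deleteriousness score(s).
#' @return Logical vector.
#' @examples
#' classify_deleterious(c(15.2, 10, 0)) # TRUE FALSE FALSE
#' @export
classify_deleterious <- function(cadd) {
  if (any(!is.finite(cadd))) stop("cadd scores must be finite")
  cadd > 10
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability `P(X >= k)` of drawing at least `k` successes in a
#' selection of size `n` from a background of `N` items containing `K`
#' successes.
#'
#' @param k successes observed in the selection.
#' @param n selection size.
#' @param K successes in the background.
#' @param N background size.
#' @return One-sided enrichment p-value.
#' @examples
#' hypergeom_enrichment(4, 5, 4, 10) # 6/252
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > n || k > K || n > N || K > N)
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  if (n == N && k != K) stop("inconsistent counts: exhaustive draw needs k == K")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Case/control allele-frequency test
#'
#' Two-sided Fisher exact test on the 2x2 allele-count table (B vs A counts
#' in cases and controls). Exact at the small counts typical of rare
#' alleles. Downstream, per-SNP p-values go through [storey_qvalues()] and
#' are thresholded at q < 0.05 to label alleles as higher / lower in cancer.
#'
#' @param case_b,case_total B-allele count and total allele count in cases.
#' @param control_b,control_total same for the control population.
#' @return Two-sided p-value.
#' @examples
#' allele_freq_test(10, 20, 10, 20) # 1
#' @export
allele_freq_test <- function(case_b, case_total, control_b, control_total) {
  if (case_b > case_total || control_b > control_total ||
      any(c(case_b, case_total, control_b, control_total) < 0))
    stop("inconsistent allele counts")
  tab <- matrix(c(case_b, case_total - case_b,
                  control_b, control_total - control_b), nrow = 2)
  fisher.test(tab)$p.value
}

#' Germline B-allele frequencies of the case cohort
#'
#' Computes per-SNP case allele frequencies from normal-sample genotypes
#' (germline, not tumor counts): heterozygous calls contribute one B allele,
#' samples with normal BAF above 0.8 two, below 0.2 zero; samples with
#' insufficient normal coverage are excluded.
#'
#' @param cohort an `ai_cohort`.
#' @return Data frame with `snp_id`, `case_b` (B alleles), `case_total`
#'   (called alleles) and `case_af`.
#' @export
case_allele_freq <- function(cohort) {
  stopifnot(inherits(cohort, "ai_cohort"))
  tot <- cohort$normal_a + cohort$normal_b
  covered <- !is.na(tot) & tot > 20
  baf <- ifelse(covered & tot > 0, cohort$normal_b / tot, NA_real_)
  b_dose <- matrix(NA_real_, nrow(tot), ncol(tot))
  b_dose[covered & cohort$is_het] <- 1
  b_dose[covered & !cohort$is_het & baf > 0.8] <- 2
  b_dose[covered & !cohort$is_het & baf < 0.2] <- 0
  called <- !is.na(b_dose)
  data.frame(snp_id = cohort$loci$snp_id,
             case_b = rowSums(b_dose, na.rm = TRUE),
             case_total = 2 * rowSums(called),
             case_af = rowSums(b_dose, na.rm = TRUE) /
               pmax(2 * rowSums(called), 1),
             stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test on gene dependency scores
#'
#' Compares dependency scores of genes carrying selected alleles against the
#' background distribution. `alternative = "greater"` tests whether the
#' selected scores skew lower (their empirical CDF lies above the
#' background's).
#'
#' @param scores_selected,scores_background numeric score vectors.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`, as in
#'   [stats::ks.test()].
#' @return List with the KS statistic `D` and the p-value `p`.
#' @export
ks_dependency_test <- function(scores_selected, scores_background,
                               alternative = "two.sided") {
  if (!length(scores_selected) || !length(scores_background))
    stop("both score sets must be non-empty")
  kt <- suppressWarnings(ks.test(scores_selected, scores_background,
                                 alternative = alternative))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Percentile bootstrap of a class fraction
#'
#' Resamples a membership-flag vector with replacement and returns the mean
#' fraction with a percentile confidence interval — the sampling
#' distribution summarized in the stratified fraction comparisons.
#'
#' @param member_flags logical membership vector.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed optional integer seed.
#' @param conf confidence level.
#' @return List with `mean`, `low`, `high` and the replicate vector
#'   `replicates`.
#' @export
bootstrap_fraction_ci <- function(member_flags, n_boot = 1000L, seed = NULL,
                                  conf = 0.95) {
  flags <- as.logical(member_flags)
  if (!length(flags) || anyNA(flags)) stop("member_flags must be non-empty logicals")
  if (n_boot < 100) stop("n_boot must be at least 100")
  run <- function() {
    n <- length(flags)
    reps <- vapply(seq_len(n_boot),
                   function(i) mean(flags[sample.int(n, n, replace = TRUE)]),
                   numeric(1))
    a <- (1 - conf) / 2
    list(mean = mean(reps),
         low = unname(quantile(reps, a)),
         high = unname(quantile(reps, 1 - a)),
         replicates = reps)
  }
  if (is.null(seed)) run() else with_seed(as.integer(seed), run())
}

#' Fraction comparison across selection strata
#'
#' For every stratum (direction x nominal significance level) of the
#' selection calls, computes the fraction of flagged alleles (by default
#' deleterious, CADD > 10), the background fraction over all called SNPs,
#' their ratio, and the upper-tail hypergeometric enrichment p-value
#' (the complementary depletion tail is reported alongside). Pairwise
#' differences between strata are assessed on percentile-bootstrap replicate
#' fractions with Tukey's honest-significant-difference procedure.
#'
#' @param calls an `ai_calls` data frame.
#' @param annotations annotation data frame with `snp_id` plus either `cadd`
#'   or the column named by `flag_col`.
#' @param flag_col optional name of a logical annotation column to use as the
#'   class flag instead of `cadd > 10`.
#' @param levels nominal significance levels defining the strata.
#' @param n_boot bootstrap replicates per stratum for the Tukey comparison
#'   (0 disables it).
#' @param seed optional seed for the bootstrap.
#' @return List with `table` (one row per stratum: `direction`, `level`,
#'   `n_stratum`, `fraction_selected`, `fraction_background`, `ratio`,
#'   `p_enrich`, `p_deplete`) and `tukey` (the `TukeyHSD` result, or `NULL`).
#' @export
stratified_fraction_comparison <- function(calls, annotations,
                                           flag_col = NULL,
                                           levels = c(0.05, 0.01, 0.001),
                                           n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(calls, "data.frame"))
  i <- match(calls$snp_id, annotations$snp_id)
  if (anyNA(i)) stop("annotations are missing ", sum(is.na(i)), " snp_id(s)")
  flag <- if (is.null(flag_col)) classify_deleterious(annotations$cadd[i])
  else as.logical(annotations[[flag_col]][i])
  N <- length(flag)
  K <- sum(flag)
  strata <- expand.grid(direction = c("selected-for", "selected-against"),
                        level = sort(levels, decreasing = TRUE),
                        stringsAsFactors = FALSE)
  rows <- vector("list", nrow(strata))
  boot_reps <- list()
  for (s in seq_len(nrow(strata))) {
    in_str <- calls$direction == strata$direction[s] &
      calls$p_emp < strata$level[s]
    n <- sum(in_str)
    k <- sum(flag[in_str])
    frac <- if (n > 0) k / n else NA_real_
    rows[[s]] <- data.frame(
      direction = strata$direction[s], level = strata$level[s],
      n_stratum = n, fraction_selected = frac,
      fraction_background = K / N,
      ratio = if (n > 0) frac / (K / N) else NA_real_,
      p_enrich = if (n > 0) hypergeom_enrichment(k, n, K, N) else NA_real_,
      p_deplete = if (n > 0) phyper(k, K, N - K, n) else NA_real_,
      stringsAsFactors = FALSE)
    if (n_boot > 0 && n > 1) {
      bt <- bootstrap_fraction_ci(flag[in_str], n_boot = n_boot,
                                  seed = if (is.null(seed)) NULL else seed + s)
      boot_reps[[paste(strata$direction[s], strata$level[s], sep = "@")]] <-
        bt$replicates
    }
  }
  tab <- do.call(rbind, rows)
  tukey <- NULL
  if (length(boot_reps) >= 2) {
    df <- data.frame(
      frac = unlist(boot_reps, use.names = FALSE),
      stratum = factor(rep(names(boot_reps), lengths(boot_reps))))
    tukey <- TukeyHSD(aov(frac ~ stratum, data = df))
  }
  list(table = tab, tukey = tukey)
}

#' Per-allele case/control frequency calls
#'
#' Runs [allele_freq_test()] per SNP on germline case counts (from
#' [case_allele_freq()]) against control-population frequencies, converts
#' p-values to Storey q-values, and labels each allele `higher`, `lower` or
#' `ns` in cancer at `q_cut`.
#'
#' @param cohort an `ai_cohort`.
#' @param annotations annotation data frame with `snp_id` and `control_af`.
#' @param control_n number of control individuals (allele counts are
#'   `2 * control_n`); the reference control cohort has 699.
#' @param q_cut q-value threshold for the direction label.
#' @return Data frame: `snp_id`, `case_af`, `control_af`, `p`, `q`,
#'   `freq_direction`.
#' @export
allele_frequency_calls <- function(cohort, annotations, control_n = 699L,
                                   q_cut = 0.05) {
  caf <- case_allele_freq(cohort)
  i <- match(caf$snp_id, annotations$snp_id)
  control_af <- annotations$control_af[i]
  ctrl_tot <- 2L * as.integer(control_n)
  ctrl_b <- round(control_af * ctrl_tot)
  p <- mapply(function(cb, ct, kb) {
    if (ct == 0 || is.na(kb)) return(NA_real_)
    allele_freq_test(cb, ct, kb, ctrl_tot)
  }, caf$case_b, caf$case_total, ctrl_b)
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  if (any(ok)) q[ok] <- storey_qvalues(p[ok])
  dir <- rep("ns", length(p))
  dir[ok & q < q_cut & caf$case_af > control_af] <- "higher"
  dir[ok & q < q_cut & caf$case_af < control_af] <- "lower"
  data.frame(snp_id = caf$snp_id, case_af = caf$case_af,
             control_af = control_af, p = p, q = q, freq_direction = dir,
             stringsAsFactors = FALSE)
}
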