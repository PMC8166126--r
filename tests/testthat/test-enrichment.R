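test_that("deleterious classification uses the strict score cutoff", {
  expect_identical(classify_deleterious(c(15.2, 10, 0, 10.0001)),
                   c(TRUE, FALSE, FALSE, TRUE))
  expect_error(classify_deleterious(c(1, NA)), "finite")
})

test_that("hypergeometric enrichment matches exhaustive subset enumeration", {
  expect_equal(hypergeom_enrichment(4, 5, 4, 10), 6 / 252)
  expect_equal(hypergeom_enrichment(0, 5, 0, 10), 1)
  expect_equal(hypergeom_enrichment(4, 10, 4, 10), 1)  # exhaustive draw
  expect_error(hypergeom_enrichment(5, 4, 6, 10), "inconsistent")

  # enumeration oracle: draw every subset of size n from N items of which K
  # are successes, count subsets with >= k successes
  enum_p <- function(k, n, K, N) {
    subsets <- combn(N, n)
    mean(colSums(subsets <= K) >= k)
  }
  for (N in c(5, 8, 12)) {
    for (K in 0:N) {
      for (n in c(1, N %/% 2, N)) {
        k_lo <- max(0, K + n - N)   # smallest observable success count
        for (k in unique(c(k_lo, min(n, K)))) {
          expect_equal(hypergeom_enrichment(k, n, K, N), enum_p(k, n, K, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the case/control allele-frequency test is exact and symmetric", {
  expect_equal(allele_freq_test(10, 20, 10, 20), 1)
  # enumeration oracle: sum of hypergeometric table probabilities not larger
  # than the observed one, margins fixed
  enum_fisher <- function(a, n1, b, n2) {
    m <- a + b
    x <- max(0, m - n2):min(n1, m)
    pr <- dhyper(x, n1, n2, m)
    sum(pr[pr <= dhyper(a, n1, n2, m) * (1 + 1e-7)])
  }
  expect_equal(allele_freq_test(3, 10, 7, 10), enum_fisher(3, 10, 7, 10))
  expect_equal(allele_freq_test(3, 10, 7, 10), 0.17889, tolerance = 1e-4)
  # case/control swap and B/A relabeling leave p unchanged
  set.seed(4)
  for (i in 1:10) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    p <- allele_freq_test(a, n1, b, n2)
    expect_equal(allele_freq_test(b, n2, a, n1), p)
    expect_equal(allele_freq_test(n1 - a, n1, n2 - b, n2), p)
  }
  expect_error(allele_freq_test(5, 3, 1, 10), "inconsistent")
})

test_that("the dependency KS test matches a direct CDF-gap scan", {
  same <- c(1, 2, 3, 4)
  r <- ks_dependency_test(same, same)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  expect_equal(ks_dependency_test(1:5, 11:20)$D, 1)
  set.seed(9)
  x <- rnorm(30); y <- rnorm(30, -0.8)
  grid <- sort(c(x, y))
  d_oracle <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  r2 <- ks_dependency_test(x, y)
  expect_equal(r2$D, d_oracle)
  expect_equal(r2$p, suppressWarnings(ks.test(x, y))$p.value)
  # one-sided "skew lower" option
  expect_lt(ks_dependency_test(y, x, alternative = "greater")$p, 0.05)
  expect_error(ks_dependency_test(numeric(0), 1:3), "non-empty")
})

test_that("bootstrap fraction intervals behave and cover the truth", {
  all_true <- bootstrap_fraction_ci(rep(TRUE, 20), n_boot = 200, seed = 1)
  expect_equal(c(all_true$mean, all_true$low, all_true$high), c(1, 1, 1))
  set.seed(5)
  flags <- runif(100) < 0.4
  ci <- bootstrap_fraction_ci(flags, n_boot = 500, seed = 2)
  expect_lte(ci$low, mean(flags))
  expect_gte(ci$high, mean(flags))
  # coverage study: 200 seeded replications, true fraction 0.4, n = 100
  covered <- vapply(1:200, function(i) {
    f <- aiselect:::with_seed(1000 + i, runif(100) < 0.4)
    ci <- bootstrap_fraction_ci(f, n_boot = 200, seed = i)
    ci$low <= 0.4 && ci$high >= 0.4
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("stratified fractions reduce to ratio 1 when a stratum mirrors the background", {
  calls <- data.frame(snp_id = sprintf("s%d", 1:100),
                      pi_hat = rep(c(0.7, 0.3), 50),
                      stat = 0.2, p_emp = rep(c(0.001, 0.5), c(40, 60)),
                      q = 0.5,
                      direction = rep(c("selected-for", "selected-against"), 50))
  # deleterious flags split exactly in half inside and outside the stratum:
  # the selected-for stratum is the odd rows of 1..40, the flag has period 4
  ann <- data.frame(snp_id = calls$snp_id,
                    cadd = rep(c(20, 20, 1, 1), 25))
  res <- stratified_fraction_comparison(calls, ann, levels = 0.05, n_boot = 0)
  row_for <- res$table[res$table$direction == "selected-for", ]
  expect_equal(row_for$fraction_selected, row_for$fraction_background)
  expect_equal(row_for$ratio, 1)
  expect_gt(row_for$p_enrich, 0.05)
})

test_that("planted deleteriousness enrichment is recovered with Tukey comparisons", {
  set.seed(8)
  n <- 400
  p_emp <- c(runif(80, 0, 0.009), runif(320, 0.2, 1))  # 80 'selected' SNPs
  dirn <- sample(c("selected-for", "selected-against"), n, TRUE)
  sel <- p_emp < 0.01
  cadd <- ifelse(sel & runif(n) < 0.7, 15, ifelse(runif(n) < 0.25, 15, 3))
  calls <- data.frame(snp_id = sprintf("s%d", 1:n), pi_hat = 0.6, stat = 0.1,
                      p_emp = p_emp, q = 0.5, direction = dirn)
  ann <- data.frame(snp_id = calls$snp_id, cadd = cadd)
  res <- stratified_fraction_comparison(calls, ann, levels = c(0.05, 0.01),
                                        n_boot = 300, seed = 3)
  strong <- res$table[res$table$level == 0.01, ]
  expect_true(all(strong$ratio > 1))
  expect_true(all(strong$p_enrich < 0.05))
  expect_s3_class(res$tukey, "TukeyHSD")
  # nested strata use nested SNP sets
  tab <- res$table
  for (d in unique(tab$direction)) {
    n_strict <- tab$n_stratum[tab$direction == d & tab$level == 0.01]
    n_loose <- tab$n_stratum[tab$direction == d & tab$level == 0.05]
    expect_lte(n_strict, n_loose)
  }
})

test_that("hypergeometric stratum p-values are calibrated without association", {
  set.seed(13)
  hits <- 0
  for (i in 1:200) {
    flag <- runif(60) < 0.3
    in_str <- runif(60) < 0.25
    if (sum(in_str) == 0) next
    p <- hypergeom_enrichment(sum(flag & in_str), sum(in_str),
                              sum(flag), 60)
    hits <- hits + (p < 0.05)
  }
  expect_lte(hits / 200, 0.10)
})

test_that("case allele frequencies come from germline genotypes", {
  # 2 loci x 3 samples: sample genotypes het / hom-ref / hom-alt
  loci <- data.frame(snp_id = c("r1", "r2"), chrom = "1", pos = c(10L, 20L),
                     arm = "1p", ref = "A", alt = "C")
  na <- rbind(c(20L, 40L, 0L), c(20L, 20L, 20L))
  nb <- rbind(c(20L, 0L, 40L), c(22L, 18L, 21L))
  co <- ai_cohort(loci, c("s1", "s2", "s3"), na, nb, na, nb)
  caf <- case_allele_freq(co)
  expect_equal(caf$case_b, c(1 + 0 + 2, 3))      # r1: het + homA + homB
  expect_equal(caf$case_total, c(6, 6))
  expect_equal(caf$case_af, c(0.5, 0.5))
})

test_that("allele frequency calls label directions at the q threshold", {
  sim <- simulate_cohort(sim_config(n_snps = 30, n_samples = 60, het_prob = 0.5,
                                    coverage_mean = 60, seed = 61))
  ann <- simulate_annotations(sim, 0, seed = 62)$annotations
  fc <- allele_frequency_calls(sim$cohort, ann, control_n = 699)
  expect_identical(nrow(fc), 30L)
  expect_true(all(fc$freq_direction %in% c("higher", "lower", "ns")))
  expect_true(all(fc$p > 0 & fc$p <= 1, na.rm = TRUE))
})
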