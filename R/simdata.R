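# Synthetic paired tumor/normal allelic-count cohorts with full ground truth.
#
# The generative model is the inverse of the fitted one: per (sample, arm)
# allelic-imbalance events promote one homolog consistently for every SNP on
# the arm (phase-consistent), the tumor B-allele fraction at an event site is
# promoted_fraction (or its complement), normal contamination mixes the tumor
# fraction linearly toward 0.5, base-calling error and mapping bias distort
# both tissues identically, and counts are beta-binomial around the distorted
# fraction given negative-binomial total depths.

#' Simulation configuration
#'
#' Validates and completes the configuration for [simulate_cohort()]. Every
#' argument has a documented default representing a plausible whole-exome
#' tumor cohort; acceptance-style calibration runs override them explicitly.
#'
#' @param n_snps number of SNP loci.
#' @param n_samples number of patients (tumor/normal pairs).
#' @param snps_per_arm loci per chromosome arm; the number of arms is
#'   `ceiling(n_snps / snps_per_arm)`.
#' @param coverage_mean mean per-site total read depth (negative binomial).
#' @param coverage_dispersion negative-binomial dispersion of depth
#'   (variance = mu + dispersion * mu^2); `0` gives Poisson depths.
#' @param het_prob probability a sample is heterozygous at a SNP.
#' @param event_rate probability of an allelic-imbalance event per
#'   (sample, arm).
#' @param promoted_fraction expected tumor B-allele fraction at an event site
#'   when the B-carrying homolog is promoted; `1` models complete clonal loss
#'   of the other homolog.
#' @param pi_true per-SNP selection parameter in (0, 1): the probability that
#'   an event on a SNP's arm promotes the homolog carrying its B allele.
#'   Scalar or length-`n_snps` vector.
#' @param delta_true base-calling error in \[0, 0.1\].
#' @param phi_true reference-mapping bias in (0, 1); 0.5 = none.
#' @param theta_true beta-binomial precision (> 0) of the allelic counts.
#' @param purity tumor cell fraction in \[0, 1\]; contaminating normal cells
#'   contribute balanced alleles at heterozygous sites.
#' @param promotion `"stochastic"` (default): each event promotes one whole
#'   homolog, drawn per (sample, arm), so per-sample tumor fractions are
#'   bimodal, as in clonal allelic imbalance. `"expected"`: every event site
#'   receives the cohort-expected tumor B fraction
#'   `pi_true * promoted_fraction + (1 - pi_true) * (1 - promoted_fraction)`,
#'   i.e. counts are drawn from the fitted model's own observation law —
#'   the mode used for estimator-calibration studies (see the vignette).
#' @param seed integer random seed (mandatory).
#' @return Object of class `ai_sim_config`.
#' @export
sim_config <- function(n_snps = 100L, n_samples = 100L, snps_per_arm = 10L,
                       coverage_mean = 60, coverage_dispersion = 0.3,
                       het_prob = 0.4, event_rate = 0.3,
                       promoted_fraction = 0.7, pi_true = 0.5,
                       delta_true = 0.002, phi_true = 0.5, theta_true = 80,
                       purity = 0.9, promotion = c("stochastic", "expected"),
                       seed = NULL) {
  cfg <- list(n_snps = as.integer(n_snps), n_samples = as.integer(n_samples),
              snps_per_arm = as.integer(snps_per_arm),
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              het_prob = het_prob, event_rate = event_rate,
              promoted_fraction = promoted_fraction, pi_true = pi_true,
              delta_true = delta_true, phi_true = phi_true,
              theta_true = theta_true, purity = purity,
              promotion = match.arg(promotion),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  chk <- function(ok, field, msg) if (!ok) stop("invalid '", field, "': ", msg)
  chk(cfg$n_snps >= 1, "n_snps", "need at least one SNP")
  chk(cfg$n_samples >= 1, "n_samples", "need at least one sample")
  chk(cfg$snps_per_arm >= 1, "snps_per_arm", "must be >= 1")
  chk(cfg$coverage_mean >= 1, "coverage_mean", "must be >= 1")
  chk(cfg$coverage_dispersion >= 0, "coverage_dispersion", "must be >= 0")
  for (f in c("het_prob", "event_rate", "purity"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must lie in [0, 1]")
  chk(cfg$promoted_fraction >= 0 && cfg$promoted_fraction <= 1,
      "promoted_fraction", "must lie in [0, 1]")
  chk(all(cfg$pi_true > 0 & cfg$pi_true < 1), "pi_true",
      "must lie strictly inside (0, 1)")
  chk(length(cfg$pi_true) %in% c(1L, cfg$n_snps), "pi_true",
      "must be scalar or length n_snps")
  chk(cfg$delta_true >= 0 && cfg$delta_true <= 0.1, "delta_true",
      "must lie in [0, 0.1]")
  chk(cfg$phi_true > 0 && cfg$phi_true < 1, "phi_true",
      "must lie strictly inside (0, 1)")
  chk(cfg$theta_true > 0, "theta_true", "must be positive")
  chk(!is.null(cfg$seed), "seed", "a seed is mandatory")
  structure(cfg, class = "ai_sim_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

draw_depth <- function(n, cfg) {
  d <- if (cfg$coverage_dispersion <= 0) stats::rpois(n, cfg$coverage_mean)
  else rnbinom(n, mu = cfg$coverage_mean, size = 1 / cfg$coverage_dispersion)
  pmax(d, 1L)
}

# beta-binomial draw around mean p with precision theta; p of 0/1 degenerate
rbetabinom_mat <- function(ntot, p, theta) {
  q <- p
  inner <- p > 0 & p < 1
  q[inner] <- rbeta(sum(inner), p[inner] * theta, (1 - p[inner]) * theta)
  yb <- rbinom(length(ntot), ntot, q)
  array(yb, dim = dim(ntot))
}

#' Simulate a paired tumor/normal cohort with ground truth
#'
#' See [sim_config()] for the generative assumptions. Within one
#' (sample, arm) every SNP shares the promoted homolog; the homolog is drawn
#' with probability proportional to the product over the sample's
#' heterozygous SNPs on the arm of `pi_true` (if the homolog carries that
#' SNP's B allele) or `1 - pi_true`, so that marginally over samples the
#' B-carrying homolog of a SNP is promoted with probability `pi_true`
#' whenever it is the arm's only non-null SNP.
#'
#' @param config an [sim_config()] object.
#' @return List of class `ai_sim` with elements `cohort` (an `ai_cohort`),
#'   `truth` (per-SNP true pi, per-(sample, arm) event/promoted-homolog
#'   table, phase and genotype matrices) and `config`. Regeneration with the
#'   same config is bit-identical.
#' @examples
#' sim <- simulate_cohort(sim_config(n_snps = 4, n_samples = 6, seed = 1))
#' sim$cohort
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "ai_sim_config"))
    stop("config must come from sim_config()")
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  ns <- cfg$n_snps; np <- cfg$n_samples
  n_arms <- ceiling(ns / cfg$snps_per_arm)
  arm_pool <- paste0(rep(seq_len(ceiling(n_arms / 2)), each = 2), c("p", "q"))
  arm <- rep(arm_pool[seq_len(n_arms)], each = cfg$snps_per_arm)[seq_len(ns)]
  chrom <- sub("[pq]$", "", arm)
  within <- stats::ave(seq_len(ns), arm, FUN = seq_along)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  loci <- data.frame(snp_id = sprintf("rs%06d", seq_len(ns)),
                     chrom = chrom, pos = 10000L + within * 1500L, arm = arm,
                     ref = ref, alt = alt,
                     gene = sprintf("GENE%04d", ceiling(seq_len(ns) / 2)),
                     maf = round(runif(ns, 0.05, 0.5), 4),
                     stringsAsFactors = FALSE)
  samples <- sprintf("S%04d", seq_len(np))
  pi_true <- rep_len(cfg$pi_true, ns)

  # genotypes: 0 hom-A, 1 het, 2 hom-B
  geno <- matrix(NA_integer_, ns, np)
  ishet <- matrix(runif(ns * np) < cfg$het_prob, ns, np)
  geno[ishet] <- 1L
  geno[!ishet] <- ifelse(runif(sum(!ishet)) < 0.5, 0L, 2L)

  # phase: homolog carrying the B allele at het sites
  b_hom <- matrix(NA_integer_, ns, np)
  b_hom[ishet] <- ifelse(runif(sum(ishet)) < 0.5, 1L, 2L)

  # per (arm, sample) events and promoted homolog
  arm_f <- factor(arm, levels = unique(arm))
  n_arm <- nlevels(arm_f)
  event <- matrix(runif(n_arm * np) < cfg$event_rate, n_arm, np,
                  dimnames = list(levels(arm_f), samples))
  l1 <- ifelse(ishet & b_hom == 1L, log(pi_true), log1p(-pi_true))
  l1[!ishet] <- 0
  l2 <- ifelse(ishet & b_hom == 2L, log(pi_true), log1p(-pi_true))
  l2[!ishet] <- 0
  s1 <- rowsum(l1, arm_f)
  s2 <- rowsum(l2, arm_f)
  promoted <- matrix(ifelse(runif(n_arm * np) < plogis(s1 - s2), 1L, 2L),
                     n_arm, np)
  promoted[!event] <- NA_integer_

  # tumor-cell B fraction, then purity mixing (het sites only)
  arm_i <- as.integer(arm_f)
  f_t <- matrix(0.5, ns, np)
  if (cfg$promotion == "expected") {
    promoted[] <- NA_integer_
    ev_snp <- event[arm_i, , drop = FALSE]
    at_event <- ishet & ev_snp
    f_exp <- pi_true * cfg$promoted_fraction +
      (1 - pi_true) * (1 - cfg$promoted_fraction)
    f_t[at_event] <- matrix(f_exp, ns, np)[at_event]
  } else {
    prom_snp <- promoted[arm_i, , drop = FALSE]
    at_event <- ishet & !is.na(prom_snp)
    f_t[at_event] <- ifelse(b_hom[at_event] == prom_snp[at_event],
                            cfg$promoted_fraction, 1 - cfg$promoted_fraction)
  }
  f_t <- cfg$purity * f_t + (1 - cfg$purity) * 0.5
  f_t[geno == 0L] <- 0
  f_t[geno == 2L] <- 1
  f_n <- matrix(0.5, ns, np)
  f_n[geno == 0L] <- 0
  f_n[geno == 2L] <- 1

  p_t <- distort_fraction(f_t, cfg$delta_true, cfg$phi_true)
  p_n <- distort_fraction(f_n, cfg$delta_true, cfg$phi_true)

  nt <- matrix(draw_depth(ns * np, cfg), ns, np)
  nn <- matrix(draw_depth(ns * np, cfg), ns, np)
  tb <- rbetabinom_mat(nt, p_t, cfg$theta_true)
  nb <- rbetabinom_mat(nn, p_n, cfg$theta_true)

  cohort <- ai_cohort(loci, samples,
                      tumor_a = nt - tb, tumor_b = tb,
                      normal_a = nn - nb, normal_b = nb)
  events_df <- data.frame(
    sample_id = rep(samples, each = n_arm),
    arm = rep(levels(arm_f), np),
    event = as.vector(event),
    promoted_homolog = as.vector(promoted),
    stringsAsFactors = FALSE)
  truth <- list(pi_true = setNames(pi_true, loci$snp_id),
                events = events_df,
                phase = b_hom, genotype = geno)
  dimnames(truth$phase) <- dimnames(truth$genotype) <-
    list(loci$snp_id, samples)
  structure(list(cohort = cohort, truth = truth, config = cfg),
            class = "ai_sim")
}

#' @export
print.ai_sim <- function(x, ...) {
  cat("Synthetic cohort (seed", x$config$seed, "):\n")
  print(x$cohort)
  ev <- x$truth$events
  cat("  AI events:", sum(ev$event), "of", nrow(ev), "(sample, arm) pairs\n")
  pt <- x$truth$pi_true
  cat("  non-null pi_true loci:", sum(abs(pt - 0.5) > 1e-12), "\n")
  invisible(x)
}

#' Simulate SNP annotations and gene dependency scores
#'
#' Emits per-SNP deleteriousness (CADD-like) scores and control-population
#' allele frequencies, and per-gene dependency scores (lower = more
#' essential), with optional planted association to the simulated selection
#' signal: when `assoc_strength > 0`, SNPs whose true pi is far from 0.5
#' receive stochastically higher scores, control frequencies shifted against
#' the selection direction, and (for selected-for loci) lower gene dependency
#' scores.
#'
#' @param sim an `ai_sim` from [simulate_cohort()].
#' @param assoc_strength non-negative association strength; `0` plants no
#'   signal.
#' @param seed integer seed.
#' @return List with `annotations` (`snp_id`, `gene`, `maf`, `cadd`,
#'   `control_af`) and `dependencies` (`gene`, `dependency_score`).
#' @export
simulate_annotations <- function(sim, assoc_strength = 0, seed) {
  if (!inherits(sim, "ai_sim")) stop("sim must come from simulate_cohort()")
  if (assoc_strength < 0) stop("assoc_strength must be non-negative")
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  with_seed(as.integer(seed), {
    loci <- sim$cohort$loci
    sel <- 2 * abs(sim$truth$pi_true - 0.5)       # 0 (null) .. 1
    dir <- 2 * (sim$truth$pi_true - 0.5)          # signed selection
    # background CADD scale 8 -> ~29% deleterious (score > 10)
    cadd <- rexp(nrow(loci), rate = 1 / (8 + 12 * assoc_strength * sel))
    base_af <- runif(nrow(loci), 0.05, 0.5)
    control_af <- pmin(pmax(base_af - 0.3 * assoc_strength * dir, 0.001), 0.999)
    ann <- data.frame(snp_id = loci$snp_id, gene = loci$gene, maf = loci$maf,
                      cadd = round(unname(cadd), 3),
                      control_af = round(unname(control_af), 4),
                      stringsAsFactors = FALSE)
    genes <- unique(loci$gene)
    pos_sel <- vapply(genes, function(g)
      max(c(0, dir[loci$gene == g])), numeric(1))
    dep <- rnorm(length(genes), 0, 0.4) - 0.8 * assoc_strength * pos_sel
    deps <- data.frame(gene = genes, dependency_score = round(unname(dep), 4),
                       stringsAsFactors = FALSE)
    list(annotations = ann, dependencies = deps)
  })
}

#' Write / read a simulation configuration
#'
#' Configurations are persisted as YAML; the seed is mandatory.
#'
#' @param config an `ai_sim_config`.
#' @param path file path.
#' @return `write_sim_config()` the path, invisibly; `read_sim_config()` an
#'   `ai_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "ai_sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
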