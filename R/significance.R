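# Permutation null, empirical p-values, Storey q-values and selection calls.
#
# The permutation swaps the parental labels of whole chromosome arms: for
# each (sample, arm) independently, with probability 0.5 every A count on the
# arm is relabeled B and vice versa, in tumor AND matched normal. Phase is
# preserved (all alleles of the arm swap together, or none do); the only
# thing randomized is which parental homolog carries the amplification or
# deletion, which is exactly the signal the selection parameter measures.

#' Swap parental allele labels per chromosome arm
#'
#' For each (sample, arm) independently, with probability 0.5 swaps the A and
#' B counts of every SNP on that arm in both tumor and normal. Totals and
#' heterozygote calls are unchanged.
#'
#' Uses R's current RNG stream unless `seed` is given, in which case the
#' caller's RNG state is left untouched.
#'
#' @param cohort an `ai_cohort` with arm labels.
#' @param seed optional integer seed for this draw.
#' @return The permuted cohort; the logical (arm x sample) swap matrix is
#'   attached as attribute `"swaps"`.
#' @export
permute_arm_labels <- function(cohort, seed = NULL) {
  if (!is.null(seed))
    return(with_seed(as.integer(seed), permute_arm_labels(cohort)))
  stopifnot(inherits(cohort, "ai_cohort"))
  arm <- cohort$loci$arm
  if (is.null(arm) || anyNA(arm)) stop("cohort loci must carry arm labels")
  arm_f <- factor(arm, levels = unique(arm))
  n_arm <- nlevels(arm_f)
  np <- length(cohort$samples)
  swaps <- matrix(runif(n_arm * np) < 0.5, n_arm, np,
                  dimnames = list(levels(arm_f), cohort$samples))
  sw <- swaps[as.integer(arm_f), , drop = FALSE]  # snp x sample
  out <- cohort
  out$tumor_a[sw] <- cohort$tumor_b[sw]
  out$tumor_b[sw] <- cohort$tumor_a[sw]
  out$normal_a[sw] <- cohort$normal_b[sw]
  out$normal_b[sw] <- cohort$normal_a[sw]
  attr(out, "swaps") <- swaps
  out
}

#' Build the pooled permutation null distribution
#'
#' Repeats arm-label permutation `n_perms` times, refits every SNP, and pools
#' the statistic `abs(0.5 - pi)` across all permutations and SNPs. Refits are
#' warm-started at the observed fit plus a central start at pi = 0.5;
#' non-converged refits are dropped and counted.
#'
#' @param cohort the (filtered) `ai_cohort`.
#' @param fit the observed [ai_fit()] (used for warm starts); if `NULL`, it
#'   is computed.
#' @param n_perms number of permutation iterations (the reference analysis
#'   uses 1000).
#' @param seed integer seed for the swap draws.
#' @param priors,min_het,factr,maxit passed to the refits; defaults match
#'   [ai_fit()].
#' @return Object of class `ai_null`: `stats` (pooled values in \[0, 0.5\]),
#'   `n_perms`, `seed`, `n_dropped` (non-converged refits).
#' @export
build_null <- function(cohort, fit = NULL, n_perms = 1000L, seed,
                       priors = ai_priors(), min_het = 1L,
                       factr = default_factr(), maxit = 200L) {
  stopifnot(inherits(cohort, "ai_cohort"))
  if (n_perms < 1) stop("n_perms must be >= 1")
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (is.null(fit))
    fit <- ai_fit(cohort, priors = priors, min_het = min_het,
                  factr = factr, maxit = maxit)
  warm <- as.matrix(fit$table[, c("pi", "delta", "phi", "theta")])
  central <- matrix(c(0.5, 0.005, 0.5, 100), nrow = 1,
                    dimnames = list(NULL, c("pi", "delta", "phi", "theta")))
  pool <- vector("list", n_perms)
  dropped <- 0L
  with_seed(as.integer(seed), {
    for (b in seq_len(n_perms)) {
      perm <- permute_arm_labels(cohort)
      fb <- ai_fit(perm, priors = priors, starts = central,
                   warm_starts = warm, min_het = min_het,
                   factr = factr, maxit = maxit)
      ok <- fb$table$converged & !is.na(fb$table$pi)
      dropped <- dropped + sum(!ok)
      pool[[b]] <- abs(0.5 - fb$table$pi[ok])
    }
  })
  stats <- unlist(pool, use.names = FALSE)
  if (!length(stats)) stop("no permutation refit converged")
  structure(list(stats = stats, n_perms = as.integer(n_perms),
                 seed = as.integer(seed), n_dropped = dropped),
            class = "ai_null")
}

#' @export
print.ai_null <- function(x, ...) {
  cat("Pooled permutation null:", length(x$stats), "values from",
      x$n_perms, "permutations (seed", x$seed, ")\n")
  cat("  dropped (non-converged):", x$n_dropped, "\n")
  cat("  quantiles of abs(0.5 - pi):\n")
  print(round(quantile(x$stats, c(0.5, 0.9, 0.95, 0.99)), 4))
  invisible(x)
}

#' Empirical p-value against a pooled null
#'
#' Add-one rule: `p = (1 + #{null >= stat}) / (1 + pool size)`, guaranteeing
#' p > 0 and validity as a permutation p-value.
#'
#' @param stat observed statistic(s), `abs(0.5 - pi)`.
#' @param null an `ai_null` or a numeric vector of pooled null statistics.
#' @return Empirical p-value(s) in (0, 1\].
#' @export
empirical_pvalue <- function(stat, null) {
  pool <- if (inherits(null, "ai_null")) null$stats else as.numeric(null)
  if (!length(pool)) stop("the null distribution is empty")
  srt <- sort(pool)
  n_ge <- length(srt) - findInterval(stat - 1e-12, srt)
  (1 + n_ge) / (1 + length(srt))
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the p-value histogram over the
#' lambda grid 0.05, 0.10, ..., 0.95 with a cubic smoothing spline evaluated
#' at the largest lambda, then converts p-values to q-values by the usual
#' step-up over ranked p-values. With fewer than 10 p-values, pi0 is fixed at
#' 1 (Benjamini-Hochberg equivalent) with a message.
#'
#' @param pvals p-values in (0, 1\].
#' @param lambda tuning grid for the pi0 estimate.
#' @return Numeric q-values, same order as `pvals`, monotone in `pvals`;
#'   the pi0 estimate is attached as attribute `"pi0"`.
#' @export
storey_qvalues <- function(pvals, lambda = seq(0.05, 0.95, by = 0.05)) {
  p <- as.numeric(pvals)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (m < 10) {
    message("fewer than 10 p-values: using pi0 = 1")
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- cummin(pmin(q, 1))
  out <- numeric(m)
  out[o] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Call alleles under somatic selection
#'
#' Combines per-SNP MAP estimates with the pooled permutation null: each
#' converged SNP gets the statistic `abs(0.5 - pi)`, an empirical p-value, a
#' Storey q-value, a direction (selected-for when pi > 0.5, selected-against
#' when pi < 0.5, none at exactly 0.5) and indicators for the nominal
#' significance levels.
#'
#' @param fit an [ai_fit()].
#' @param null an `ai_null` from [build_null()].
#' @param alphas nominal significance levels for the indicator columns.
#' @param q_cut q-value threshold recorded in the result's attributes.
#' @return Data frame of class `ai_calls`: `snp_id`, `pi_hat`, `stat`,
#'   `p_emp`, `q`, `direction`, and one logical `sig_<alpha>` column per
#'   level. Non-converged SNPs are excluded (with a warning when present).
#' @export
call_selection <- function(fit, null, alphas = c(0.05, 0.01, 0.001),
                           q_cut = 0.1) {
  stopifnot(inherits(fit, "ai_fit"))
  tab <- fit$table
  bad <- !(tab$converged & !is.na(tab$pi))
  if (any(bad)) {
    warning(sum(bad), " non-converged fits excluded from selection calls")
    tab <- tab[!bad, , drop = FALSE]
  }
  stat <- abs(0.5 - tab$pi)
  p <- empirical_pvalue(stat, null)
  q <- storey_qvalues(p)
  dir <- ifelse(tab$pi > 0.5, "selected-for",
                ifelse(tab$pi < 0.5, "selected-against", "none"))
  out <- data.frame(snp_id = tab$snp_id, pi_hat = tab$pi, stat = stat,
                    p_emp = p, q = as.numeric(q), direction = dir,
                    stringsAsFactors = FALSE)
  for (a in sort(alphas, decreasing = TRUE))
    out[[paste0("sig_", format(a, scientific = FALSE))]] <- p < a
  attr(out, "q_cut") <- q_cut
  attr(out, "pi0") <- attr(q, "pi0")
  class(out) <- c("ai_calls", "data.frame")
  out
}

#' @export
print.ai_calls <- function(x, ...) {
  cat("Selection calls for", nrow(x), "SNPs (pi0 =",
      round(attr(x, "pi0"), 3), ")\n")
  sig_cols <- grep("^sig_", names(x), value = TRUE)
  for (sc in sig_cols) {
    n_for <- sum(x[[sc]] & x$direction == "selected-for")
    n_ag <- sum(x[[sc]] & x$direction == "selected-against")
    cat(sprintf("  %-10s selected-for %4d   selected-against %4d\n",
                sub("sig_", "alpha ", sc), n_for, n_ag))
  }
  qc <- attr(x, "q_cut")
  cat("  q <", qc, ":", sum(x$q < qc), "SNPs\n")
  invisible(x)
}

#' Persist and reload selection outputs
#'
#' `write_calls_table()` writes the calls data frame as TSV;
#' `write_null_distribution()` stores the pooled null as a single-column TSV
#' whose header comment records `n_perms` and `seed`;
#' `read_null_distribution()` inverts it.
#'
#' @param calls an `ai_calls` data frame.
#' @param null an `ai_null`.
#' @param path file path.
#' @return The path (writers, invisibly) or the reconstructed `ai_null`.
#' @export
write_calls_table <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_table
#' @export
write_null_distribution <- function(null, path) {
  stopifnot(inherits(null, "ai_null"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_perms=%d seed=%d n_dropped=%d",
                     null$n_perms, null$seed, null$n_dropped), con)
  writeLines("stat", con)
  writeLines(format(null$stats, digits = 15, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_calls_table
#' @export
read_null_distribution <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]])
  stats <- read.delim(path, skip = 1)$stat
  structure(list(stats = as.numeric(stats), n_perms = meta[1],
                 seed = meta[2], n_dropped = meta[3]),
            class = "ai_null")
}
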