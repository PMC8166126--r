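#' Beta-binomial log probability mass
#'
#' Mean-precision parameterization: the success probability is beta-distributed
#' with mean `p` and precision `theta`, i.e. shape parameters
#' \eqn{\alpha = p\theta}, \eqn{\beta = (1-p)\theta}. `theta` \eqn{\to\infty}
#' recovers the binomial; `theta = 2`, `p = 0.5` is discrete uniform on
#' `0:n`.
#'
#' @param k number of successes (vectorized).
#' @param n number of trials.
#' @param p mean success probability, strictly inside (0, 1).
#' @param theta precision, > 0.
#' @return Log probability mass, same length as the recycled arguments.
#' @examples
#' exp(betabinom_logpmf(0:10, 10, 0.5, 2)) # all 1/11
#' @export
betabinom_logpmf <- function(k, n, p, theta) {
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  if (any(theta <= 0)) stop("theta must be positive")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  a <- p * theta
  b <- (1 - p) * theta
  lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
}

#' Expected tumor and normal B-allele fractions
#'
#' Propagates the allele-fraction vector through the base-calling error mixing
#' matrix \eqn{E(\delta)} (off-diagonal \eqn{\delta}, diagonal
#' \eqn{1-\delta}) and the mapping-bias matrix
#' \eqn{M(\varphi) = \mathrm{diag}(2(1-\varphi), 2\varphi)}. The tumor starts
#' from \eqn{(1-\pi, \pi)}, the normal from \eqn{(0.5, 0.5)}; the per-sample
#' depth scale multiplies both components and cancels in the ratio, so it is
#' omitted.
#'
#' @param params list or vector with `pi`, `delta`, `phi` (a `theta` element
#'   is ignored).
#' @return List with `p_tumor` and `p_normal`, the expected B-allele shares.
#' @examples
#' expected_allele_fractions(list(pi = 0.7, delta = 0, phi = 0.5))$p_tumor # 0.7
#' @export
expected_allele_fractions <- function(params) {
  params <- as.list(params)
  pi <- params$pi; delta <- params$delta; phi <- params$phi
  if (is.null(pi) || is.null(delta) || is.null(phi))
    stop("params must contain pi, delta and phi")
  if (pi <= 0 || pi >= 1) stop("pi must lie strictly inside (0, 1)")
  if (delta < 0 || delta > 0.5) stop("delta must lie in [0, 0.5]")
  if (phi <= 0 || phi >= 1) stop("phi must lie strictly inside (0, 1)")
  out <- list(p_tumor = distort_fraction(pi, delta, phi),
              p_normal = distort_fraction(0.5, delta, phi))
  if (any(unlist(out) <= 0) || any(unlist(out) >= 1))
    stop("degenerate expected allele fraction (0 or 1)")
  out
}

# B-share of (1-f, f) %*% E(delta) %*% M(phi); vectorized in f
distort_fraction <- function(f, delta, phi) {
  a1 <- (1 - f) * (1 - delta) + f * delta
  b1 <- (1 - f) * delta + f * (1 - delta)
  a2 <- 2 * (1 - phi) * a1
  b2 <- 2 * phi * b1
  b2 / (a2 + b2)
}

#' Per-SNP log likelihood of the selection model
#'
#' Product over heterozygous samples of the tumor and normal beta-binomial
#' terms, both parameterized by the A-allele count with A-side means
#' \eqn{1 - p} and \eqn{1 - p'} from [expected_allele_fractions()], sharing
#' one precision `theta`. Conditions on the observed totals; there is no
#' marginal depth model.
#'
#' @param counts data frame (or list) with columns `tumor_a`, `tumor_b`,
#'   `normal_a`, `normal_b`, one row per heterozygous sample.
#' @param params list or vector with `pi`, `delta`, `phi`, `theta`.
#' @return Log likelihood; `0` for an empty sample set (log of an empty
#'   product).
#' @export
log_likelihood <- function(counts, params) {
  counts <- as.data.frame(counts)
  if (nrow(counts) == 0) return(0)
  need <- c("tumor_a", "tumor_b", "normal_a", "normal_b")
  if (!all(need %in% names(counts)))
    stop("counts must have columns ", paste(need, collapse = ", "))
  nt <- counts$tumor_a + counts$tumor_b
  nn <- counts$normal_a + counts$normal_b
  if (any(nt <= 0) || any(nn <= 0)) stop("every sample needs positive totals")
  params <- as.list(params)
  ef <- expected_allele_fractions(params)
  sum(betabinom_logpmf(counts$tumor_a, nt, 1 - ef$p_tumor, params$theta)) +
    sum(betabinom_logpmf(counts$normal_a, nn, 1 - ef$p_normal, params$theta))
}

#' Per-SNP log posterior
#'
#' [log_likelihood()] plus [prior_logdensity()]; `-Inf` outside the prior box
#' (rejected by the optimizer contract).
#'
#' @inheritParams log_likelihood
#' @param priors an [ai_priors()] object.
#' @return Log posterior (unnormalized).
#' @export
log_posterior <- function(params, counts, priors = ai_priors()) {
  lp <- prior_logdensity(priors, params)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(counts, params)
}

default_starts <- function() {
  m <- rbind(c(0.3, 0.005, 0.5, 100),
             c(0.5, 0.005, 0.5, 100),
             c(0.7, 0.005, 0.5, 100))
  colnames(m) <- c("pi", "delta", "phi", "theta")
  m
}

# lbfgsb terminates when the objective reduction falls below factr * eps;
# 1e-8 relative reduction is the model's convergence tolerance.
default_factr <- function() 1e-8 / .Machine$double.eps

#' MAP fit of the selection model for a single SNP
#'
#' Bounded quasi-Newton (L-BFGS-B) maximization of [log_posterior()] in
#' transformed coordinates (scaled logit for \eqn{\pi}, \eqn{\delta},
#' \eqn{\varphi}; logit of log \eqn{\theta}), from a deterministic
#' multi-start at \eqn{\pi \in \{0.3, 0.5, 0.7\}}. Ties in the objective
#' break toward the \eqn{\pi} closest to 0.5.
#'
#' @param counts data frame with `tumor_a`, `tumor_b`, `normal_a`, `normal_b`
#'   rows for the heterozygous samples of one SNP.
#' @param priors an [ai_priors()] object.
#' @param starts numeric matrix of starting points, 4 columns
#'   (`pi`, `delta`, `phi`, `theta`).
#' @param factr,maxit optimizer controls; the default `factr` corresponds to
#'   a 1e-8 relative objective reduction.
#' @return List of class `ai_map_fit`: `params` (named vector), `log_posterior`,
#'   `n_het`, `converged`, `n_iter`.
#' @examples
#' counts <- data.frame(tumor_a = c(12, 9), tumor_b = c(28, 33),
#'                      normal_a = c(21, 18), normal_b = c(19, 23))
#' fit_map(counts)$params
#' @export
fit_map <- function(counts, priors = ai_priors(), starts = default_starts(),
                    factr = default_factr(), maxit = 200L) {
  counts <- as.data.frame(counts)
  if (nrow(counts) < 1) stop("fit_map needs at least one heterozygous sample")
  ta <- matrix(as.numeric(counts$tumor_a), nrow = 1)
  tn <- matrix(as.numeric(counts$tumor_a + counts$tumor_b), nrow = 1)
  na <- matrix(as.numeric(counts$normal_a), nrow = 1)
  nn <- matrix(as.numeric(counts$normal_a + counts$normal_b), nrow = 1)
  r <- cpp_fit_cohort(ta, tn, na, nn, priors_matrix(priors), starts, NULL,
                      factr, 0, as.integer(maxit), 1L)[1, ]
  structure(list(params = c(pi = r[["pi"]], delta = r[["delta"]],
                            phi = r[["phi"]], theta = r[["theta"]]),
                 log_posterior = r[["log_posterior"]],
                 n_het = as.integer(r[["n_het"]]),
                 converged = r[["converged"]] == 1,
                 n_iter = as.integer(r[["n_iter"]])),
            class = "ai_map_fit")
}

#' @export
print.ai_map_fit <- function(x, ...) {
  cat("MAP fit over", x$n_het, "heterozygous samples",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$params, 4))
  cat("log posterior:", format(x$log_posterior), "\n")
  invisible(x)
}

#' Fit the selection model across a cohort
#'
#' The central modelling function: fits the per-SNP beta-binomial MAP model
#' to every locus of a cohort with at least `min_het` heterozygous samples.
#'
#' @param cohort an `ai_cohort` (from [simulate_cohort()] or
#'   [read_count_table()]) with heterozygote flags set.
#' @param priors an [ai_priors()] object.
#' @param starts multi-start matrix, see [fit_map()].
#' @param warm_starts optional n-SNP x 4 matrix of additional per-SNP starting
#'   points (used to warm-start permutation refits).
#' @param min_het minimum heterozygous samples for a SNP to be fitted.
#' @param factr,maxit optimizer controls.
#' @return Object of class `ai_fit` with a per-SNP coefficient table
#'   (`$table`: `snp_id`, `pi`, `delta`, `phi`, `theta`, `n_het`,
#'   `log_posterior`, `converged`), the priors and the call. Methods:
#'   `print`, `summary`, `coef`, `plot`.
#' @seealso [build_null()], [call_selection()]
#' @export
ai_fit <- function(cohort, priors = ai_priors(), starts = default_starts(),
                   warm_starts = NULL, min_het = 1L,
                   factr = default_factr(), maxit = 200L) {
  stopifnot(inherits(cohort, "ai_cohort"))
  mask <- cohort$is_het
  ta <- ifelse(mask, cohort$tumor_a, NA_real_)
  tb <- ifelse(mask, cohort$tumor_b, NA_real_)
  na <- ifelse(mask, cohort$normal_a, NA_real_)
  nb <- ifelse(mask, cohort$normal_b, NA_real_)
  m <- cpp_fit_cohort(ta, ta + tb, na, na + nb, priors_matrix(priors),
                      starts, warm_starts, factr, 0, as.integer(maxit),
                      as.integer(min_het))
  tab <- data.frame(snp_id = cohort$loci$snp_id,
                    pi = m[, "pi"], delta = m[, "delta"], phi = m[, "phi"],
                    theta = m[, "theta"], n_het = as.integer(m[, "n_het"]),
                    log_posterior = m[, "log_posterior"],
                    converged = m[, "converged"] == 1,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, priors = priors, min_het = as.integer(min_het),
                 call = match.call()),
            class = "ai_fit")
}

#' @export
print.ai_fit <- function(x, ...) {
  tab <- x$table
  cat("Allelic-selection model fit:", nrow(tab), "SNPs,",
      sum(tab$converged, na.rm = TRUE), "converged\n")
  ok <- tab$converged & !is.na(tab$pi)
  if (any(ok)) {
    cat("pi (B-allele promotion preference):\n")
    print(round(summary(tab$pi[ok]), 4))
  }
  invisible(x)
}

#' @export
summary.ai_fit <- function(object, ...) {
  tab <- object$table
  ok <- tab$converged & !is.na(tab$pi)
  out <- list(n_snps = nrow(tab), n_converged = sum(ok),
              n_skipped = sum(is.na(tab$pi)),
              pi_summary = if (any(ok)) summary(tab$pi[ok]) else NULL,
              theta_median = if (any(ok)) median(tab$theta[ok]) else NA_real_,
              mean_n_het = mean(tab$n_het))
  class(out) <- "summary.ai_fit"
  out
}

#' @export
print.summary.ai_fit <- function(x, ...) {
  cat("SNPs fitted:   ", x$n_snps, "\n")
  cat("  converged:   ", x$n_converged, "\n")
  cat("  skipped:     ", x$n_skipped, "(below min_het)\n")
  cat("  mean het/SNP:", round(x$mean_n_het, 1), "\n")
  if (!is.null(x$pi_summary)) {
    cat("pi estimates:\n")
    print(round(x$pi_summary, 4))
    cat("median theta:", round(x$theta_median, 1), "\n")
  }
  invisible(x)
}

#' @export
coef.ai_fit <- function(object, ...) {
  tab <- object$table
  m <- as.matrix(tab[, c("pi", "delta", "phi", "theta")])
  rownames(m) <- tab$snp_id
  m
}

#' @export
plot.ai_fit <- function(x, breaks = 40, ...) {
  ok <- x$table$converged & !is.na(x$table$pi)
  hist(x$table$pi[ok], breaks = breaks, main = "MAP selection parameter",
       xlab = expression(hat(pi)), col = "grey85", border = "grey40", ...)
  abline(v = 0.5, lty = 2)
  invisible(x)
}
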