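#' Prior specification for the selection model
#'
#' Builds the prior set for the four model parameters. Each prior is a named
#' list with a `family` (`"uniform"`, `"beta"` or `"loguniform"`), interval
#' bounds `lower` / `upper`, and for the beta family `shape1` / `shape2`.
#' Densities are used unnormalized over their truncation interval; only the
#' location of the posterior mode matters for MAP estimation.
#'
#' Defaults: \eqn{\pi} uniform on \[0.01, 0.99\] (agnostic about selection
#' direction), \eqn{\delta} Beta(1, 50) on \[1e-6, 0.1\] (base-calling error
#' is small), \eqn{\varphi} Beta(20, 20) on \[0.2, 0.8\] (mapping bias
#' centered on none), \eqn{\theta} log-uniform on \[1, 1e4\] (scale-free
#' precision). These are configurable stand-ins; see the package vignette.
#'
#' @param pi,delta,phi,theta single-parameter prior lists as described above.
#' @return An object of class `ai_priors`.
#' @examples
#' pr <- ai_priors()
#' pr$phi$shape1
#' @export
ai_priors <- function(pi = list(family = "uniform", lower = 0.01, upper = 0.99),
                      delta = list(family = "beta", shape1 = 1, shape2 = 50,
                                   lower = 1e-6, upper = 0.1),
                      phi = list(family = "beta", shape1 = 20, shape2 = 20,
                                 lower = 0.2, upper = 0.8),
                      theta = list(family = "loguniform", lower = 1, upper = 1e4)) {
  pr <- list(pi = pi, delta = delta, phi = phi, theta = theta)
  for (nm in names(pr)) {
    p <- pr[[nm]]
    if (is.null(p$family) || !p$family %in% c("uniform", "beta", "loguniform"))
      stop("prior for '", nm, "' must have family uniform, beta or loguniform")
    if (is.null(p$lower) || is.null(p$upper) || !is.finite(p$lower) ||
        !is.finite(p$upper) || p$lower >= p$upper)
      stop("prior for '", nm, "' needs finite bounds with lower < upper")
    if (p$family == "beta") {
      if (is.null(p$shape1) || is.null(p$shape2) || p$shape1 <= 0 || p$shape2 <= 0)
        stop("beta prior for '", nm, "' needs positive shape1 and shape2")
      if (p$lower < 0 || p$upper > 1)
        stop("beta prior for '", nm, "' must be truncated within [0, 1]")
    }
    if (p$family == "loguniform" && p$lower <= 0)
      stop("loguniform prior for '", nm, "' needs a positive lower bound")
  }
  if (pr$theta$lower <= 0) stop("theta prior must have a positive lower bound")
  structure(pr, class = "ai_priors")
}

#' @export
print.ai_priors <- function(x, ...) {
  cat("Model priors (unnormalized, truncated):\n")
  for (nm in names(x)) {
    p <- x[[nm]]
    extra <- if (p$family == "beta")
      sprintf(" shape = (%g, %g)", p$shape1, p$shape2) else ""
    cat(sprintf("  %-6s %-10s on [%g, %g]%s\n", nm, p$family, p$lower, p$upper, extra))
  }
  invisible(x)
}

# 4 x 5 numeric encoding consumed by the compiled fit loop
priors_matrix <- function(priors) {
  stopifnot(inherits(priors, "ai_priors"))
  fam_code <- c(uniform = 0, beta = 1, loguniform = 2)
  m <- t(vapply(priors, function(p) {
    c(fam_code[[p$family]],
      if (p$family == "beta") p$shape1 else 0,
      if (p$family == "beta") p$shape2 else 0,
      p$lower, p$upper)
  }, numeric(5)))
  dimnames(m) <- list(names(priors), c("family", "a", "b", "lower", "upper"))
  m
}

#' Log prior density of a parameter set
#'
#' Sum of the four independent (unnormalized) log prior densities; `-Inf`
#' outside the prior box.
#'
#' @param priors an [ai_priors()] object.
#' @param params numeric vector or list with elements `pi`, `delta`, `phi`,
#'   `theta`.
#' @return A single numeric log density.
#' @export
prior_logdensity <- function(priors, params) {
  stopifnot(inherits(priors, "ai_priors"))
  params <- as.list(params)
  tot <- 0
  for (nm in names(priors)) {
    p <- priors[[nm]]
    v <- params[[nm]]
    if (is.null(v) || !is.finite(v)) stop("params must contain finite '", nm, "'")
    if (v < p$lower || v > p$upper) return(-Inf)
    tot <- tot + switch(p$family,
      uniform = 0,
      beta = (p$shape1 - 1) * log(v) + (p$shape2 - 1) * log1p(-v),
      loguniform = -log(v))
  }
  tot
}
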