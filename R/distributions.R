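#' Fit a sampling distribution to a base value and 95% bounds
#'
#' Fits a parameter's probabilistic-sensitivity-analysis distribution by
#' moment matching, the usual health-technology-assessment convention: the
#' printed lower/upper bounds are read as a 95% interval, so
#' `sd = (upper - lower) / (2 * 1.96)`, and the distribution's mean is set
#' to the base value. Beta is used for probabilities, Gamma for
#' non-negative costs, Normal for unconstrained quantities.
#'
#' Moment matching preserves the mean and spread, not the quantiles, so the
#' fitted 2.5%/97.5% points only approximate the stated bounds (closely for
#' near-symmetric cases).
#'
#' @param base central (base-case) value; becomes the fitted mean.
#' @param lower,upper bounds with `lower <= base <= upper`.
#' @param family one of `"beta"`, `"gamma"`, `"normal"`.
#' @param name optional parameter name used in error messages.
#' @return an object of class `dist_spec`: a list with `family`, `base`,
#'   `lower`, `upper`, `sd` and the family-specific shape parameters
#'   (`shape1`/`shape2` for Beta, `shape`/`scale` for Gamma, `mean`/`sd`
#'   for Normal).
#' @examples
#' fit_distribution(0.52, 0.39, 0.65, "beta")
#' fit_distribution(3024, 2268, 3780, "gamma")
#' @export
fit_distribution <- function(base, lower, upper, family, name = "parameter") {
  family <- match.arg(tolower(family), c("beta", "gamma", "normal"))
  if (!(lower <= base && base <= upper)) {
    stop(sprintf("%s: bounds must satisfy lower <= base <= upper", name),
         call. = FALSE)
  }
  sd <- (upper - lower) / (2 * 1.96)
  v <- sd^2
  spec <- list(family = family, base = base, lower = lower, upper = upper,
               sd = sd)
  if (family == "beta") {
    if (base <= 0 || base >= 1) {
      stop(sprintf("%s: Beta requires base in (0, 1)", name), call. = FALSE)
    }
    if (v > 0 && v >= base * (1 - base)) {
      stop(sprintf(
        "%s: variance %.4g too large for a Beta with mean %.4g", name, v, base),
        call. = FALSE)
    }
    if (v == 0) {
      spec$shape1 <- NA_real_
      spec$shape2 <- NA_real_
    } else {
      k <- base * (1 - base) / v - 1
      spec$shape1 <- base * k
      spec$shape2 <- (1 - base) * k
    }
  } else if (family == "gamma") {
    if (base < 0) {
      stop(sprintf("%s: Gamma requires a non-negative base", name),
           call. = FALSE)
    }
    if (v == 0 || base == 0) {
      spec$shape <- NA_real_
      spec$scale <- NA_real_
    } else {
      spec$shape <- base^2 / v
      spec$scale <- v / base
    }
  } else {
    spec$mean <- base
  }
  structure(spec, class = "dist_spec")
}

#' Sample from a fitted distribution
#'
#' @param spec a `dist_spec` from [fit_distribution()].
#' @param n number of draws.
#' @return numeric vector of length `n`. A degenerate spec (zero spread)
#'   returns the base value.
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$sd == 0) return(rep(spec$base, n))
  switch(spec$family,
    beta = rbeta(n, spec$shape1, spec$shape2),
    gamma = rgamma(n, shape = spec$shape, scale = spec$scale),
    normal = rnorm(n, spec$mean, spec$sd)
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("%s distribution: mean %.6g, sd %.6g (bounds [%.6g, %.6g])\n",
              x$family, x$base, x$sd, x$lower, x$upper))
  invisible(x)
}

# Fit every stochastic parameter in a configuration. Parameters with family
# "none" or degenerate bounds stay fixed at base.
fit_all_distributions <- function(config) {
  specs <- list()
  for (nm in names(config$parameters)) {
    p <- config$parameters[[nm]]
    if (is.null(p$dist) || identical(p$dist, "none") ||
        is.null(p$lower) || is.null(p$upper) ||
        is.na(p$lower) || is.na(p$upper) || p$lower == p$upper) {
      next
    }
    specs[[nm]] <- fit_distribution(p$base, p$lower, p$upper, p$dist,
                                    name = nm)
  }
  specs
}
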