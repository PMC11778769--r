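# Incremental cost and effect of one comparison at the given parameter
# values (vectorised over draws).
comparison_deltas <- function(config, intervention, comparator, values) {
  tot <- evaluate_totals_vec(config, values,
                             strategies = c(intervention, comparator))
  list(delta_cost = unname(tot$cost_inr[, intervention] -
                             tot$cost_inr[, comparator]),
       delta_effect = unname(tot$quitters[, intervention] -
                               tot$quitters[, comparator]))
}

#' One-way sensitivity analysis (tornado table)
#'
#' Varies each uncertain parameter in turn to its lower and upper bound,
#' holding every other parameter at base, and records the ICER of the
#' chosen comparison at each extreme. The swing (absolute difference
#' between the two ICERs) measures the parameter's leverage; rows are
#' returned sorted by swing, largest first, ready for a tornado diagram.
#'
#' If a bound makes the incremental effect zero the ICER on that side is
#' undefined: `NA` is recorded, the swing uses the defined side only, and a
#' warning is raised.
#'
#' @param config a `cea_config` object.
#' @param intervention,comparator strategy names to compare.
#' @return a tibble with columns `parameter`, `base` (the base-case value
#'   of the parameter), `icer_low`, `icer_high` (ICER with the parameter at
#'   its lower/upper bound) and `swing`, sorted by decreasing swing.
#' @export
owsa <- function(config, intervention, comparator) {
  stopifnot(inherits(config, "cea_config"))
  base_vals <- param_base_values(config)
  varied <- names(config$parameters)[vapply(config$parameters, function(p) {
    !is.null(p$lower) && !is.null(p$upper) &&
      !is.na(p$lower) && !is.na(p$upper)
  }, logical(1))]
  icer_at <- function(pname, value) {
    vals <- base_vals
    vals[[pname]] <- value
    d <- comparison_deltas(config, intervention, comparator, vals)
    icer(d$delta_cost, d$delta_effect)
  }
  rows <- lapply(varied, function(pname) {
    p <- config$parameters[[pname]]
    lo <- icer_at(pname, p$lower)
    hi <- icer_at(pname, p$upper)
    if (is.na(lo) || is.na(hi)) {
      warning(sprintf(
        "parameter '%s': incremental effect is zero at a bound; ICER undefined on that side",
        pname), call. = FALSE)
    }
    swing <- if (is.na(lo) && is.na(hi)) NA_real_
             else if (is.na(lo) || is.na(hi)) abs(c(lo, hi)[!is.na(c(lo, hi))])
             else abs(hi - lo)
    tibble::tibble(parameter = pname, base = p$base,
                   icer_low = lo, icer_high = hi, swing = swing)
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$swing, out$parameter), ]
}

#' Probabilistic sensitivity analysis by Monte-Carlo simulation
#'
#' Draws every uncertain parameter independently from its moment-matched
#' distribution ([fit_distribution()]): Beta for quit probabilities and
#' prevalences, Gamma for unit costs. Combined counselling effects are
#' recomputed from the sampled singleton quit rates within each iteration,
#' so the two arms of every comparison stay internally coherent. Normal
#' parameters (mean age) are sampled for completeness but enter no economic
#' computation. Stratum prevalences are renormalized within each iteration.
#'
#' @param config a `cea_config` object.
#' @param comparator name of the comparator strategy.
#' @param n number of Monte-Carlo iterations (default 1000).
#' @param seed integer seed; the run is reproducible given the same seed
#'   and configuration.
#' @param interventions strategies to contrast with the comparator;
#'   defaults to every other strategy.
#' @return an object of class `cea_psa`: a list with `draws` (a tibble of
#'   `iteration`, `intervention`, `delta_cost`, `delta_effect`), `samples`
#'   (a tibble of the sampled parameter values, one row per iteration),
#'   `n`, `seed` and `comparator`.
#' @export
run_psa <- function(config, comparator, n = 1000, seed = 1L,
                    interventions = NULL) {
  stopifnot(inherits(config, "cea_config"))
  if (is.null(interventions)) {
    interventions <- setdiff(names(config$strategies), comparator)
  }
  if (!comparator %in% names(config$strategies)) {
    stop(sprintf("unknown comparator '%s'", comparator), call. = FALSE)
  }
  specs <- fit_all_distributions(config)
  values <- param_base_values(config)
  withr::with_seed(as.integer(seed), {
    for (nm in names(specs)) values[[nm]] <- sample_dist(specs[[nm]], n)
  })
  tot <- evaluate_totals_vec(config, values,
                             strategies = c(interventions, comparator))
  draws <- dplyr::bind_rows(lapply(interventions, function(s) {
    tibble::tibble(
      iteration = seq_len(n), intervention = s,
      delta_cost = tot$cost_inr[, s] - tot$cost_inr[, comparator],
      delta_effect = tot$quitters[, s] - tot$quitters[, comparator]
    )
  }))
  samples <- tibble::as_tibble(
    as.data.frame(lapply(values[names(specs)], rep_len, n))
  )
  structure(list(draws = draws, samples = samples, n = n,
                 seed = as.integer(seed), comparator = comparator),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf(
    "Probabilistic sensitivity analysis: %d iterations, comparator %s, seed %d\n",
    x$n, x$comparator, x$seed))
  cat(sprintf("Interventions: %s\n",
              paste(unique(x$draws$intervention), collapse = ", ")))
  invisible(x)
}

#' Cost-effectiveness plane quadrant proportions
#'
#' Fraction of PSA iterations falling in each quadrant of the
#' cost-effectiveness plane for one comparison. Boundary draws (a zero
#' incremental cost or effect, measure-zero under continuous sampling) are
#' assigned to the favourable side: a zero effect difference counts as
#' "more effective", a zero cost difference as "less costly".
#'
#' @param psa a `cea_psa` object.
#' @param intervention intervention name present in the PSA draws.
#' @return named numeric vector of proportions summing to 1:
#'   `more_effective_less_costly`, `more_effective_more_costly`,
#'   `less_effective_less_costly`, `less_effective_more_costly`.
#' @export
quadrant_proportions <- function(psa, intervention) {
  stopifnot(inherits(psa, "cea_psa"))
  d <- psa$draws[psa$draws$intervention == intervention, ]
  if (nrow(d) == 0L) {
    stop(sprintf("no PSA draws for intervention '%s'", intervention),
         call. = FALSE)
  }
  eff <- d$delta_effect >= 0
  cheap <- d$delta_cost <= 0
  c(more_effective_less_costly = mean(eff & cheap),
    more_effective_more_costly = mean(eff & !cheap),
    less_effective_less_costly = mean(!eff & cheap),
    less_effective_more_costly = mean(!eff & !cheap))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the intervention
#' is cost-effective: the fraction of PSA iterations with a positive
#' incremental net monetary benefit, `wtp * delta_effect - delta_cost > 0`
#' (ties count as not cost-effective).
#'
#' @param psa a `cea_psa` object.
#' @param wtp_grid non-empty vector of non-negative willingness-to-pay
#'   values (INR per quitter).
#' @param interventions interventions to include; defaults to all in the
#'   PSA.
#' @return a tibble with columns `wtp`, `intervention`, `probability`.
#' @export
ceac <- function(psa, wtp_grid, interventions = NULL) {
  stopifnot(inherits(psa, "cea_psa"))
  if (length(wtp_grid) == 0L || any(wtp_grid < 0)) {
    stop("wtp_grid must be non-empty and non-negative", call. = FALSE)
  }
  if (is.null(interventions)) {
    interventions <- unique(psa$draws$intervention)
  }
  rows <- lapply(interventions, function(s) {
    d <- psa$draws[psa$draws$intervention == s, ]
    tibble::tibble(
      wtp = wtp_grid, intervention = s,
      probability = vapply(wtp_grid, function(l) {
        mean(l * d$delta_effect - d$delta_cost > 0)
      }, numeric(1))
    )
  })
  dplyr::bind_rows(rows)
}
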