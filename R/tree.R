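#' Combined quit rate of independently acting interventions
#'
#' Combines the quit probabilities of several cessation interventions under
#' the assumption that they act independently: the probability that at least
#' one succeeds is `1 - prod(1 - p)`. This is the rule used to form the
#' combined effect of counselling packages and pharmacotherapy stages, e.g.
#' enhanced counselling layered on top of brief behavioural advice.
#'
#' @param probabilities numeric vector of quit probabilities, each in
#'   \[0, 1\]. May be empty, in which case the combined rate is 0.
#' @return a single probability, `1 - prod(1 - probabilities)`. Always at
#'   least `max(probabilities)` and at most 1.
#' @examples
#' combined_quit_rate(c(0.83, 0.52)) # enhanced counselling + brief advice
#' combined_quit_rate(numeric(0))    # no intervention, no quitters
#' @export
combined_quit_rate <- function(probabilities) {
  probabilities <- as.numeric(probabilities)
  if (length(probabilities) == 0L) return(0)
  if (anyNA(probabilities) || any(probabilities < 0) || any(probabilities > 1)) {
    stop("quit probabilities must lie in [0, 1]", call. = FALSE)
  }
  1 - prod(1 - probabilities)
}

#' Stage reach probabilities in a sequential treatment pathway
#'
#' In the decision tree each treatment stage is attempted only by smokers
#' who did not quit at any earlier stage. Given the ordered stage quit
#' rates, returns the probability of reaching each stage: the first stage is
#' reached with probability 1 and stage j with probability
#' `prod(1 - q[1:(j-1)])`.
#'
#' @param quit_rates ordered numeric vector of per-stage quit probabilities.
#' @return numeric vector of the same length; non-increasing, starting at 1
#'   (empty input gives an empty vector).
#' @examples
#' stage_reach_probs(c(0.52, 0.6, 0.5))
#' @export
stage_reach_probs <- function(quit_rates) {
  quit_rates <- as.numeric(quit_rates)
  if (length(quit_rates) == 0L) return(numeric(0))
  if (anyNA(quit_rates) || any(quit_rates < 0) || any(quit_rates > 1)) {
    stop("quit probabilities must lie in [0, 1]", call. = FALSE)
  }
  c(1, cumprod(1 - quit_rates))[seq_along(quit_rates)]
}

#' Convert Indian rupees to US dollars
#'
#' @param amount amount in INR.
#' @param rate exchange rate, INR per USD; must be positive.
#' @return amount in USD (`amount / rate`).
#' @examples
#' inr_to_usd(359867788, 83.93)
#' @export
inr_to_usd <- function(amount, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0) {
    stop("exchange rate must be a single positive number (INR per USD)",
         call. = FALSE)
  }
  amount / rate
}

# ---- internal vectorised engine ------------------------------------------
#
# `values` is a named list of numeric vectors (all the same length n, or
# length 1), one entry per scalar parameter. Every computation below is
# elementwise over the n parameter draws, so the same code serves the base
# case (n = 1), one-way sensitivity analysis and the Monte-Carlo PSA.

param_base_values <- function(config) {
  lapply(config$parameters, function(p) p$base)
}

component_quit_vec <- function(component, values) {
  if (length(component$quit) == 0L) return(0)
  fail <- 1
  for (pname in component$quit) fail <- fail * (1 - values[[pname]])
  1 - fail
}

component_cost_vec <- function(component, values) {
  if (length(component$cost) == 0L) return(0)
  Reduce(`+`, values[component$cost])
}

# normalized stratum weights as a list of vectors, one per stratum
stratum_weights_vec <- function(config, values) {
  prevs <- lapply(config$strata$prevalence, function(p) values[[p]])
  total <- Reduce(`+`, prevs)
  if (any(total <= 0)) {
    stop("configuration error: stratum prevalences must have a positive sum",
         call. = FALSE)
  }
  lapply(prevs, function(p) p / total)
}

# expected combined quit rate and per-person cost for one stratum pathway
stratum_outcome_vec <- function(stage_names, config, values) {
  fail <- 1
  cost <- 0
  for (nm in stage_names) {
    comp <- config$components[[nm]]
    if (is.null(comp)) {
      stop(sprintf("configuration error: unknown component '%s'", nm),
           call. = FALSE)
    }
    q <- component_quit_vec(comp, values)
    unit <- component_cost_vec(comp, values)
    reach <- if (identical(comp$kind, "counselling")) 1 else fail
    cost <- cost + unit * reach
    fail <- fail * (1 - q)
  }
  list(quit_rate = 1 - fail, cost_per_person = cost)
}

# totals for every strategy: list of matrices (n draws x strategies)
evaluate_totals_vec <- function(config, values, strategies = NULL) {
  if (is.null(strategies)) strategies <- names(config$strategies)
  weights <- stratum_weights_vec(config, values)
  n <- max(vapply(values, length, 1L), 1L)
  cohort <- config$cohort_size
  quitters <- matrix(0, n, length(strategies),
                     dimnames = list(NULL, strategies))
  cost <- quitters
  for (s in strategies) {
    strat <- config$strategies[[s]]
    if (is.null(strat)) {
      stop(sprintf("unknown strategy '%s'", s), call. = FALSE)
    }
    for (k in seq_along(config$strata$label)) {
      lab <- config$strata$label[k]
      out <- stratum_outcome_vec(strat$stages[[lab]], config, values)
      n_s <- cohort * weights[[k]]
      quitters[, s] <- quitters[, s] + n_s * out$quit_rate
      cost[, s] <- cost[, s] + n_s * out$cost_per_person
    }
  }
  list(quitters = quitters, cost_inr = cost)
}

#' Evaluate one strategy on the decision tree
#'
#' Allocates the cohort across dependence strata by normalized prevalence,
#' runs the sequential quit/no-quit pathway configured for each stratum, and
#' accrues expected quitters and costs. Counselling costs are incurred by
#' every person entering a stratum; pharmacotherapy costs only by those who
#' reach that stage (i.e. did not quit earlier).
#'
#' @param config a `cea_config` object (see [load_config()]).
#' @param strategy name of a strategy defined in `config`.
#' @param values optional named list of parameter values overriding the base
#'   case (used by the sensitivity analyses); defaults to base values.
#' @return a tibble with one row per stratum plus a `"Total"` row; columns
#'   `strategy`, `stratum`, `n` (persons entering), `quit_rate`, `quitters`,
#'   `cost_inr`, `cost_usd`.
#' @examples
#' cfg <- base_case_config()
#' evaluate_strategy(cfg, "CS")
#' @export
evaluate_strategy <- function(config, strategy, values = NULL) {
  stopifnot(inherits(config, "cea_config"))
  if (is.null(values)) values <- param_base_values(config)
  strat <- config$strategies[[strategy]]
  if (is.null(strat)) {
    stop(sprintf("configuration error: unknown strategy '%s'", strategy),
         call. = FALSE)
  }
  weights <- stratum_weights_vec(config, values)
  rows <- lapply(seq_along(config$strata$label), function(k) {
    lab <- config$strata$label[k]
    out <- stratum_outcome_vec(strat$stages[[lab]], config, values)
    n_s <- config$cohort_size * weights[[k]][1]
    tibble::tibble(
      strategy = strategy, stratum = lab, n = n_s,
      quit_rate = out$quit_rate[1],
      quitters = n_s * out$quit_rate[1],
      cost_inr = n_s * out$cost_per_person[1]
    )
  })
  res <- dplyr::bind_rows(rows)
  total <- tibble::tibble(
    strategy = strategy, stratum = "Total", n = sum(res$n),
    quit_rate = sum(res$quitters) / sum(res$n),
    quitters = sum(res$quitters), cost_inr = sum(res$cost_inr)
  )
  res <- dplyr::bind_rows(res, total)
  res$cost_usd <- inr_to_usd(res$cost_inr, config$exchange_rate)
  res
}

#' Evaluate several strategies on the decision tree
#'
#' @inheritParams evaluate_strategy
#' @param strategies character vector of strategy names; defaults to every
#'   strategy in the configuration. Must be non-empty and free of
#'   duplicates.
#' @return a tibble stacking the [evaluate_strategy()] output of each
#'   strategy, in the order given.
#' @export
evaluate_strategies <- function(config, strategies = NULL, values = NULL) {
  stopifnot(inherits(config, "cea_config"))
  if (is.null(strategies)) strategies <- names(config$strategies)
  if (length(strategies) == 0L) {
    stop("no strategies to evaluate", call. = FALSE)
  }
  dup <- unique(strategies[duplicated(strategies)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate strategy name: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  dplyr::bind_rows(lapply(strategies, function(s) {
    tryCatch(evaluate_strategy(config, s, values = values),
             error = function(e) {
               stop(sprintf("strategy '%s': %s", s, conditionMessage(e)),
                    call. = FALSE)
             })
  }))
}

#' Extract per-strategy totals from an evaluation table
#'
#' @param evaluations output of [evaluate_strategies()].
#' @return a tibble with columns `strategy`, `quitters`, `cost_inr`,
#'   `cost_usd` (one row per strategy).
#' @export
strategy_totals <- function(evaluations) {
  out <- evaluations[evaluations$stratum == "Total",
                     c("strategy", "quitters", "cost_inr", "cost_usd")]
  tibble::as_tibble(out)
}
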