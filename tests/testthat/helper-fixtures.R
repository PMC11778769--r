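# Published per-strategy totals (cost in INR, expected quitters) for the
# four strategies, as transcribed from the source cost-effectiveness table;
# used as inputs to the incremental and dominance analyses.
published_totals <- function() {
  tibble::tibble(
    strategy = c("PS1", "PS2", "PS3", "CS"),
    quitters = c(98396, 91029, 98527, 90263),
    cost_inr = c(327083021, 362588359, 327545518, 359867788)
  )
}

# Build a minimal one-stratum configuration with the given stages, each
# stage with its own quit/cost parameter. `kinds` defaults to counselling
# for the first stage and pharmacotherapy afterwards.
make_linear_config <- function(quits, costs, kinds = NULL, cohort = 100,
                               extra_strategy = NULL) {
  k <- length(quits)
  if (is.null(kinds)) {
    kinds <- c("counselling", rep("pharmacotherapy", max(k - 1, 0)))
  }
  pars <- list(prev_1 = list(base = 1))
  comps <- list()
  stage_names <- character(k)
  for (j in seq_len(k)) {
    qn <- sprintf("q%d", j)
    cn <- sprintf("c%d", j)
    pars[[qn]] <- list(base = quits[j], lower = 0, upper = 1, dist = "beta")
    pars[[cn]] <- list(base = costs[j], dist = "gamma",
                       lower = costs[j] * 0.75, upper = costs[j] * 1.25)
    stage_names[j] <- sprintf("Stage %d", j)
    comps[[j]] <- list(name = stage_names[j], kind = kinds[j],
                       quit = list(qn), cost = list(cn))
  }
  strategies <- list(list(name = "S", stages = list("Only" = as.list(stage_names))))
  if (!is.null(extra_strategy)) strategies <- c(strategies, list(extra_strategy))
  raw <- list(
    cohort_size = cohort, wtp_threshold = 1e6, exchange_rate = 83.93,
    parameters = pars,
    strata = list(list(label = "Only", prevalence = "prev_1")),
    components = comps,
    strategies = strategies
  )
  suppressWarnings(ceatree:::config_from_list(raw))
}

# Hand-built PSA object for testing the summaries without running a model.
make_psa <- function(delta_cost, delta_effect, intervention = "A",
                     comparator = "B") {
  structure(list(
    draws = tibble::tibble(iteration = seq_along(delta_cost),
                           intervention = intervention,
                           delta_cost = delta_cost,
                           delta_effect = delta_effect),
    samples = tibble::tibble(), n = length(delta_cost), seed = 0L,
    comparator = comparator), class = "cea_psa")
}
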