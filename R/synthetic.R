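#' Specification for a synthetic model scenario
#'
#' Describes the shape of a randomly generated, internally consistent
#' parameter set with the same structure as the packaged base case: one
#' counselling stage per strategy plus a rising number of pharmacotherapy
#' stages across strata, Beta-distributed probabilities, Gamma-distributed
#' costs, and symmetric bounds at a fixed fraction of the base value (the
#' packaged base case uses 25%).
#'
#' @param n_strata number of dependence strata (>= 1).
#' @param n_strategies number of strategies (>= 1).
#' @param quit_range range the quit probabilities are drawn from (within
#'   (0, 1)).
#' @param cost_range range the unit costs are drawn from (positive).
#' @param half_width half-width of the parameter bounds as a fraction of
#'   the base value (default 0.25); probability bounds are clipped to
#'   \[0, 1\].
#' @param cohort_size cohort size of the generated scenario.
#' @param seed integer seed; generation is reproducible.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(n_strata = 4, n_strategies = 3,
                          quit_range = c(0.3, 0.8),
                          cost_range = c(50, 4000),
                          half_width = 0.25, cohort_size = 100000,
                          seed = 1L) {
  if (n_strata < 1 || n_strategies < 1) {
    stop("need at least one stratum and one strategy", call. = FALSE)
  }
  if (half_width < 0 || half_width > 1) {
    stop("half_width must lie in [0, 1]", call. = FALSE)
  }
  if (quit_range[1] <= 0 || quit_range[2] >= 1 ||
      quit_range[1] > quit_range[2]) {
    stop("quit_range must be an increasing interval inside (0, 1)",
         call. = FALSE)
  }
  if (cost_range[1] <= 0 || cost_range[1] > cost_range[2]) {
    stop("cost_range must be an increasing positive interval", call. = FALSE)
  }
  structure(list(n_strata = n_strata, n_strategies = n_strategies,
                 quit_range = quit_range, cost_range = cost_range,
                 half_width = half_width, cohort_size = cohort_size,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate a synthetic, internally consistent parameter set
#'
#' Draws a full model configuration at random: per-strategy counselling and
#' pharmacotherapy components with quit probabilities in the requested
#' range (Beta family, symmetric bounds clipped to \[0, 1\]), positive
#' costs (Gamma family), and stratum prevalences drawn from a flat simplex.
#' Stratum `k` of each strategy receives the counselling stage plus up to
#' two pharmacotherapy stages, mirroring the dose-escalation structure of
#' the base case. The result passes [validate_config()] and survives a
#' [write_config()] / [load_config()] round trip.
#'
#' @param spec a [scenario_spec()].
#' @return a validated `cea_config`.
#' @export
generate_parameter_set <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  withr::with_seed(spec$seed, {
    pars <- list()
    add_prob <- function(name) {
      base <- runif(1, spec$quit_range[1], spec$quit_range[2])
      pars[[name]] <<- list(base = base,
                            lower = max(0, base * (1 - spec$half_width)),
                            upper = min(1, base * (1 + spec$half_width)),
                            dist = "beta")
      name
    }
    add_cost <- function(name) {
      base <- runif(1, spec$cost_range[1], spec$cost_range[2])
      pars[[name]] <<- list(base = base,
                            lower = base * (1 - spec$half_width),
                            upper = base * (1 + spec$half_width),
                            dist = "gamma")
      name
    }
    # flat simplex (Dirichlet(1)) prevalences; they sum to 1 exactly
    w <- rexp(spec$n_strata)
    w <- w / sum(w)
    strata_labels <- sprintf("Stratum %d", seq_len(spec$n_strata))
    for (k in seq_len(spec$n_strata)) {
      base <- w[k]
      pars[[sprintf("prev_%d", k)]] <- list(
        base = base,
        lower = max(0, base * (1 - spec$half_width)),
        upper = min(1, base * (1 + spec$half_width)),
        dist = "beta")
    }
    comps <- list()
    strategies <- list()
    for (i in seq_len(spec$n_strategies)) {
      cname <- sprintf("Counsel %d", i)
      comps[[cname]] <- list(
        name = cname, kind = "counselling",
        quit = add_prob(sprintf("quit_counsel_%d", i)),
        cost = add_cost(sprintf("cost_counsel_%d", i)))
      pharms <- character(0)
      for (j in 1:2) {
        pname <- sprintf("Drug %d-%d", i, j)
        comps[[pname]] <- list(
          name = pname, kind = "pharmacotherapy",
          quit = add_prob(sprintf("quit_drug_%d_%d", i, j)),
          cost = add_cost(sprintf("cost_drug_%d_%d", i, j)))
        pharms <- c(pharms, pname)
      }
      stages <- lapply(seq_len(spec$n_strata), function(k) {
        c(cname, pharms[seq_len(min(k - 1, 2))])
      })
      names(stages) <- strata_labels
      sname <- sprintf("S%d", i)
      strategies[[sname]] <- list(name = sname, stages = stages)
    }
    config <- new_cea_config(list(
      cohort_size = spec$cohort_size,
      wtp_threshold = 2 * mean(spec$cost_range),
      wtp_alternative = NA_real_,
      exchange_rate = 83.93,
      parameters = pars,
      strata = tibble::tibble(label = strata_labels,
                              prevalence = sprintf("prev_%d",
                                                   seq_len(spec$n_strata))),
      components = comps, strategies = strategies,
      combined_effects = NULL, seed = spec$seed
    ))
    validate_config(config)
    config
  })
}

#' Generate strategy totals with known dominance structure
#'
#' Hand-constructs a set of strategy totals (cost, quitters) whose
#' dominance structure is known by construction, for exercising
#' [dominance_prune()]:
#' \describe{
#'   \item{`"frontier-only"`}{strictly increasing cost and effect with
#'     strictly increasing sequential ICERs — nothing should be removed.}
#'   \item{`"strict"`}{a frontier plus one planted strategy that is dearer
#'     and less effective than an existing one — strictly dominated.}
#'   \item{`"extended"`}{a frontier plus one planted strategy lying above
#'     the segment joining two adjacent frontier strategies — extendedly
#'     dominated.}
#' }
#'
#' @param kind one of `"strict"`, `"extended"`, `"frontier-only"`.
#' @param seed integer seed.
#' @param n_frontier number of frontier strategies (>= 3).
#' @return a list with `totals` (tibble of `strategy`, `quitters`,
#'   `cost_inr`) and `truth` (a list giving the planted strategy's name and
#'   expected elimination tag, or `NULL` for `"frontier-only"`).
#' @export
generate_dominance_scenario <- function(kind = c("strict", "extended",
                                                 "frontier-only"),
                                        seed = 1L, n_frontier = 4) {
  kind <- match.arg(kind)
  stopifnot(n_frontier >= 3)
  withr::with_seed(as.integer(seed), {
    effect <- cumsum(runif(n_frontier, 100, 1000))
    # strictly increasing incremental ICERs make every point a frontier point
    icers <- cumsum(runif(n_frontier, 1, 50))
    cost <- cumsum(c(runif(1, 1e4, 1e5), icers[-1] * diff(effect)))
    totals <- tibble::tibble(
      strategy = sprintf("F%d", seq_len(n_frontier)),
      quitters = effect, cost_inr = cost)
    truth <- NULL
    if (kind == "strict") {
      i <- sample(n_frontier, 1)
      planted <- tibble::tibble(
        strategy = "planted",
        quitters = effect[i] - runif(1, 1, 50),
        cost_inr = cost[i] + runif(1, 1, 1e3))
      totals <- dplyr::bind_rows(totals, planted)
      truth <- list(strategy = "planted", tag = "strictly-dominated")
    } else if (kind == "extended") {
      i <- sample(n_frontier - 1, 1)
      lambda <- runif(1, 0.3, 0.7)
      e_star <- effect[i] + lambda * (effect[i + 1] - effect[i])
      chord <- cost[i] + lambda * (cost[i + 1] - cost[i])
      # above the chord but still cheaper than the next frontier point:
      # more effective and dearer than i, less effective and cheaper than
      # i+1, so not strictly dominated, yet beaten by a mixture
      eps <- runif(1, 0.05, 0.9) * (cost[i + 1] - chord)
      planted <- tibble::tibble(strategy = "planted", quitters = e_star,
                                cost_inr = chord + eps)
      totals <- dplyr::bind_rows(totals, planted)
      truth <- list(strategy = "planted", tag = "extended-dominated")
    }
    # shuffle so input order carries no information
    totals <- totals[sample(nrow(totals)), ]
    list(totals = totals, truth = truth)
  })
}
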