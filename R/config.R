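# Configuration objects
#
# A `cea_config` is a validated list with:
#   cohort_size     persons in the hypothetical cohort
#   wtp_threshold   willingness to pay, INR per quitter
#   wtp_alternative optional second WTP constant carried for reference
#   exchange_rate   INR per USD
#   parameters      named list; each entry list(base, lower, upper, dist)
#                   with dist in {"beta","gamma","normal","none"}
#   strata          tibble(label, prevalence) where `prevalence` names a
#                   parameter holding the raw prevalence
#   components      named list; each entry list(name, kind, quit, cost)
#                   where quit/cost are character vectors of parameter
#                   names (quit rates are combined by combined_quit_rate,
#                   costs are summed)
#   strategies      named list; each entry list(name, stages) with stages a
#                   named list stratum label -> character vector of
#                   component names
#   combined_effects optional tibble of published combined quit rates kept
#                   for validation against combined_quit_rate()
#   seed            optional default seed

new_cea_config <- function(x) {
  structure(x, class = "cea_config")
}

#' @export
print.cea_config <- function(x, ...) {
  cat(sprintf(
    "Decision-tree CEA configuration: cohort %s, %d strata, %d components, %d strategies\n",
    format(x$cohort_size, big.mark = ","), nrow(x$strata),
    length(x$components), length(x$strategies)))
  cat(sprintf("WTP threshold: INR %s per quitter; exchange rate %.2f INR/USD\n",
              format(x$wtp_threshold, big.mark = ","), x$exchange_rate))
  invisible(x)
}

config_fail <- function(fmt, ...) {
  stop(sprintf(paste0("configuration error: ", fmt), ...), call. = FALSE)
}

#' Validate a model configuration
#'
#' Checks every structural invariant of a `cea_config`: parameter bounds
#' bracket the base value, probabilities lie in \[0, 1\], Beta is only used
#' for \[0, 1\] quantities and Gamma only for non-negative costs, strata and
#' component references resolve, strategy stage lists contain no duplicate
#' component within a stratum, and every strategy covers every stratum.
#'
#' @param config a `cea_config` (or plain list with the same structure).
#' @return the validated config, invisibly. Raises an error naming the
#'   offending field otherwise.
#' @export
validate_config <- function(config) {
  req <- c("cohort_size", "wtp_threshold", "exchange_rate", "parameters",
           "strata", "components", "strategies")
  miss <- setdiff(req, names(config))
  if (length(miss) > 0L) {
    config_fail("missing field(s): %s", paste(miss, collapse = ", "))
  }
  if (!is.numeric(config$cohort_size) || config$cohort_size <= 0) {
    config_fail("cohort_size must be a positive number")
  }
  if (!is.numeric(config$exchange_rate) || config$exchange_rate <= 0) {
    config_fail("exchange_rate must be positive (INR per USD)")
  }
  if (!is.numeric(config$wtp_threshold) || config$wtp_threshold < 0) {
    config_fail("wtp_threshold must be non-negative")
  }
  pars <- config$parameters
  if (length(pars) == 0L || is.null(names(pars)) || any(names(pars) == "")) {
    config_fail("parameters must be a non-empty named list")
  }
  for (nm in names(pars)) {
    p <- pars[[nm]]
    if (is.null(p$base) || !is.numeric(p$base)) {
      config_fail("parameter '%s': missing numeric base value", nm)
    }
    dist <- if (is.null(p$dist)) "none" else tolower(p$dist)
    if (!dist %in% c("beta", "gamma", "normal", "none")) {
      config_fail("parameter '%s': unknown distribution '%s'", nm, dist)
    }
    has_bounds <- !is.null(p$lower) && !is.null(p$upper) &&
      !is.na(p$lower) && !is.na(p$upper)
    if (has_bounds && !(p$lower <= p$base && p$base <= p$upper)) {
      config_fail("parameter '%s': bounds must satisfy lower <= base <= upper",
                  nm)
    }
    if (dist == "beta") {
      lo <- if (has_bounds) p$lower else p$base
      hi <- if (has_bounds) p$upper else p$base
      if (lo < 0 || hi > 1) {
        config_fail("parameter '%s': Beta requires values in [0, 1]", nm)
      }
    }
    if (dist == "gamma" && (p$base < 0 || (has_bounds && p$lower < 0))) {
      config_fail("parameter '%s': Gamma requires non-negative values", nm)
    }
  }
  st <- config$strata
  if (is.null(st$label) || is.null(st$prevalence)) {
    config_fail("strata must have 'label' and 'prevalence' columns")
  }
  if (anyDuplicated(st$label)) config_fail("duplicate stratum labels")
  for (i in seq_along(st$label)) {
    pref <- st$prevalence[i]
    if (!pref %in% names(pars)) {
      config_fail("stratum '%s': unknown prevalence parameter '%s'",
                  st$label[i], pref)
    }
    b <- pars[[pref]]$base
    if (b < 0 || b > 1) {
      config_fail("stratum '%s': prevalence must lie in [0, 1]", st$label[i])
    }
  }
  comps <- config$components
  if (anyDuplicated(names(comps))) config_fail("duplicate component names")
  for (nm in names(comps)) {
    cmp <- comps[[nm]]
    if (!identical(cmp$kind, "counselling") &&
        !identical(cmp$kind, "pharmacotherapy")) {
      config_fail("component '%s': kind must be counselling or pharmacotherapy",
                  nm)
    }
    for (pref in c(cmp$quit, cmp$cost)) {
      if (!pref %in% names(pars)) {
        config_fail("component '%s': unknown parameter '%s'", nm, pref)
      }
    }
    for (pref in cmp$quit) {
      b <- pars[[pref]]$base
      if (b < 0 || b > 1) {
        config_fail("component '%s': quit parameter '%s' outside [0, 1]",
                    nm, pref)
      }
    }
    for (pref in cmp$cost) {
      if (pars[[pref]]$base < 0) {
        config_fail("component '%s': cost parameter '%s' is negative",
                    nm, pref)
      }
    }
  }
  strat <- config$strategies
  if (length(strat) == 0L) config_fail("at least one strategy is required")
  if (anyDuplicated(names(strat))) config_fail("duplicate strategy names")
  for (nm in names(strat)) {
    stages <- strat[[nm]]$stages
    miss <- setdiff(st$label, names(stages))
    if (length(miss) > 0L) {
      config_fail("strategy '%s': no stage list for stratum '%s'",
                  nm, miss[1])
    }
    for (lab in names(stages)) {
      seqn <- stages[[lab]]
      if (anyDuplicated(seqn)) {
        config_fail("strategy '%s', stratum '%s': duplicate component in stage list",
                    nm, lab)
      }
      unknown <- setdiff(seqn, names(comps))
      if (length(unknown) > 0L) {
        config_fail("strategy '%s', stratum '%s': unknown component '%s'",
                    nm, lab, unknown[1])
      }
    }
  }
  invisible(config)
}

#' Load a model configuration from a YAML file
#'
#' Reads, validates and returns a `cea_config`. Raw stratum prevalences
#' need not sum to 1 (published prevalence tables often do not); the model
#' normalizes them so the whole cohort is allocated, and the loader warns
#' when the raw sum differs from 1.
#'
#' @param path path to a YAML configuration file (see the packaged
#'   `base_case.yaml` under `inst/extdata` for the schema).
#' @return a validated `cea_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  config_from_list(raw)
}

# Build and validate a cea_config from a plain (YAML-shaped) list.
config_from_list <- function(raw) {
  pars <- lapply(raw$parameters, function(p) {
    list(base = as.numeric(p$base),
         lower = if (is.null(p$lower)) NA_real_ else as.numeric(p$lower),
         upper = if (is.null(p$upper)) NA_real_ else as.numeric(p$upper),
         dist = if (is.null(p$dist)) "none" else tolower(p$dist))
  })
  strata <- tibble::tibble(
    label = vapply(raw$strata, function(s) s$label, character(1)),
    prevalence = vapply(raw$strata, function(s) s$prevalence, character(1))
  )
  comps <- list()
  for (cmp in raw$components) {
    comps[[cmp$name]] <- list(name = cmp$name, kind = cmp$kind,
                              quit = as.character(unlist(cmp$quit)),
                              cost = as.character(unlist(cmp$cost)))
  }
  strategies <- list()
  for (s in raw$strategies) {
    stages <- lapply(s$stages, function(x) as.character(unlist(x)))
    strategies[[s$name]] <- list(name = s$name, stages = stages)
  }
  combined <- NULL
  if (!is.null(raw$combined_effects)) {
    combined <- tibble::tibble(
      name = vapply(raw$combined_effects, function(x) x$name, character(1)),
      components = lapply(raw$combined_effects,
                          function(x) as.character(unlist(x$of))),
      base = vapply(raw$combined_effects, function(x) as.numeric(x$base),
                    numeric(1))
    )
  }
  config <- new_cea_config(list(
    cohort_size = as.numeric(raw$cohort_size),
    wtp_threshold = as.numeric(raw$wtp_threshold),
    wtp_alternative = if (is.null(raw$wtp_alternative)) NA_real_
                      else as.numeric(raw$wtp_alternative),
    exchange_rate = as.numeric(raw$exchange_rate),
    parameters = pars, strata = strata, components = comps,
    strategies = strategies, combined_effects = combined,
    seed = if (is.null(raw$seed)) NA_integer_ else as.integer(raw$seed)
  ))
  validate_config(config)
  prev_sum <- sum(vapply(strata$prevalence,
                         function(p) pars[[p]]$base, numeric(1)))
  if (abs(prev_sum - 1) > 1e-9) {
    warning(sprintf(
      "raw stratum prevalences sum to %.4g, not 1; weights are normalized so the full cohort is allocated",
      prev_sum), call. = FALSE)
  }
  config
}

#' Write a model configuration to a YAML file
#'
#' Inverse of [load_config()]: a written configuration loads back to an
#' identical object (round trip).
#'
#' @param config a `cea_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cea_config"))
  raw <- list(
    cohort_size = config$cohort_size,
    wtp_threshold = config$wtp_threshold,
    exchange_rate = config$exchange_rate,
    parameters = lapply(config$parameters, function(p) {
      out <- list(base = p$base)
      if (!is.na(p$lower)) out$lower <- p$lower
      if (!is.na(p$upper)) out$upper <- p$upper
      out$dist <- p$dist
      out
    }),
    strata = lapply(seq_len(nrow(config$strata)), function(i) {
      list(label = config$strata$label[i],
           prevalence = config$strata$prevalence[i])
    }),
    components = unname(lapply(config$components, function(cmp) {
      list(name = cmp$name, kind = cmp$kind,
           quit = as.list(cmp$quit), cost = as.list(cmp$cost))
    })),
    strategies = unname(lapply(config$strategies, function(s) {
      list(name = s$name, stages = lapply(s$stages, as.list))
    }))
  )
  if (!is.na(config$wtp_alternative)) {
    raw$wtp_alternative <- config$wtp_alternative
  }
  if (!is.null(config$combined_effects)) {
    raw$combined_effects <- lapply(seq_len(nrow(config$combined_effects)),
      function(i) {
        list(name = config$combined_effects$name[i],
             of = as.list(config$combined_effects$components[[i]]),
             base = config$combined_effects$base[i])
      })
  }
  if (!is.na(config$seed)) raw$seed <- config$seed
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' The packaged base-case configuration
#'
#' Loads the base-case parameter set shipped with the package: a 100,000
#' person cohort of smokers stratified by Fagerstrom index, published quit
#' rates and unit costs for brief behavioural intervention (BI), enhanced
#' counselling (EC), nicotine replacement therapy (2 mg / 4 mg), bupropion
#' and bupropion sustained release, and the four strategies compared in the
#' analysis (the current strategy CS and proposed strategies PS1–PS3).
#' The raw stratum prevalences sum to 0.98, so loading warns that weights
#' are normalized.
#'
#' @param quiet suppress the prevalence-normalization warning (default
#'   `TRUE`, since the normalization is a documented property of this
#'   parameter set).
#' @return a validated `cea_config`.
#' @export
base_case_config <- function(quiet = TRUE) {
  path <- system.file("extdata", "base_case.yaml", package = "ceatree")
  if (quiet) {
    suppressWarnings(load_config(path))
  } else {
    load_config(path)
  }
}
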