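#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_effect`, the extra money spent per extra quitter.
#' When the effect difference is zero the ratio is undefined and `NA` is
#' returned rather than an infinity, so callers can decide how to report it.
#'
#' @param delta_cost incremental cost (INR).
#' @param delta_effect incremental effect (quitters).
#' @return the ICER, or `NA` where `delta_effect == 0`. Vectorised.
#' @examples
#' icer(-32784767, 8133)
#' icer(5, 0) # NA
#' @export
icer <- function(delta_cost, delta_effect) {
  out <- delta_cost / delta_effect
  out[delta_effect == 0] <- NA_real_
  out
}

# Classification of an intervention-vs-comparator contrast.
# A negative ICER is deliberately never used to decide anything: the sign
# alone cannot distinguish "cheaper and better" from "dearer and worse".
classify_incremental <- function(delta_cost, delta_effect, icer_value, wtp) {
  if (delta_cost == 0 && delta_effect == 0) return("equivalent")
  if (delta_cost < 0 && delta_effect > 0) return("cost-saving")
  if (delta_cost > 0 && delta_effect < 0) return("dominated")
  if (delta_effect > 0) {
    if (!is.na(icer_value) && icer_value >= 0 && icer_value <= wtp) {
      return("cost-effective")
    }
    return("not-cost-effective")
  }
  # less (or equally) effective without being strictly dominated: never
  # recommended at face value
  "not-cost-effective"
}

#' Incremental analysis against a fixed comparator
#'
#' Computes, for every strategy except the comparator, the incremental cost,
#' incremental effect, ICER and a classification against the
#' willingness-to-pay threshold: `cost-saving` (cheaper and more effective),
#' `dominated` (dearer and less effective), `cost-effective`
#' (more effective with `0 <= ICER <= wtp`), `not-cost-effective`
#' otherwise, and `equivalent` when both differences are zero.
#'
#' @param totals a data frame with columns `strategy`, `quitters`,
#'   `cost_inr` — e.g. from [strategy_totals()], or totals transcribed from
#'   a published table.
#' @param comparator name of the comparator strategy (must appear in
#'   `totals`).
#' @param wtp willingness-to-pay threshold, INR per quitter.
#' @return a tibble with columns `intervention`, `comparator`, `delta_cost`,
#'   `delta_effect`, `icer`, `classification`.
#' @export
incremental_table <- function(totals, comparator, wtp) {
  totals <- as.data.frame(totals)
  stopifnot(all(c("strategy", "quitters", "cost_inr") %in% names(totals)))
  if (!comparator %in% totals$strategy) {
    stop(sprintf("comparator '%s' not among the evaluated strategies",
                 comparator), call. = FALSE)
  }
  ref <- totals[match(comparator, totals$strategy), ]
  rows <- totals[totals$strategy != comparator, , drop = FALSE]
  dc <- rows$cost_inr - ref$cost_inr
  de <- rows$quitters - ref$quitters
  ic <- icer(dc, de)
  cls <- vapply(seq_along(dc), function(i) {
    classify_incremental(dc[i], de[i], ic[i], wtp)
  }, character(1))
  tibble::tibble(
    intervention = rows$strategy, comparator = comparator,
    delta_cost = dc, delta_effect = de, icer = ic, classification = cls
  )
}

#' Dominance pruning and the cost-effectiveness frontier
#'
#' Sorts strategies by effectiveness, removes strictly dominated strategies
#' (another strategy is at least as cheap and at least as effective, and
#' strictly better on one axis), then repeatedly removes extendedly
#' dominated strategies (a strategy whose incremental ICER over the previous
#' retained strategy exceeds the next sequential ICER, so a mixture of its
#' neighbours outperforms it) until the sequential ICERs along the frontier
#' are strictly increasing.
#'
#' Ties are deterministic: with equal effectiveness the cheaper strategy is
#' kept; strategies identical on both axes keep the first by input order and
#' the rest are tagged strictly dominated.
#'
#' @param totals a data frame with columns `strategy`, `quitters`,
#'   `cost_inr` (see [incremental_table()]).
#' @return an object of class `cea_frontier`: a list with
#'   \describe{
#'     \item{retained}{tibble of frontier strategies in increasing
#'       effectiveness order, with `icer_sequential` between adjacent
#'       frontier strategies (`NA` for the first).}
#'     \item{eliminated}{tibble of removed strategies with a `tag` of
#'       `"strictly-dominated"` or `"extended-dominated"`.}
#'   }
#' @export
dominance_prune <- function(totals) {
  totals <- as.data.frame(totals)
  stopifnot(all(c("strategy", "quitters", "cost_inr") %in% names(totals)))
  if (nrow(totals) == 0L) stop("need at least one strategy", call. = FALSE)
  df <- data.frame(strategy = totals$strategy, effect = totals$quitters,
                   cost = totals$cost_inr, order = seq_len(nrow(totals)),
                   stringsAsFactors = FALSE)

  strictly_dominated <- function(i, df) {
    any(df$cost <= df$cost[i] & df$effect >= df$effect[i] &
          (df$cost < df$cost[i] | df$effect > df$effect[i]))
  }
  # exact duplicates on both axes: keep the first by input order
  dup <- duplicated(df[, c("effect", "cost")])
  elim <- df[dup, , drop = FALSE]
  keep <- df[!dup, , drop = FALSE]
  sd <- vapply(seq_len(nrow(keep)), strictly_dominated, logical(1), df = keep)
  elim <- rbind(elim, keep[sd, , drop = FALSE])
  elim$tag <- rep("strictly-dominated", nrow(elim))
  keep <- keep[!sd, , drop = FALSE]

  # sort surviving strategies by effect (cost as tie-break, then input order)
  keep <- keep[order(keep$effect, keep$cost, keep$order), , drop = FALSE]

  # extended dominance: enforce strictly increasing sequential ICERs
  ext <- keep[0, , drop = FALSE]
  repeat {
    if (nrow(keep) < 3L) break
    icers <- diff(keep$cost) / diff(keep$effect)
    bad <- which(diff(icers) <= 0)
    if (length(bad) == 0L) break
    drop_i <- bad[1] + 1L  # the middle strategy of the first offending pair
    ext <- rbind(ext, keep[drop_i, , drop = FALSE])
    keep <- keep[-drop_i, , drop = FALSE]
  }
  if (nrow(ext) > 0L) {
    ext$tag <- "extended-dominated"
    elim <- rbind(elim, ext)
  }

  seq_icer <- if (nrow(keep) > 1L) {
    c(NA_real_, diff(keep$cost) / diff(keep$effect))
  } else {
    rep(NA_real_, nrow(keep))
  }
  structure(
    list(
      retained = tibble::tibble(strategy = keep$strategy,
                                quitters = keep$effect,
                                cost_inr = keep$cost,
                                icer_sequential = seq_icer),
      eliminated = tibble::tibble(strategy = elim$strategy,
                                  quitters = elim$effect,
                                  cost_inr = elim$cost,
                                  tag = elim$tag)
    ),
    class = "cea_frontier"
  )
}

#' @export
print.cea_frontier <- function(x, ...) {
  cat("Cost-effectiveness frontier\n")
  cat("Retained strategies (increasing effectiveness):\n")
  print(x$retained)
  if (nrow(x$eliminated) > 0L) {
    cat("Eliminated strategies:\n")
    print(x$eliminated)
  }
  invisible(x)
}
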