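#' Format rupee amounts with Indian digit grouping
#'
#' Display-only helper: groups the last three digits, then pairs
#' (e.g. `4287713` becomes `"42,87,713"`), the convention used in Indian
#' cost tables. Stored and computed values always use plain decimals.
#'
#' @param x numeric vector of amounts.
#' @param digits decimal places to keep (default 0, i.e. rounded rupees).
#' @return character vector.
#' @examples
#' format_inr(4287713)
#' @export
format_inr <- function(x, digits = 0) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    neg <- v < 0
    v <- round(abs(v), digits)
    whole <- formatC(floor(v), format = "f", digits = 0)
    frac <- if (digits > 0) {
      sprintf(paste0("%.", digits, "f"), v - floor(v))
    } else ""
    frac <- sub("^0", "", frac)
    ch <- strsplit(whole, "")[[1]]
    n <- length(ch)
    grouped <- if (n <= 3) whole else {
      head_part <- ch[seq_len(n - 3)]
      tail_part <- paste(ch[(n - 2):n], collapse = "")
      m <- length(head_part)
      pairs <- rev(split(rev(head_part),
                         ceiling(seq_along(rev(head_part)) / 2)))
      paste(c(vapply(pairs, function(p) paste(rev(p), collapse = ""),
                     character(1)), tail_part), collapse = ",")
    }
    paste0(if (neg) "-" else "", grouped, frac)
  }, character(1))
}

# md5 of the canonical YAML serialization of a config
config_digest <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write analysis results to CSV files with a run manifest
#'
#' Serializes the base-case evaluation and the incremental tables (before
#' and after dominance pruning), plus any sensitivity outputs supplied, as
#' RFC-4180 CSV files with fixed names and headers. INR amounts are stored
#' at full precision with an additional display-rounded column. A manifest
#' (JSON) records the configuration digest, seed, package version,
#' timestamp and every file written.
#'
#' @param evaluations output of [evaluate_strategies()] (must be
#'   non-empty).
#' @param incremental_before output of [incremental_table()].
#' @param frontier output of [dominance_prune()].
#' @param out_dir output directory (created if needed).
#' @param config the `cea_config` used, for the manifest digest.
#' @param tornado optional [owsa()] table.
#' @param psa optional `cea_psa` object; its draw log is written.
#' @param ceac_table optional [ceac()] table.
#' @param seed optional seed to record in the manifest.
#' @return the manifest, invisibly (a list; also written to
#'   `manifest.json`).
#' @export
write_results <- function(evaluations, incremental_before, frontier,
                          out_dir, config = NULL, tornado = NULL,
                          psa = NULL, ceac_table = NULL, seed = NULL) {
  if (is.null(evaluations) || nrow(evaluations) == 0L) {
    stop("no evaluations to write", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    ok <- tryCatch({
      write.csv(df, path, row.names = FALSE)
      TRUE
    }, error = function(e) {
      stop(sprintf("failed to write %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
    files <<- c(files, name)
    path
  }

  base_case <- evaluations
  base_case$cost_inr_display <- format_inr(base_case$cost_inr)
  emit(base_case, "base_case.csv")

  before <- incremental_before
  before$icer_display <- ifelse(is.na(before$icer), "",
                                format_inr(round(before$icer)))
  emit(before, "incremental_before.csv")

  after <- frontier$retained
  after$icer_display <- ifelse(is.na(after$icer_sequential), "",
                               format_inr(round(after$icer_sequential)))
  emit(after, "incremental_after.csv")
  emit(frontier$eliminated, "eliminated.csv")

  if (!is.null(tornado)) emit(tornado, "tornado.csv")
  if (!is.null(psa)) emit(psa$draws, "psa_draws.csv")
  if (!is.null(ceac_table)) emit(ceac_table, "ceac.csv")

  manifest <- list(
    package = "ceatree",
    version = as.character(packageVersion("ceatree")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (is.null(seed)) NA else as.integer(seed),
    config_digest = if (is.null(config)) NA_character_
                    else config_digest(config),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
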