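# End-to-end study pipeline: ingest or synthesise data, filter, describe,
# fit the rotated models for every wellbeing domain, and build the
# reallocation grid, with reproducible file outputs.

read_checked <- function(path, required) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss)) {
    stop(basename(path), " is missing column(s): ", paste(miss, collapse = ", "))
  }
  d
}

#' Read study input tables
#'
#' Thin, schema-checked readers for the three delimited-text inputs: per-day
#' movement summaries, wide questionnaire items, and demographics.  All are
#' UTF-8 CSV with a header row.
#'
#' @param path File path.
#' @return Data frame.
#' @name readers
NULL

#' @rdname readers
#' @export
read_day_summaries <- function(path) {
  read_checked(path, c("participant_id", "day", "sleep_min", "sed_min",
                       "lpa_min", "mvpa_min", "wear_hours"))
}

#' @rdname readers
#' @export
read_epoch_items <- function(path) {
  read_checked(path, c("participant_id", sprintf("item_%02d", 1:20)))
}

#' @rdname readers
#' @export
read_demographics <- function(path) {
  read_checked(path, c("participant_id", "school", "age", "gender"))
}

#' Descriptive summary of an analysis sample
#'
#' Arithmetic mean and SD of raw minutes per behaviour, the closed
#' geometric-mean composition with percentage shares at one decimal place,
#' wellbeing domain means and SDs, and demographic counts.
#'
#' @param data Analysis data frame (part columns in minutes, wellbeing
#'   domains, `age`, `gender`).
#' @param parts Part columns (default [mb_parts()]).
#' @return List of class `coda_descriptives`.
#' @export
describe_cohort <- function(data, parts = mb_parts()) {
  m <- as.matrix(data[, parts, drop = FALSE])
  gm <- gmean_composition(m)
  shares <- round(100 * gm / sum(gm), 1)
  domains <- intersect(epoch_domains(), names(data))
  wellbeing <- if (length(domains)) {
    data.frame(domain = domains,
               mean = vapply(domains, function(d) mean(data[[d]]), 0),
               sd = vapply(domains, function(d) stats::sd(data[[d]]), 0),
               row.names = NULL)
  } else NULL
  structure(list(
    n = nrow(data),
    arithmetic = data.frame(part = parts, mean = colMeans(m),
                            sd = apply(m, 2, stats::sd), row.names = NULL),
    geometric = gm, shares_pct = shares,
    wellbeing = wellbeing,
    age_mean = if ("age" %in% names(data)) mean(data$age) else NA_real_,
    age_sd = if ("age" %in% names(data)) stats::sd(data$age) else NA_real_,
    gender = if ("gender" %in% names(data)) table(data$gender) else NULL
  ), class = "coda_descriptives")
}

#' @export
print.coda_descriptives <- function(x, ...) {
  cat("Analysis sample: n =", x$n, "\n")
  if (!is.na(x$age_mean)) {
    cat(sprintf("Age: %.1f (SD %.1f)\n", x$age_mean, x$age_sd))
  }
  cat("Arithmetic mean minutes/day (SD):\n")
  for (i in seq_len(nrow(x$arithmetic))) {
    cat(sprintf("  %-6s %6.1f (%.1f)\n", mb_label(x$arithmetic$part[i]),
                x$arithmetic$mean[i], x$arithmetic$sd[i]))
  }
  cat("Geometric mean minutes/day (% of 24 h):\n")
  for (p in names(x$geometric)) {
    cat(sprintf("  %-6s %6.1f (%.1f%%)\n", mb_label(p),
                round(x$geometric[[p]], 1), x$shares_pct[[p]]))
  }
  if (!is.null(x$wellbeing)) {
    cat("Wellbeing domains, mean (SD):\n")
    for (i in seq_len(nrow(x$wellbeing))) {
      cat(sprintf("  %-13s %.2f (%.2f)\n", x$wellbeing$domain[i],
                  x$wellbeing$mean[i], x$wellbeing$sd[i]))
    }
  }
  invisible(x)
}

#' Run the full study pipeline
#'
#' Executes every analysis stage on an analysis-ready data frame (or on a
#' freshly generated synthetic cohort when `data` is `NULL`): descriptive
#' statistics, the variation matrix, the four rotated compositional
#' regressions for each wellbeing domain, residual diagnostics, and the
#' pairwise time-reallocation grid around the sample geometric mean.
#' Given the same inputs (or the same generator config), the report is
#' identical across runs.
#'
#' @param data Analysis data frame (one row per included participant), or
#'   `NULL` to generate one from `config`.
#' @param config A [cohort_config()] used when `data` is `NULL`.
#' @param delta Reallocation amount in minutes (default 30).
#' @param outcomes Wellbeing domains to model (default all five present).
#' @param out_dir Optional directory; when given, the regression table,
#'   reallocation grid and a JSON report are written there.
#' @param ... Passed to [fit_composition_model()] (e.g. `cluster`,
#'   `gender_levels`).
#' @return Object of class `study_report`: `descriptives`,
#'   `variation`, `regressions` (per-outcome `coda_rotations`),
#'   `regression_table`, `diagnostics`, `reallocation` grid, `base`
#'   composition, and `n`.
#' @export
run_study <- function(data = NULL, config = cohort_config(), delta = 30,
                      outcomes = NULL, out_dir = NULL, ...) {
  cohort <- NULL
  if (is.null(data)) {
    cohort <- generate_cohort(config)
    data <- cohort$data
  }
  parts <- mb_parts()
  if (is.null(outcomes)) outcomes <- intersect(epoch_domains(), names(data))
  if (!length(outcomes)) stop("no wellbeing outcome columns found")

  desc <- describe_cohort(data, parts)
  vm <- variation_matrix(data[, parts])
  regressions <- lapply(stats::setNames(outcomes, outcomes), function(o) {
    fit_rotations(data, o, parts = parts, ...)
  })
  reg_table <- do.call(rbind, c(lapply(regressions, function(r) {
    cbind(r$table, r2 = r$r2, model_p = r$model_p)
  }), make.row.names = FALSE))

  diagnostics <- lapply(regressions, function(r) {
    model_diagnostics(r$models[[1]])
  })

  # reallocations are predicted around the geometric-mean composition of
  # the sample actually used in the models
  first <- regressions[[1]]$models[[1]]
  base <- gmean_composition(data[, parts])
  grid <- reallocation_grid(lapply(regressions, function(r) r$models[[1]]),
                            base = base, delta = delta)

  report <- structure(list(
    n = first$n_used, descriptives = desc, variation = vm,
    regressions = regressions, regression_table = reg_table,
    diagnostics = diagnostics, reallocation = grid, base = base,
    delta = delta, cohort = cohort
  ), class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(reg_table, file.path(out_dir, "regressions.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(grid),
                     file.path(out_dir, "reallocation.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(vm)),
                     file.path(out_dir, "variation_matrix.csv"))
    jsonlite::write_json(list(
      n = report$n,
      geometric_mean = as.list(round(desc$geometric, 4)),
      shares_pct = as.list(desc$shares_pct),
      regression_table = reg_table,
      reallocation = as.data.frame(grid)
    ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("=== 24-h movement behaviour composition study ===\n\n")
  print(x$descriptives)
  cat("\n")
  print(x$variation)
  cat("\nRegression summary (beta = part-vs-rest coefficient):\n")
  tab <- x$regression_table
  tab[, c("beta", "se", "p", "r2", "model_p")] <-
    round(tab[, c("beta", "se", "p", "r2", "model_p")], 3)
  print(tab[, c("outcome", "label", "beta", "se", "p", "r2", "model_p")],
        row.names = FALSE)
  cat("\nReallocation grid (", x$delta, " min, around the sample geometric mean):\n",
      sep = "")
  print(x$reallocation)
  invisible(x)
}

#' Build an analysis sample from raw study tables
#'
#' The ingestion half of the pipeline: filters valid days, averages each
#' included participant's days into a closed composition, validates and
#' scores the questionnaire, joins demographics, and accounts for every
#' exclusion in an [inclusion_flow()].
#'
#' @param days Per-day movement summaries ([read_day_summaries()] layout).
#' @param items Questionnaire item responses ([read_epoch_items()] layout).
#' @param demographics Demographic table ([read_demographics()] layout).
#' @param min_hours,min_days Valid-day rules (defaults 16 h, 3 days).
#' @param mapping Item-to-domain mapping ([default_epoch_mapping()]).
#' @return List: `data` (analysis-ready rows), `flow` (inclusion flow from
#'   the roster through both exclusion steps), `participants` (per-person
#'   validity detail).
#' @export
build_analysis_sample <- function(days, items, demographics,
                                  min_hours = 16, min_days = 3,
                                  mapping = default_epoch_mapping()) {
  fv <- filter_valid(days, min_hours = min_hours, min_days = min_days)
  included_ids <- fv$participants$participant_id[fv$participants$included]

  comps <- do.call(rbind, lapply(included_ids, function(id) {
    pd <- fv$valid_days[fv$valid_days$participant_id == id, , drop = FALSE]
    comp <- participant_composition(pd)
    data.frame(participant_id = id, as.list(comp), stringsAsFactors = FALSE)
  }))

  ve <- validate_epoch(items[items$participant_id %in% included_ids, ,
                             drop = FALSE], mapping)
  scores <- score_epoch(ve$valid, mapping)

  data <- merge(merge(comps, scores, by = "participant_id"),
                demographics, by = "participant_id")
  enrolled <- length(unique(demographics$participant_id))
  flow <- inclusion_flow(enrolled, c(
    insufficient_accelerometer = enrolled - length(included_ids),
    invalid_wellbeing = ve$n_excluded
  ))
  list(data = data, flow = flow, participants = fv$participants)
}
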