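# Accelerometer-side processing: ENMO intensity classification, day
# summaries, valid-day filtering and the participant inclusion flow.

# ENMO cut-points (milli-g) for adolescents; left-closed upper intervals.
# Upper SED bound 35.6, LPA/MPA bound 201.4, MPA/VPA bound 707.0.
.enmo_cuts <- c(sed_lpa = 35.6, lpa_mpa = 201.4, mpa_vpa = 707.0)

#' Classify epoch-level ENMO into intensity classes
#'
#' Applies adolescent ENMO (Euclidean Norm Minus One) cut-points:
#' sedentary below 35.6 mg, light activity in \[35.6, 201.4), moderate in
#' \[201.4, 707.0), vigorous at or above 707.0 mg.  Intervals are
#' left-closed at the upper boundary, so a value exactly at a cut-point
#' falls in the higher class.  (Published cut-point tables sometimes print
#' the vigorous boundary as 707.7 mg; 707.0 is used here, treating the
#' other reading as a typographical variant.)
#'
#' @param enmo Numeric vector of ENMO values in milli-g (non-negative).
#' @return Ordered factor with levels `SED < LPA < MPA < VPA`.
#' @examples
#' classify_epoch(c(30, 100, 300, 800))
#' @export
classify_epoch <- function(enmo) {
  if (any(!is.finite(enmo) | enmo < 0)) {
    stop("ENMO values must be finite and non-negative")
  }
  cut(enmo, breaks = c(-Inf, .enmo_cuts, Inf),
      labels = c("SED", "LPA", "MPA", "VPA"),
      right = FALSE, ordered_result = TRUE)
}

#' Summarise one day of epoch-level data
#'
#' Converts epoch-level ENMO values into minutes per intensity class for one
#' participant-day.  MVPA is the sum of moderate and vigorous minutes.  Wear
#' time is the span covered by the supplied epochs; a day with no epochs is
#' flagged as non-wear.
#'
#' @param enmo Numeric vector of ENMO values (milli-g), one per worn epoch.
#' @param epoch_length Epoch duration in seconds (default 5, a common raw
#'   accelerometry aggregation).
#' @param sleep_minutes Sleep minutes for the day, supplied by the upstream
#'   sleep-detection step (default 0).
#' @param epoch_index Optional integer index per epoch; duplicates are an
#'   error (they would double-count time).
#' @param participant_id,day Identifiers carried into the output.
#' @return One-row data frame: minutes in SED/LPA/MPA/VPA, `mvpa_min`,
#'   `sleep_min`, `wear_hours`, and a `non_wear` flag.
#' @export
summarise_day <- function(enmo, epoch_length = 5, sleep_minutes = 0,
                          epoch_index = NULL,
                          participant_id = NA_character_, day = NA_integer_) {
  stopifnot(epoch_length > 0, sleep_minutes >= 0)
  if (!is.null(epoch_index) && anyDuplicated(epoch_index)) {
    stop("duplicated epoch indices: time would be double-counted")
  }
  cls <- if (length(enmo)) classify_epoch(enmo) else
    factor(character(), levels = c("SED", "LPA", "MPA", "VPA"))
  mins <- as.numeric(table(cls)) * epoch_length / 60
  names(mins) <- levels(cls)
  data.frame(
    participant_id = participant_id, day = day,
    sed_min = mins[["SED"]], lpa_min = mins[["LPA"]],
    mpa_min = mins[["MPA"]], vpa_min = mins[["VPA"]],
    mvpa_min = mins[["MPA"]] + mins[["VPA"]],
    sleep_min = sleep_minutes,
    wear_hours = length(enmo) * epoch_length / 3600,
    non_wear = length(enmo) == 0,
    stringsAsFactors = FALSE
  )
}

#' Filter valid days and decide participant inclusion
#'
#' A day is valid when it has at least `min_hours` of wear and more than
#' 0 minutes of sleep; a participant is included when they have at least
#' `min_days` valid days.  Excluded participants carry the reason
#' `fewer_than_min_valid_days`, plus a `wear_limited` flag marking those who
#' had enough sleep-valid days but lost days to the wear-hours rule — the
#' two exclusion patterns reported separately in study flow charts.
#'
#' @param days Data frame with one row per participant-day, containing at
#'   least `participant_id`, `wear_hours` and `sleep_min`.
#' @param min_hours Minimum wear hours per valid day (default 16).
#' @param min_days Minimum number of valid days for inclusion (default 3).
#' @return List with `valid_days` (the rows of `days` that are valid and
#'   belong to included participants) and `participants` (one row per
#'   participant: `n_days`, `n_valid`, `included`, `reason`, `wear_limited`).
#' @export
filter_valid <- function(days, min_hours = 16, min_days = 3) {
  need <- c("participant_id", "wear_hours", "sleep_min")
  miss <- setdiff(need, names(days))
  if (length(miss)) stop("days is missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(days)) {
    return(list(valid_days = days,
                participants = data.frame(participant_id = character(),
                                          n_days = integer(), n_valid = integer(),
                                          included = logical(), reason = character(),
                                          wear_limited = logical())))
  }
  valid <- days$wear_hours >= min_hours & days$sleep_min > 0
  sleep_ok <- days$sleep_min > 0
  ids <- unique(days$participant_id)
  n_days <- tapply(rep(1L, nrow(days)), days$participant_id, sum)[ids]
  n_valid <- tapply(as.integer(valid), days$participant_id, sum)[ids]
  n_sleep_ok <- tapply(as.integer(sleep_ok), days$participant_id, sum)[ids]
  included <- n_valid >= min_days
  participants <- data.frame(
    participant_id = ids,
    n_days = as.integer(n_days),
    n_valid = as.integer(n_valid),
    included = unname(included),
    reason = ifelse(included, NA_character_, "fewer_than_min_valid_days"),
    wear_limited = !included & n_sleep_ok >= min_days,
    row.names = NULL, stringsAsFactors = FALSE
  )
  keep <- valid & days$participant_id %in% ids[included]
  list(valid_days = days[keep, , drop = FALSE], participants = participants)
}

#' Average a participant's valid days into a daily composition
#'
#' Takes the arithmetic mean of sleep, SED, LPA and MVPA minutes across a
#' participant's valid days, then closes the result to 1440 minutes.
#' Averaging raw minutes first and closing second matches how descriptive
#' tables report arithmetic means in raw minutes alongside a closed
#' geometric-mean composition.
#'
#' @param valid_days Data frame of this participant's valid days with
#'   columns `sleep_min`, `sed_min`, `lpa_min`, `mvpa_min`.
#' @param total Closure constant (default 1440 minutes).
#' @return Named composition vector (sleep, sed, lpa, mvpa) summing to
#'   `total`.
#' @export
participant_composition <- function(valid_days, total = 1440) {
  cols <- c(sleep = "sleep_min", sed = "sed_min", lpa = "lpa_min",
            mvpa = "mvpa_min")
  miss <- setdiff(unname(cols), names(valid_days))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(valid_days)) stop("no valid days supplied")
  m <- colMeans(valid_days[, unname(cols), drop = FALSE])
  names(m) <- names(cols)
  if (any(m <= 0)) {
    stop("zero minutes in part(s) ", paste(names(m)[m <= 0], collapse = ", "),
         " after averaging; see replace_zeros() for an explicit pre-step")
  }
  close_composition(m, total = total)
}

#' Participant inclusion flow
#'
#' Reconciles an enrolment count against sequential exclusion counts and
#' reports the final analytic sample with percentages of the enrolled total
#' (1 decimal place, flow-chart style).
#'
#' @param enrolled Number of participants enrolled.
#' @param exclusions Named integer vector of exclusion counts applied in
#'   order, e.g. `c(device = 5, insufficient_accelerometer = 60,
#'   invalid_wellbeing = 4)`.
#' @return Object of class `inclusion_flow`: enrolled, per-step counts and
#'   percentages, `final`, and `retention_pct`.
#' @examples
#' inclusion_flow(193, c(device = 5, insufficient_accelerometer = 60,
#'                       invalid_wellbeing = 4))
#' @export
inclusion_flow <- function(enrolled, exclusions) {
  if (length(enrolled) != 1 || enrolled < 0 || enrolled != round(enrolled)) {
    stop("enrolled must be a single non-negative integer")
  }
  if (any(exclusions < 0)) stop("exclusion counts must be non-negative")
  if (sum(exclusions) > enrolled) stop("exclusions exceed enrolment")
  final <- enrolled - sum(exclusions)
  structure(list(
    enrolled = as.integer(enrolled),
    exclusions = as.integer(exclusions) |> stats::setNames(names(exclusions)),
    exclusion_pct = round(100 * exclusions / enrolled, 1),
    final = as.integer(final),
    retention_pct = round(100 * final / enrolled, 1)
  ), class = "inclusion_flow")
}

#' @export
print.inclusion_flow <- function(x, ...) {
  cat("Enrolled:", x$enrolled, "\n")
  for (nm in names(x$exclusions)) {
    cat(sprintf("  excluded %-28s %4d (%.1f%%)\n", nm, x$exclusions[[nm]],
                x$exclusion_pct[[nm]]))
  }
  cat(sprintf("Final analytic sample: %d (%.1f%% retention)\n",
              x$final, x$retention_pct))
  invisible(x)
}
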