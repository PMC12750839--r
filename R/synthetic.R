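# Synthetic cohort generator: logistic-normal compositions on the simplex,
# school-clustered wellbeing outcomes with known ground truth, and item-level
# questionnaire responses, so the full pipeline is testable without data.

#' Default target variation matrix for the generator
#'
#' Pairwise log-ratio variances used to calibrate the generator's ILR
#' covariance.  The sleep-SED, sleep-LPA and SED-LPA entries (0.054, 0.063,
#' 0.088) follow the ordering reported for adolescent 24-hour compositions
#' (sleep and sedentary time most co-dependent); the MVPA pairs (0.32,
#' 0.36, 0.40) are set largest, making MVPA the most compositionally
#' distinct behaviour.
#'
#' @return 4 x 4 symmetric matrix over [mb_parts()].
#' @export
default_target_variation <- function() {
  p <- mb_parts()
  Tm <- matrix(0, 4, 4, dimnames = list(p, p))
  Tm["sleep", "sed"] <- Tm["sed", "sleep"] <- 0.054
  Tm["sleep", "lpa"] <- Tm["lpa", "sleep"] <- 0.063
  Tm["sed", "lpa"] <- Tm["lpa", "sed"] <- 0.088
  Tm["sleep", "mvpa"] <- Tm["mvpa", "sleep"] <- 0.32
  Tm["sed", "mvpa"] <- Tm["mvpa", "sed"] <- 0.36
  Tm["lpa", "mvpa"] <- Tm["mvpa", "lpa"] <- 0.40
  Tm
}

#' ILR covariance implied by a target variation matrix
#'
#' Converts a D x D variation matrix T into the covariance of the ILR
#' coordinates of `basis`, via the centred log-ratio covariance
#' `Sigma_clr = -G T G / 2` with `G = I - J/D`, then `t(V) Sigma_clr V`.
#' A logistic-normal sample with this ILR covariance reproduces `T` exactly
#' in expectation.
#'
#' @param variation Symmetric non-negative D x D matrix with zero diagonal,
#'   rows/columns named by part.
#' @param basis An [ilr_basis] over the same parts.
#' @return (D-1) x (D-1) covariance matrix.
#' @export
ilr_covariance_from_variation <- function(variation, basis = pivot_basis()) {
  stopifnot(inherits(basis, "ilr_basis"))
  Tm <- variation[basis$order, basis$order]
  D <- basis$D
  G <- diag(D) - matrix(1 / D, D, D)
  S <- t(basis$V) %*% (-0.5 * G %*% Tm %*% G) %*% basis$V
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    stop("target variation matrix does not yield a positive-definite ",
         "ILR covariance")
  }
  S
}

#' Generator configuration for a synthetic study cohort
#'
#' Bundles the study conditions the generator emulates: cohort size and
#' school clustering, the target geometric-mean composition, between-person
#' compositional variability (via a target variation matrix), true outcome
#' effects, covariate effects, school and residual noise, and the seed.
#'
#' True compositional effects are specified per outcome as a zero-sum
#' "part effect" vector `a` on the centred log-ratio scale: the outcome's
#' compositional contribution is `sum(a * clr(x))`, so the induced true
#' coefficient vector on the ILR coordinates of any basis is
#' `t(V) %*% a` (see [true_ilr_beta()]).  The default gives happiness a
#' positive LPA effect and a negative SED effect, and leaves the other four
#' domains null.
#'
#' @param n Number of participants (default 124).
#' @param n_schools Number of school clusters (default 7).
#' @param target_gm Geometric-mean composition in minutes, named by part
#'   (default sleep 473.0, SED 680.9, LPA 250.7, MVPA 35.3).
#' @param target_variation Target variation matrix
#'   ([default_target_variation()]); ignored when `ilr_covariance` is given.
#' @param ilr_covariance Optional 3 x 3 covariance of canonical-basis ILR
#'   coordinates; by default derived from `target_variation`.
#' @param effects Named list, one zero-sum length-4 numeric vector per
#'   wellbeing domain (clr-scale part effects).
#' @param intercepts Named vector of domain means at the reference covariate
#'   profile (defaults 3.39/3.62/3.61/4.35/3.92).
#' @param beta_age,beta_gender Covariate effects (per year of age, centred
#'   at 14.8; female vs male, centred at 0.5), shared across domains.
#' @param school_sd SD of additive school random intercepts on outcomes.
#' @param noise_sd Residual SD of outcomes (scale units).
#' @param item_sd SD of item-level noise around the domain score when
#'   simulating questionnaire items.
#' @param prob_gender Sampling probabilities for male/female/other.
#' @param age_range Age limits in years (default 13-17, mean 14.8, SD 1).
#' @param seed Integer seed; the generator uses R's default Mersenne-Twister
#'   RNG, so a config regenerates its dataset bit-identically.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n = 124, n_schools = 7,
                          target_gm = c(sleep = 473.0, sed = 680.9,
                                        lpa = 250.7, mvpa = 35.3),
                          target_variation = default_target_variation(),
                          ilr_covariance = NULL,
                          effects = NULL,
                          intercepts = c(engagement = 3.39, perseverance = 3.62,
                                         optimism = 3.61, connectedness = 4.35,
                                         happiness = 3.92),
                          beta_age = -0.05, beta_gender = -0.10,
                          school_sd = 0.15, noise_sd = 0.70, item_sd = 0.25,
                          prob_gender = c(male = 0.492, female = 0.460,
                                          other = 0.048),
                          age_range = c(13, 17), seed = 20240124) {
  if (n_schools < 2) stop("need at least 2 schools")
  if (any(target_gm <= 0)) stop("target_gm must be strictly positive")
  if (is.null(effects)) {
    effects <- lapply(stats::setNames(epoch_domains(), epoch_domains()),
                      function(d) stats::setNames(rep(0, 4), mb_parts()))
    effects$happiness <- c(sleep = 0, sed = -0.6, lpa = 0.8, mvpa = -0.2)
  }
  for (d in names(effects)) {
    a <- effects[[d]]
    if (length(a) != 4 || abs(sum(a)) > 1e-8) {
      stop("effects$", d, " must be a zero-sum length-4 vector")
    }
  }
  basis <- pivot_basis()
  if (is.null(ilr_covariance)) {
    ilr_covariance <- ilr_covariance_from_variation(target_variation, basis)
  }
  if (!isTRUE(all.equal(ilr_covariance, t(ilr_covariance))) ||
      min(eigen(ilr_covariance, symmetric = TRUE,
                only.values = TRUE)$values) < 0) {
    stop("ilr_covariance must be symmetric positive semi-definite")
  }
  structure(list(
    n = n, n_schools = n_schools,
    target_gm = close_composition(target_gm),
    ilr_covariance = ilr_covariance,
    effects = effects, intercepts = intercepts,
    beta_age = beta_age, beta_gender = beta_gender,
    school_sd = school_sd, noise_sd = noise_sd, item_sd = item_sd,
    prob_gender = prob_gender, age_range = age_range,
    age_mean = 14.8, age_sd = 1.0,
    seed = as.integer(seed), rng = "Mersenne-Twister"
  ), class = "cohort_config")
}

#' True ILR coefficient vector implied by a config's part effects
#'
#' @param config A [cohort_config()].
#' @param outcome Wellbeing domain name.
#' @param basis Basis in which the coefficients are expressed.
#' @return Length D-1 vector: the coefficients an ILR regression in `basis`
#'   should recover.
#' @export
true_ilr_beta <- function(config, outcome, basis = pivot_basis()) {
  a <- config$effects[[outcome]]
  if (is.null(a)) stop("no effects defined for outcome '", outcome, "'")
  drop(t(basis$V) %*% a[basis$order])
}

#' Draw synthetic 24-hour compositions
#'
#' ILR coordinates are drawn from a multivariate normal centred at the ILR
#' image of the target geometric mean with the config's ILR covariance
#' (a logistic-normal model on the simplex), then mapped back and closed to
#' 1440 minutes.  The closed sample geometric mean converges to
#' `target_gm` as n grows.
#'
#' @param config A [cohort_config()].
#' @param seed Seed to set before drawing; `NULL` leaves the RNG state
#'   untouched (used internally by [generate_cohort()]).
#' @return n x 4 matrix of strictly positive compositions closed to 1440.
#' @export
generate_compositions <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  basis <- pivot_basis()
  mu <- ilr_pivot(config$target_gm, basis)
  z <- MASS::mvrnorm(config$n, mu = mu, Sigma = config$ilr_covariance)
  if (config$n == 1) z <- matrix(z, nrow = 1)
  ilr_inverse(z, basis, total = 1440)
}

generate_demographics <- function(config) {
  n <- config$n
  school <- factor(sprintf("school_%02d", rep_len(seq_len(config$n_schools), n)))
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                   config$age_range[1]), config$age_range[2])
  gender <- sample(names(config$prob_gender), n, replace = TRUE,
                   prob = config$prob_gender)
  data.frame(participant_id = sprintf("p%04d", seq_len(n)),
             school = school, age = round(age, 1), gender = gender,
             stringsAsFactors = FALSE)
}

#' Simulate wellbeing outcomes from compositions and demographics
#'
#' Each domain score is linear in the centred log-ratio of the composition
#' (equivalently, in ILR coordinates), age and gender, plus an additive
#' school random intercept and Gaussian residual noise:
#' `y = intercept + sum(a * (clr(x) - clr(gm))) + beta_age * (age - 14.8)
#'  + beta_gender * female + school_effect + eps`.
#' Continuous scores are returned untruncated — bounding into \[1, 5\]
#' happens only when item responses are simulated.
#'
#' @param compositions n x 4 matrix from [generate_compositions()].
#' @param demographics Data frame with `school`, `age`, `gender`.
#' @param config A [cohort_config()].
#' @inheritParams generate_compositions
#' @return List: `outcomes` (data frame, one column per domain) and `truth`
#'   (school effects, noiseless outcomes, per-basis true ILR betas).
#' @export
generate_outcomes <- function(compositions, demographics, config,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(compositions)
  if (nrow(demographics) != n) stop("compositions and demographics disagree on n")
  clr_centre <- log(config$target_gm) - mean(log(config$target_gm))
  lx <- log(compositions)
  clr <- lx - rowMeans(lx)
  female <- as.numeric(demographics$gender == "female")
  school_eff <- stats::rnorm(config$n_schools, 0, config$school_sd)
  names(school_eff) <- levels(factor(demographics$school))
  se_i <- school_eff[as.character(demographics$school)]
  outcomes <- data.frame(row.names = seq_len(n))
  noiseless <- data.frame(row.names = seq_len(n))
  for (d in epoch_domains()) {
    a <- config$effects[[d]][colnames(compositions)]
    mu <- config$intercepts[[d]] +
      drop((clr - matrix(clr_centre, n, 4, byrow = TRUE)) %*% a) +
      config$beta_age * (demographics$age - config$age_mean) +
      config$beta_gender * (female - 0.5)
    noiseless[[d]] <- mu + se_i
    outcomes[[d]] <- noiseless[[d]] + stats::rnorm(n, 0, config$noise_sd)
  }
  truth <- list(
    effects = config$effects,
    ilr_beta = lapply(stats::setNames(epoch_domains(), epoch_domains()),
                      function(d) true_ilr_beta(config, d)),
    beta_age = config$beta_age, beta_gender = config$beta_gender,
    school_effects = school_eff,
    noiseless = noiseless
  )
  list(outcomes = outcomes, truth = truth)
}

#' Simulate item-level questionnaire responses from domain scores
#'
#' Each of a domain's four items is the domain score plus independent
#' Gaussian noise (`item_sd`), rounded and clamped into the 1..5 response
#' coding.  Re-scoring the items recovers the domain mean up to
#' discretisation error.
#'
#' @param scores Data frame with one column per wellbeing domain.
#' @param config A [cohort_config()] (supplies `item_sd`).
#' @param mapping Item-to-domain table ([default_epoch_mapping()]).
#' @inheritParams generate_compositions
#' @return Data frame with columns `item_01`..`item_20`.
#' @export
generate_item_responses <- function(scores, config,
                                    mapping = default_epoch_mapping(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_epoch_mapping(mapping)
  n <- nrow(scores)
  out <- data.frame(row.names = seq_len(n))
  for (k in seq_len(nrow(mapping))) {
    d <- mapping$domain[k]
    raw <- scores[[d]] + stats::rnorm(n, 0, config$item_sd)
    out[[mapping$item[k]]] <- pmin(5L, pmax(1L, as.integer(round(raw))))
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Orchestrates [generate_compositions()], demographics,
#' [generate_outcomes()] and [generate_item_responses()] under a single
#' seed.  Regenerating with the same config is bit-identical.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `data` (one row per
#'   participant: id, school, age, gender, the four behaviour columns in
#'   minutes, five continuous domain scores, and `item_01`..`item_20`),
#'   `truth`, and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 50, seed = 1))
#' head(coh$data[, c("sleep", "sed", "lpa", "mvpa", "happiness")])
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  comps <- generate_compositions(config, seed = NULL)
  demo <- generate_demographics(config)
  out <- generate_outcomes(comps, demo, config, seed = NULL)
  items <- generate_item_responses(out$outcomes, config, seed = NULL)
  data <- cbind(demo, as.data.frame(comps), out$outcomes, items)
  rownames(data) <- NULL
  structure(list(data = data, truth = out$truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: n =", nrow(x$data), "participants,",
      x$config$n_schools, "schools, seed", x$config$seed, "\n")
  invisible(x)
}

#' Expand a cohort into noisy per-day summaries
#'
#' Emulates the day-level table the processing stage ingests: each
#' participant contributes `n_days` days whose compositions are their own
#' composition perturbed by day-to-day logistic-normal noise, with wear
#' hours drawn around 21.5 h (SD 2.3) so some days fail the 16-h validity
#' rule.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_days Days per participant (default 7).
#' @param day_sd SD of day-level ILR noise (default 0.12).
#' @param seed Seed (defaults to the cohort seed + 1).
#' @return Data frame with one row per participant-day: `participant_id`,
#'   `day`, `sleep_min`, `sed_min`, `lpa_min`, `mvpa_min`, `wear_hours`.
#' @export
generate_day_summaries <- function(cohort, n_days = 7, day_sd = 0.12,
                                   seed = cohort$config$seed + 1L) {
  set.seed(seed)
  d <- cohort$data
  basis <- pivot_basis()
  rows <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    z <- ilr_pivot(unlist(d[i, mb_parts()]), basis)
    zd <- matrix(rep(z, each = n_days), n_days) +
      matrix(stats::rnorm(n_days * 3, 0, day_sd), n_days)
    comp <- ilr_inverse(zd, basis, total = 1440)
    rows[[i]] <- data.frame(
      participant_id = d$participant_id[i], day = seq_len(n_days),
      sleep_min = comp[, "sleep"], sed_min = comp[, "sed"],
      lpa_min = comp[, "lpa"], mvpa_min = comp[, "mvpa"],
      wear_hours = pmin(24, pmax(6, stats::rnorm(n_days, 21.5, 2.3))),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort to delimited text and JSON
#'
#' Emits the same formats the ingestion functions read: `days.csv` (per-day
#' summaries), `epoch_items.csv` (questionnaire items), `demographics.csv`,
#' plus `truth.json` and `config.json` recording the ground truth and the
#' exact generator settings.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- cohort$data
  files <- c(
    days = file.path(dir, "days.csv"),
    items = file.path(dir, "epoch_items.csv"),
    demo = file.path(dir, "demographics.csv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.json")
  )
  utils::write.csv(generate_day_summaries(cohort), files[["days"]],
                   row.names = FALSE)
  utils::write.csv(cbind(d["participant_id"],
                         d[grep("^item_", names(d))]),
                   files[["items"]], row.names = FALSE)
  utils::write.csv(d[c("participant_id", "school", "age", "gender")],
                   files[["demo"]], row.names = FALSE)
  jsonlite::write_json(cohort$truth, files[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  cfg <- cohort$config
  cfg$ilr_covariance <- unclass(cfg$ilr_covariance)
  jsonlite::write_json(unclass(cfg), files[["config"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(files)
}
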