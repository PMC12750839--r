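# Pairwise time-reallocation (isotemporal substitution) engine: predicted
# wellbeing differences, with cluster-robust CIs, for moving minutes between
# behaviours around a base composition.

#' Move minutes between two behaviours
#'
#' Subtracts `delta` minutes from the donor part and adds them to the
#' recipient, leaving the other parts and the 1440-minute total untouched.
#'
#' @param base Named composition vector (minutes, strictly positive).
#' @param from,to Donor and recipient part names.
#' @param delta Minutes to move (must be less than `base[from]`).
#' @return The reallocated composition.
#' @examples
#' reallocate(c(sleep = 473, sed = 681, lpa = 251, mvpa = 35),
#'            from = "sed", to = "lpa", delta = 30)
#' @export
reallocate <- function(base, from, to, delta) {
  base <- close_composition(base, total = sum(base))  # validates positivity
  if (!from %in% names(base) || !to %in% names(base)) {
    stop("unknown part(s): ", paste(setdiff(c(from, to), names(base)),
                                    collapse = ", "))
  }
  if (from == to) stop("donor and recipient must differ")
  if (delta < 0) stop("delta must be non-negative")
  if (delta >= base[[from]]) {
    stop("infeasible reallocation: delta = ", delta, " min >= ", from,
         " = ", round(base[[from]], 1), " min")
  }
  out <- base
  out[[from]] <- out[[from]] - delta
  out[[to]] <- out[[to]] + delta
  out
}

#' Predicted outcome difference for one reallocation
#'
#' Predicts the change in a wellbeing domain when `delta` minutes move from
#' one behaviour to another around a base composition, under a fitted
#' compositional model.  The covariates cancel, so the difference is the
#' inner product of the ILR coordinate change with the model's ILR
#' coefficients; its variance comes from the corresponding block of the
#' cluster-robust covariance, and the CI uses the model's t reference
#' (G - 1 df).  By ILR isometry the estimate does not depend on which pivot
#' rotation the model was fitted in.
#'
#' @param model A `coda_fit`.
#' @param base Base composition (minutes); conventionally the sample
#'   geometric mean.
#' @param from,to Donor and recipient parts.
#' @param delta Minutes to move (default 30).
#' @param conf Confidence level (default 0.95).
#' @return One-row data frame: `from`, `to`, `delta`, `outcome`,
#'   `estimate`, `se`, `lower`, `upper`, `significant` (CI excludes 0).
#' @export
predict_difference <- function(model, base, from, to, delta = 30,
                               conf = 0.95) {
  stopifnot(inherits(model, "coda_fit"))
  basis <- model$basis
  miss <- setdiff(basis$order, names(base))
  if (length(miss)) {
    stop("base composition is missing model part(s): ",
         paste(miss, collapse = ", "))
  }
  new <- reallocate(base, from, to, delta)
  dz <- ilr_pivot(new, basis) - ilr_pivot(base, basis)
  znames <- paste0("z", seq_len(basis$D - 1))
  bz <- model$coefficients$estimate[match(znames, model$coefficients$term)]
  est <- sum(dz * bz)
  v <- drop(t(dz) %*% model$vcov_cluster[znames, znames] %*% dz)
  se <- sqrt(v)
  tcrit <- stats::qt(1 - (1 - conf) / 2, model$df)
  lo <- est - tcrit * se
  hi <- est + tcrit * se
  data.frame(from = from, to = to, delta = delta, outcome = model$outcome,
             estimate = est, se = se, lower = lo, upper = hi,
             significant = lo > 0 | hi < 0,
             stringsAsFactors = FALSE)
}

#' Full reallocation grid
#'
#' Predicted differences for every ordered pair of behaviours (12 pairs for
#' four parts) and every supplied outcome model, at a common `delta`.
#' Per-minute columns (`estimate_per_min`, CI bounds divided by `delta`)
#' are emitted alongside the per-`delta` estimates, since published tables
#' appear in both scales.
#'
#' @param models A single `coda_fit` or a list of them (one per outcome).
#' @param base Base composition; default the geometric mean of the data the
#'   first model was fitted on is *not* recoverable from the fit, so `base`
#'   must be supplied (use [gmean_composition()] on the analysis sample).
#' @param delta Minutes to move (default 30).
#' @param conf Confidence level (default 0.95).
#' @return Data frame of class `realloc_grid`, one row per (from, to,
#'   outcome), with `significant` flagged where the CI excludes 0.
#' @export
reallocation_grid <- function(models, base, delta = 30, conf = 0.95) {
  if (inherits(models, "coda_fit")) models <- list(models)
  parts <- models[[1]]$basis$order
  pairs <- expand.grid(from = parts, to = parts, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  # donor-major order: all reallocations out of each behaviour together
  pairs <- pairs[order(match(pairs$from, parts), match(pairs$to, parts)), ]
  rows <- list()
  for (m in models) {
    for (k in seq_len(nrow(pairs))) {
      rows[[length(rows) + 1L]] <- predict_difference(
        m, base, pairs$from[k], pairs$to[k], delta = delta, conf = conf)
    }
  }
  out <- do.call(rbind, rows)
  out$estimate_per_min <- out$estimate / delta
  out$lower_per_min <- out$lower / delta
  out$upper_per_min <- out$upper / delta
  rownames(out) <- NULL
  class(out) <- c("realloc_grid", "data.frame")
  out
}

#' @export
print.realloc_grid <- function(x, digits = 3, ...) {
  cat("Time-reallocation grid: delta =", x$delta[1], "min,",
      length(unique(x$outcome)), "outcome(s),",
      length(unique(paste(x$from, x$to))), "ordered pairs\n")
  tab <- data.frame(
    from = mb_label(x$from), to = mb_label(x$to), outcome = x$outcome,
    beta = sprintf(paste0("%.", digits, "f"), x$estimate),
    ci = sprintf(paste0("(%.", digits, "f, %.", digits, "f)%s"),
                 x$lower, x$upper, ifelse(x$significant, "*", "")),
    stringsAsFactors = FALSE
  )
  print(tab, row.names = FALSE)
  invisible(x)
}
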