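# Compositional linear regression of wellbeing domains on ILR coordinates,
# with pivot rotation, covariate adjustment and school-cluster-robust
# inference.

#' Fit a compositional regression for one outcome and pivot
#'
#' Ordinary least squares of a wellbeing domain on the three ILR pivot
#' coordinates of the movement-behaviour composition, adjusted for age and
#' gender.  Inference uses a cluster-robust (sandwich) covariance by school
#' with the HC1 small-sample correction, referred to a t distribution with
#' G - 1 degrees of freedom (G = number of schools); naive OLS covariance is
#' also retained.  Participants whose gender is neither of the two modelled
#' levels are dropped before fitting, with the count recorded.
#'
#' @param data Data frame with the part columns (minutes), the outcome,
#'   `age`, `gender` and the cluster column.
#' @param outcome Name of the outcome column.
#' @param pivot Part whose "vs rest" coordinate should lead (default
#'   sleep, the canonical order).
#' @param parts Part columns (default [mb_parts()]).
#' @param covariates Adjustment columns (default age and gender).
#' @param cluster Cluster column (default `"school"`).
#' @param gender_levels The two modelled gender levels; the first is the
#'   reference.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Object of class `coda_fit`: coefficient table (estimate,
#'   cluster-robust SE, t, p), `vcov_cluster`, `vcov_ols`, `r2`, `model_p`
#'   (joint cluster-robust Wald test of all non-intercept terms), `df`
#'   (G - 1), `basis`, `n_used`, `n_dropped_gender`, and the underlying
#'   `lm` fit.
#' @export
fit_composition_model <- function(data, outcome, pivot = "sleep",
                                  parts = mb_parts(),
                                  covariates = c("age", "gender"),
                                  cluster = "school",
                                  gender_levels = c("male", "female"),
                                  alpha = 0.05) {
  need <- c(parts, outcome, covariates, cluster)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data is missing column(s): ", paste(miss, collapse = ", "))

  dd <- data
  n_dropped_gender <- 0L
  if ("gender" %in% covariates) {
    keep <- dd$gender %in% gender_levels
    n_dropped_gender <- sum(!keep)
    dd <- dd[keep, , drop = FALSE]
    dd$gender <- factor(dd$gender, levels = gender_levels)
    if (nlevels(droplevels(dd$gender)) < 2) {
      stop("gender has a single level after exclusions; cannot adjust for it")
    }
  }
  dd <- dd[stats::complete.cases(dd[, need, drop = FALSE]), , drop = FALSE]

  basis <- rotate_basis(parts, pivot)
  Z <- ilr_pivot(dd[, parts, drop = FALSE], basis)
  md <- cbind(as.data.frame(Z), dd[, c(outcome, covariates), drop = FALSE])
  p_model <- ncol(Z) + length(covariates) + 1L
  if (nrow(md) < p_model + 2L) stop("too few complete cases to fit the model")

  cl <- factor(dd[[cluster]])
  G <- nlevels(droplevels(cl))
  if (G < 2) stop("need at least 2 clusters for school-level adjustment")

  fml <- stats::reformulate(c(colnames(Z), covariates), response = outcome)
  fit <- stats::lm(fml, data = md)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }

  vc_cl <- sandwich::vcovCL(fit, cluster = cl, type = "HC1")
  vc_ols <- stats::vcov(fit)
  b <- stats::coef(fit)
  se <- sqrt(diag(vc_cl))
  df <- G - 1L
  tval <- b / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  coef_tab <- data.frame(term = names(b), estimate = unname(b),
                         se = unname(se), t = unname(tval), p = unname(pval),
                         row.names = NULL, stringsAsFactors = FALSE)

  # joint Wald test of every non-intercept term under the cluster-robust
  # covariance, F(q, G-1)
  idx <- which(names(b) != "(Intercept)")
  q <- length(idx)
  W <- drop(t(b[idx]) %*% solve(vc_cl[idx, idx]) %*% b[idx])
  model_p <- stats::pf(W / q, q, df, lower.tail = FALSE)

  structure(list(
    outcome = outcome, basis = basis, coefficients = coef_tab,
    vcov_cluster = vc_cl, vcov_ols = vc_ols,
    r2 = summary(fit)$r.squared, model_p = model_p,
    df = df, n_used = nrow(md), n_clusters = G,
    n_dropped_gender = n_dropped_gender, alpha = alpha,
    fitted = stats::fitted(fit), residuals = stats::residuals(fit),
    fit = fit
  ), class = "coda_fit")
}

#' @export
print.coda_fit <- function(x, digits = 3, ...) {
  cat("Compositional regression: ", x$outcome, " ~ ILR(",
      paste(x$basis$order, collapse = ", "), ") + covariates\n", sep = "")
  cat("n =", x$n_used, "in", x$n_clusters, "school clusters",
      if (x$n_dropped_gender)
        paste0("(", x$n_dropped_gender, " dropped on gender)"), "\n")
  tab <- x$coefficients
  tab[, -1] <- round(tab[, -1], digits)
  print(tab, row.names = FALSE)
  cat(sprintf("R^2 = %.*f, model p = %.*f (cluster-robust, df = %d)\n",
              digits, x$r2, digits, x$model_p, x$df))
  invisible(x)
}

row_label <- function(pivot, parts = mb_parts()) {
  rest <- setdiff(parts, pivot)
  paste0(mb_label(pivot), " vs. (", paste(mb_label(rest), collapse = " + "), ")")
}

#' Fit the four pivot rotations for one outcome
#'
#' Refits the same compositional model with each behaviour leading the
#' pivot order and collects, per behaviour, its first-coordinate ("part vs
#' rest") coefficient, cluster-robust SE and p-value.  The fit itself —
#' fitted values, R-squared and model p — is identical across rotations
#' (the basis change is an orthogonal transform of the ILR design block),
#' so those are reported once.
#'
#' @inheritParams fit_composition_model
#' @return Object of class `coda_rotations`: `models` (named list of
#'   [fit_composition_model()] results), `table` (4 rows: outcome, label,
#'   beta, se, p, significant), `r2`, `model_p`.
#' @export
fit_rotations <- function(data, outcome, parts = mb_parts(), ...) {
  models <- lapply(stats::setNames(parts, parts), function(p) {
    fit_composition_model(data, outcome, pivot = p, parts = parts, ...)
  })
  rows <- lapply(parts, function(p) {
    ct <- models[[p]]$coefficients
    z1 <- ct[ct$term == "z1", ]
    data.frame(outcome = outcome, pivot = p,
               label = row_label(p, parts),
               beta = z1$estimate, se = z1$se, p = z1$p,
               significant = z1$p < models[[p]]$alpha,
               stringsAsFactors = FALSE)
  })
  structure(list(models = models, table = do.call(rbind, rows),
                 r2 = models[[1]]$r2, model_p = models[[1]]$model_p,
                 outcome = outcome),
            class = "coda_rotations")
}

#' @export
print.coda_rotations <- function(x, digits = 3, ...) {
  cat("Rotated compositional models for ", x$outcome,
      sprintf(" (R^2 = %.*f, model p = %.*f)\n", digits, x$r2, digits,
              x$model_p), sep = "")
  tab <- x$table[, c("label", "beta", "se", "p", "significant")]
  tab[, c("beta", "se", "p")] <- round(tab[, c("beta", "se", "p")], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Residual and collinearity diagnostics for a fitted model
#'
#' Reports (without refitting) the Shapiro-Wilk normality statistic on the
#' residuals, the studentised Breusch-Pagan heteroscedasticity test, and
#' generalised variance inflation factors for the design columns.
#' Aliased/duplicated columns are reported as a collinearity flag rather
#' than an error.
#'
#' @param model A `coda_fit`.
#' @param alpha Flagging level (default 0.05).
#' @return List of class `coda_diagnostics` with `shapiro`, `bp`, `vif`
#'   and logical flags `nonnormal`, `heteroscedastic`, `collinear`.
#' @export
model_diagnostics <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "coda_fit"))
  sw <- stats::shapiro.test(model$residuals)
  bp <- lmtest::bptest(model$fit)
  vif <- tryCatch(car::vif(model$fit),
                  error = function(e) structure(Inf, failure = conditionMessage(e)))
  vmax <- if (is.matrix(vif)) max(vif[, 1]) else max(vif)
  structure(list(
    shapiro = sw, bp = bp, vif = vif,
    nonnormal = sw$p.value < alpha,
    heteroscedastic = bp$p.value < alpha,
    collinear = !is.finite(vmax) || vmax > 10
  ), class = "coda_diagnostics")
}

#' @export
print.coda_diagnostics <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk W = %.3f (p = %.3f)%s\n", x$shapiro$statistic,
              x$shapiro$p.value, if (x$nonnormal) " *" else ""))
  cat(sprintf("Breusch-Pagan = %.3f (p = %.3f)%s\n", x$bp$statistic,
              x$bp$p.value, if (x$heteroscedastic) " *" else ""))
  cat("max VIF:", if (all(is.finite(unlist(x$vif))))
    round(max(if (is.matrix(x$vif)) x$vif[, 1] else x$vif), 2) else "Inf",
    if (x$collinear) "(collinearity flagged)", "\n")
  invisible(x)
}
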