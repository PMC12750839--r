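#' @keywords internal
"_PACKAGE"

#' Canonical movement-behaviour parts
#'
#' The four parts of the 24-hour movement behaviour composition, in canonical
#' order: sleep, sedentary time (SED), light physical activity (LPA) and
#' moderate-to-vigorous physical activity (MVPA).
#'
#' @return Character vector of the four part names.
#' @export
mb_parts <- function() c("sleep", "sed", "lpa", "mvpa")

# Pretty labels used in printed tables.
.mb_labels <- c(sleep = "Sleep", sed = "SED", lpa = "LPA", mvpa = "MVPA")

mb_label <- function(part) {
  ifelse(part %in% names(.mb_labels), unname(.mb_labels[part]), part)
}

# Coerce a composition (named vector, matrix or data.frame) to an n x D
# matrix with columns in `parts` order, validating strict positivity.
as_part_matrix <- function(x, parts = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (is.null(parts)) {
    parts <- colnames(x)
    if (is.null(parts)) parts <- mb_parts()[seq_len(ncol(x))]
  }
  if (!is.null(colnames(x))) {
    missing <- setdiff(parts, colnames(x))
    if (length(missing)) {
      stop("composition is missing part(s): ", paste(missing, collapse = ", "))
    }
    x <- x[, parts, drop = FALSE]
  } else {
    if (ncol(x) != length(parts)) {
      stop("composition has ", ncol(x), " columns but ", length(parts),
           " parts were expected")
    }
    colnames(x) <- parts
  }
  storage.mode(x) <- "double"
  bad <- which(!(is.finite(x) & x > 0), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive or non-finite value in part '",
         parts[bad[1, 2]], "' (row ", bad[1, 1], "); ",
         "compositions must be strictly positive. ",
         "See replace_zeros() for an explicit zero-replacement pre-step.")
  }
  x
}

#' Close a composition to a fixed total
#'
#' Rescales each composition so its parts sum to `total` (by default the
#' 1440 minutes of a day) without changing the ratios between parts.
#'
#' @param x A strictly positive composition: a named numeric vector, or a
#'   matrix/data frame with one composition per row.
#' @param total Closure constant (minutes); default 1440.
#' @param parts Part names and order; defaults to the column names of `x`
#'   or [mb_parts()].
#' @return A closed composition with the same shape as `x` (vectors stay
#'   vectors); rows sum to `total`.
#' @examples
#' close_composition(c(sleep = 473.0, sed = 680.9, lpa = 250.7, mvpa = 35.3),
#'                   total = 100)
#' @export
close_composition <- function(x, total = 1440, parts = NULL) {
  stopifnot(is.numeric(total), length(total) == 1, total > 0)
  vec <- is.null(dim(x)) && !is.data.frame(x)
  m <- as_part_matrix(x, parts)
  out <- m * (total / rowSums(m))
  if (vec) out[1, ] else out
}

#' Compositional (geometric mean) centre of a sample
#'
#' Part-wise geometric mean across compositions, closed to `total`.  This is
#' the standard CoDA centre; for the study cohort it is the "geometric mean"
#' column of the descriptive table.
#'
#' @param x Matrix/data frame of compositions, one row per participant.
#' @inheritParams close_composition
#' @return Named vector: the closed geometric-mean composition.
#' @export
gmean_composition <- function(x, total = 1440, parts = NULL) {
  m <- as_part_matrix(x, parts)
  if (nrow(m) < 1) stop("empty sample")
  g <- exp(colMeans(log(m)))
  close_composition(g, total = total)
}

#' Perturbation (simplex addition)
#'
#' Component-wise product of two compositions followed by closure: the
#' translation operation of Aitchison geometry.
#'
#' @param x,p Compositions over the same parts.
#' @inheritParams close_composition
#' @return Closed perturbed composition, same shape as `x`.
#' @export
perturb <- function(x, p, total = 1440, parts = NULL) {
  vec <- is.null(dim(x)) && !is.data.frame(x)
  m <- as_part_matrix(x, parts)
  pm <- as_part_matrix(p, colnames(m))
  if (nrow(pm) == 1) pm <- pm[rep(1, nrow(m)), , drop = FALSE]
  out <- close_composition(m * pm, total = total)
  if (vec) out[1, ] else out
}

#' Variation matrix of a compositional sample
#'
#' Entry (i, j) is the sample variance (n - 1 denominator) of
#' `log(x_i / x_j)` across the sample.  Values near 0 indicate strong
#' co-dependence between the two parts; larger values indicate that the
#' parts vary more independently.
#'
#' @param x Matrix/data frame of compositions, one row per participant
#'   (at least two rows).
#' @param parts Part names/order; defaults to the columns of `x`.
#' @return A D x D symmetric matrix with zero diagonal, of class
#'   `variation_matrix`.
#' @export
variation_matrix <- function(x, parts = NULL) {
  m <- as_part_matrix(x, parts)
  if (nrow(m) < 2) stop("variation matrix needs at least 2 compositions")
  lx <- log(m)
  D <- ncol(m)
  out <- matrix(0, D, D, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(D - 1)) {
    for (j in (i + 1):D) {
      v <- stats::var(lx[, i] - lx[, j])
      out[i, j] <- out[j, i] <- v
    }
  }
  structure(out, class = c("variation_matrix", "matrix"))
}

#' @export
print.variation_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise log-ratio variation matrix (", ncol(x), " parts)\n", sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Pivot-coordinate ILR basis
#'
#' Builds the isometric log-ratio basis induced by a pivot ordering of the
#' parts.  Coordinate k contrasts the k-th part of the ordering against the
#' geometric mean of the parts after it; the first coordinate therefore
#' isolates the pivot part against all remaining behaviours, which is the
#' coordinate interpreted in the rotated regression models.
#'
#' @param parts Character vector of part names in pivot order.
#' @return An object of class `ilr_basis`: the ordering, the dimension `D`,
#'   and the D x (D-1) orthonormal contrast matrix `V` (rows in `parts`
#'   order) satisfying `clr(x) = V %*% z`.
#' @seealso [rotate_basis()], [ilr_pivot()]
#' @export
pivot_basis <- function(parts = mb_parts()) {
  parts <- as.character(parts)
  D <- length(parts)
  if (D < 2) stop("need at least 2 parts")
  if (anyDuplicated(parts)) stop("duplicated part names")
  V <- matrix(0, D, D - 1, dimnames = list(parts, paste0("z", seq_len(D - 1))))
  for (k in seq_len(D - 1)) {
    m <- D - k
    s <- sqrt(m / (m + 1))
    V[k, k] <- s
    V[(k + 1):D, k] <- -s / m
  }
  structure(list(order = parts, D = D, V = V, pivot = parts[1]),
            class = "ilr_basis")
}

#' @export
print.ilr_basis <- function(x, ...) {
  cat("Pivot-coordinate ILR basis: ", paste(x$order, collapse = " > "),
      " (z1 = ", x$pivot, " vs rest)\n", sep = "")
  invisible(x)
}

#' Rotate the pivot basis so a chosen behaviour leads
#'
#' Moves `pivot` to the front of the part ordering; the remaining parts keep
#' their canonical relative order.  Used to refit the same model four times
#' so each behaviour's "part vs rest" coefficient is directly interpretable.
#'
#' @param parts Canonical part ordering (default [mb_parts()]).
#' @param pivot Part to move to the front.
#' @return An `ilr_basis`.
#' @examples
#' rotate_basis(pivot = "lpa")$order  # lpa, sleep, sed, mvpa
#' @export
rotate_basis <- function(parts = mb_parts(), pivot = parts[1]) {
  if (!pivot %in% parts) {
    stop("unknown pivot part '", pivot, "'; parts are: ",
         paste(parts, collapse = ", "))
  }
  pivot_basis(c(pivot, setdiff(parts, pivot)))
}

#' ILR pivot coordinates of compositions
#'
#' Maps compositions to the D-1 real pivot coordinates of `basis`.
#' Coordinate k (parts taken in pivot order) is
#' `sqrt((D-k)/(D-k+1)) * log(x_k / gmean(x_{k+1}, ..., x_D))`.
#' The map is closure-invariant: raw minutes and closed compositions give
#' identical coordinates.  Positive z1 means the pivot part is large relative
#' to the geometric mean of the remaining parts.
#'
#' @param x Composition(s): named vector or matrix/data frame rows.
#' @param basis An [ilr_basis]; default canonical pivot order.
#' @return Numeric vector (for a single composition) or n x (D-1) matrix of
#'   coordinates, columns `z1..z(D-1)`.
#' @export
ilr_pivot <- function(x, basis = pivot_basis()) {
  stopifnot(inherits(basis, "ilr_basis"))
  vec <- is.null(dim(x)) && !is.data.frame(x)
  m <- as_part_matrix(x, basis$order)
  D <- basis$D
  lx <- log(m)
  z <- matrix(0, nrow(m), D - 1,
              dimnames = list(rownames(m), paste0("z", seq_len(D - 1))))
  for (k in seq_len(D - 1)) {
    rest <- (k + 1):D
    gm <- rowMeans(lx[, rest, drop = FALSE])
    z[, k] <- sqrt((D - k) / (D - k + 1)) * (lx[, k] - gm)
  }
  if (vec) z[1, ] else z
}

#' Inverse ILR transform
#'
#' Maps pivot coordinates back to compositions closed to `total`.
#'
#' @param z Numeric vector of D-1 coordinates, or an n x (D-1) matrix.
#' @param basis An [ilr_basis].
#' @inheritParams close_composition
#' @return Composition(s) over `basis$order` parts, closed to `total`.
#' @export
ilr_inverse <- function(z, basis = pivot_basis(), total = 1440) {
  stopifnot(inherits(basis, "ilr_basis"))
  vec <- is.null(dim(z))
  if (vec) z <- matrix(z, nrow = 1)
  if (ncol(z) != basis$D - 1) {
    stop("expected ", basis$D - 1, " coordinates, got ", ncol(z))
  }
  clr <- z %*% t(basis$V)            # n x D, columns in basis$order
  out <- close_composition(exp(clr), total = total, parts = basis$order)
  if (vec) out[1, ] else out
}

#' Aitchison distance between compositions
#'
#' Euclidean distance between ILR coordinates; by isometry the value does not
#' depend on which pivot rotation is used.
#'
#' @param x,y Compositions over the same parts.
#' @param parts Part names; defaults to those of `x`.
#' @return Non-negative scalar.
#' @export
aitchison_distance <- function(x, y, parts = NULL) {
  mx <- as_part_matrix(x, parts)
  my <- as_part_matrix(y, colnames(mx))
  if (nrow(mx) != 1 || nrow(my) != 1) {
    stop("aitchison_distance expects single compositions")
  }
  b <- pivot_basis(colnames(mx))
  sqrt(sum((ilr_pivot(mx, b) - ilr_pivot(my, b))^2))
}

#' Multiplicative zero replacement
#'
#' Optional pre-step for datasets that, unlike the study sample, contain
#' zero minutes in some part: zeros are replaced by `delta` minutes and the
#' non-zero parts are multiplicatively rescaled so the row total is
#' preserved.  Not applied automatically anywhere; all core functions treat
#' zeros as errors.
#'
#' @param x Matrix/data frame of non-negative compositions.
#' @param delta Replacement value in minutes (default 1).
#' @return Matrix of strictly positive compositions with unchanged row sums.
#' @export
replace_zeros <- function(x, delta = 1) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  storage.mode(x) <- "double"
  if (any(x < 0)) stop("negative values cannot be zero-replaced")
  tot <- rowSums(x)
  for (i in seq_len(nrow(x))) {
    z <- x[i, ] == 0
    if (any(z)) {
      shrink <- 1 - sum(z) * delta / tot[i]
      if (shrink <= 0) stop("row ", i, ": too many zeros for delta = ", delta)
      x[i, !z] <- x[i, !z] * shrink
      x[i, z] <- delta
    }
  }
  x
}
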