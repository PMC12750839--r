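test_that("closure preserves ratios and reproduces the descriptive shares", {
  gm <- c(sleep = 473.0, sed = 680.9, lpa = 250.7, mvpa = 35.3)
  pct <- close_composition(gm, total = 100)
  expect_equal(round(unname(pct), 1), c(32.8, 47.3, 17.4, 2.5))

  expect_equal(unname(close_composition(c(sleep = 1, sed = 1, lpa = 1, mvpa = 1),
                                        total = 1)),
               rep(0.25, 4))
  expect_equal(unname(close_composition(c(sleep = 2, sed = 1, lpa = 1, mvpa = 1))),
               c(576, 288, 288, 288))

  x <- c(sleep = 400, sed = 700, lpa = 300, mvpa = 40)
  cl <- close_composition(x, total = 1440)
  expect_equal(sum(cl), 1440, tolerance = 1e-9)
  expect_equal(unname(cl / cl[1]), unname(x / x[1]))
})

test_that("non-positive parts are rejected with the part named", {
  expect_error(close_composition(c(sleep = 0, sed = 1, lpa = 1, mvpa = 1)),
               "sleep")
  expect_error(ilr_pivot(c(sleep = 1, sed = 1, lpa = -2, mvpa = 1)), "lpa")
})

test_that("geometric-mean composition is idempotent and part-wise correct", {
  x <- close_composition(c(sleep = 450, sed = 700, lpa = 250, mvpa = 40))
  same <- rbind(x, x, x)
  expect_equal(gmean_composition(same), x, tolerance = 1e-12)

  two <- close_composition(rbind(c(4, 1, 1, 1), c(1, 4, 1, 1)),
                           parts = mb_parts())
  gm <- gmean_composition(two, total = 1)
  expect_equal(unname(gm), c(2, 2, 1, 1) / 6, tolerance = 1e-12)

  expect_error(gmean_composition(two[0, , drop = FALSE]), "empty")
})

test_that("variation matrix matches brute-force log-ratio variances", {
  set.seed(11)
  X <- random_compositions(40)
  vm <- variation_matrix(X)
  expect_true(isSymmetric(unclass(vm)))
  expect_equal(unname(diag(vm)), rep(0, 4))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(vm[i, j], var(log(X[, i] / X[, j])), tolerance = 1e-12)
  }

  # hand case: ln-ratios {0, 2} -> sample variance 2 with n-1 denominator
  Y <- close_composition(rbind(c(1, 1, 1, 1), c(exp(2), 1, 1, 1)),
                         parts = mb_parts())
  expect_equal(variation_matrix(Y)["sleep", "sed"], 2)

  expect_equal(unname(unclass(variation_matrix(rbind(X[1, ], X[1, ])))),
               matrix(0, 4, 4))
  expect_error(variation_matrix(X[1, , drop = FALSE]), "at least 2")
})

test_that("variation matrix is invariant to perturbation and closure", {
  set.seed(12)
  X <- random_compositions(25)
  p <- c(sleep = 2, sed = 0.5, lpa = 3, mvpa = 1)
  expect_equal(unclass(variation_matrix(perturb(X, p))),
               unclass(variation_matrix(X)), tolerance = 1e-10)
  expect_equal(unclass(variation_matrix(close_composition(X, total = 1))),
               unclass(variation_matrix(X)), tolerance = 1e-10)
})

test_that("pivot coordinates follow the defining balance formula", {
  # neutral element
  expect_equal(unname(ilr_pivot(c(sleep = 1, sed = 1, lpa = 1, mvpa = 1))),
               rep(0, 3))
  # two-part case collapses to sqrt(1/2) * ln(x1/x2)
  b2 <- pivot_basis(c("a", "b"))
  expect_equal(unname(ilr_pivot(c(a = exp(1), b = 1), b2)), sqrt(1 / 2))
  # positive z1 iff the pivot part exceeds the gmean of the rest
  z <- ilr_pivot(c(sleep = 200, sed = 600, lpa = 600, mvpa = 40),
                 rotate_basis(pivot = "lpa"))
  expect_gt(z[["z1"]], 0)
})

test_that("pivot ILR agrees with the Gram-Schmidt contrast oracle", {
  set.seed(13)
  X <- random_compositions(200)
  for (pv in mb_parts()) {
    b <- rotate_basis(pivot = pv)
    Z <- ilr_pivot(X, b)
    for (i in sample(nrow(X), 25)) {
      expect_equal(unname(Z[i, ]), oracle_ilr(X[i, ], b$order),
                   tolerance = 1e-10)
    }
  }
})

test_that("ILR is closure-invariant and inverts to 1e-9", {
  set.seed(14)
  X <- random_compositions(100)
  b <- rotate_basis(pivot = "mvpa")
  expect_equal(ilr_pivot(close_composition(X, total = 7), b),
               ilr_pivot(X, b), tolerance = 1e-12)
  Z <- ilr_pivot(X, b)
  back <- ilr_inverse(Z, b)[, mb_parts()]
  expect_lt(max(abs(back - X)), 1e-9)
  # vector round-trip through a different basis
  x <- X[1, ]
  z <- ilr_pivot(x, pivot_basis())
  expect_equal(ilr_inverse(z), x, tolerance = 1e-9)
  expect_equal(unname(ilr_inverse(c(0, 0, 0), total = 1)), rep(0.25, 4))
})

test_that("rotation rule puts the pivot first and keeps canonical tail order", {
  expect_equal(rotate_basis(pivot = "lpa")$order,
               c("lpa", "sleep", "sed", "mvpa"))
  expect_equal(rotate_basis(pivot = "sleep")$order, mb_parts())
  orders <- vapply(mb_parts(), function(p) rotate_basis(pivot = p)$order[1], "")
  expect_equal(unname(orders), mb_parts())
  expect_error(rotate_basis(pivot = "tv"), "unknown pivot")
})

test_that("Aitchison distance is a rotation-invariant isometry", {
  set.seed(15)
  X <- random_compositions(10)
  Y <- random_compositions(10)
  for (i in 1:10) {
    d <- aitchison_distance(X[i, ], Y[i, ])
    for (pv in mb_parts()) {
      b <- rotate_basis(pivot = pv)
      dz <- sqrt(sum((ilr_pivot(X[i, ], b) - ilr_pivot(Y[i, ], b))^2))
      expect_equal(dz, d, tolerance = 1e-10)
    }
  }
  expect_equal(aitchison_distance(X[1, ], X[1, ]), 0)
  p <- c(sleep = 3, sed = 0.2, lpa = 1, mvpa = 5)
  expect_equal(aitchison_distance(perturb(X[1, ], p), perturb(Y[1, ], p)),
               aitchison_distance(X[1, ], Y[1, ]), tolerance = 1e-10)
})

test_that("cross-basis round trip preserves the composition exactly", {
  set.seed(16)
  X <- random_compositions(30)
  b1 <- rotate_basis(pivot = "sed")
  b2 <- rotate_basis(pivot = "mvpa")
  back <- ilr_inverse(ilr_pivot(ilr_inverse(ilr_pivot(X, b1), b1), b2), b2)
  expect_lt(max(abs(back[, mb_parts()] - X)), 1e-9)
})

test_that("zero replacement preserves totals and positivity", {
  x <- rbind(c(480, 900, 60, 0), c(470, 880, 80, 10))
  colnames(x) <- mb_parts()
  r <- replace_zeros(x, delta = 1)
  expect_true(all(r > 0))
  expect_equal(rowSums(r), rowSums(x))
  expect_equal(r[2, ], x[2, ])  # untouched when no zeros
  expect_error(replace_zeros(-x), "negative")
})
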