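# Two-point CBS / CPS extrapolation of scalars and matrix sets.

test_that("CBS reference extrapolation solves the exponential two-point form", {
  p <- extrapolation_params("CBS", 2, 3)   # table defaults: alpha 4.420
  expect_equal(p$alpha, 4.420)
  expect_equal(p$beta, 2.460)
  # constant input is a fixed point (A = 0)
  expect_equal(cbs_reference(-100, -100, p), -100)
  # frozen value from the independent 2x2 linear solve of
  # E(n) = E_CBS + A exp(-alpha sqrt(n)) through (2, -100.0), (3, -100.1)
  expect_equal(cbs_reference(-100.0, -100.1, p), -100.13252162,
               tolerance = 1e-8)
  # and the live oracle: direct algebraic solve
  A <- matrix(c(1, exp(-p$alpha * sqrt(2)), 1, exp(-p$alpha * sqrt(3))),
              2, 2, byrow = TRUE)
  expect_equal(cbs_reference(-100.0, -100.1, p),
               solve(A, c(-100.0, -100.1))[1], tolerance = 1e-12)
  # monotone continuation: the limit continues past E_Y in the same direction
  expect_true(sign(cbs_reference(-100.0, -100.1, p) - (-100.1)) ==
                sign(-100.1 - (-100.0)))
  # degenerate weights: a vanishing exponent makes both basis weights 1
  expect_error(cbs_reference(-1, -2, extrapolation_params(
    "CBS", 2, 3, alpha = 1e-18, beta = 2.46)), "degenerate")
})

test_that("CBS correlation extrapolation follows the inverse-power formula", {
  p <- extrapolation_params("CBS", 2, 3, alpha = 4.42, beta = 2.46)
  expect_equal(cbs_correlation(-0.3, -0.3, p), -0.3)
  # frozen value from the direct formula oracle
  expect_equal(cbs_correlation(-0.300, -0.350, p), -0.37921682,
               tolerance = 1e-7)
  # large-beta limit approaches E_Y
  pl <- extrapolation_params("CBS", 2, 3, alpha = 4.42, beta = 60)
  expect_equal(cbs_correlation(-0.300, -0.350, pl), -0.350, tolerance = 1e-8)
})

test_that("CPS is the affine two-point formula with multiplier F", {
  p <- extrapolation_params("CPS", 6, 7, F = 1.5)
  expect_equal(cps(-0.5, -0.5, p), -0.5)
  expect_equal(cps(-0.500, -0.520, p), -0.530, tolerance = 1e-12)
  p1 <- extrapolation_params("CPS", 6, 7, F = 1)
  expect_identical(cps(-0.500, -0.520, p1), -0.520)
})

test_that("extrapolation recovers limits exactly on model-form data", {
  set.seed(4)
  p <- extrapolation_params("CBS", 3, 4)    # alpha 5.460, beta 3.050
  for (k in 1:20) {
    e_cbs <- runif(1, -200, -50)
    A <- runif(1, -2, 2)
    ex <- e_cbs + A * exp(-p$alpha * sqrt(3))
    ey <- e_cbs + A * exp(-p$alpha * sqrt(4))
    expect_equal(cbs_reference(ex, ey, p), e_cbs, tolerance = 1e-10)
    B <- runif(1, -1, 1)
    cx <- e_cbs + B * 3^-p$beta
    cy <- e_cbs + B * 4^-p$beta
    expect_equal(cbs_correlation(cx, cy, p), e_cbs, tolerance = 1e-10)
  }
})

test_that("both CBS forms and CPS are affine in the two energies", {
  p <- extrapolation_params("CBS", 2, 3)
  pc <- extrapolation_params("CPS", 6, 7, F = 1.5)
  for (fn in list(cbs_reference, cbs_correlation, cps)) {
    pp <- if (identical(fn, cps)) pc else p
    a <- fn(-1.0, -1.1, pp); b <- fn(-0.4, -0.35, pp)
    expect_equal(fn(-1.0 + -0.4, -1.1 + -0.35, pp), a + b, tolerance = 1e-10)
    expect_equal(fn(3 * -1.0, 3 * -1.1, pp), 3 * a, tolerance = 1e-10)
  }
})

build_nbody_sets <- function(gt, bsse = FALSE) {
  specs <- enumerate_campaign(gt$geometry, gt$subsystems, list(gt$setting),
                              bsse = bsse, include_twobody = FALSE)
  recs <- lapply(specs, truth_record, gt = gt)
  assemble_standard_nbody(recs[[1]], recs[-1], gt$subsystems)
}

test_that("matrix-set extrapolation equals cellwise scalar extrapolation", {
  gt <- generate_ground_truth(2, c(2, 2), seed = 91)
  p <- extrapolation_params("CBS", 2, 3)
  ser <- ground_truth_series(gt, p, seed = 5)
  sx <- build_nbody_sets(ser$x)
  sy <- build_nbody_sets(ser$y)
  lim <- build_nbody_sets(gt)
  ext <- extrapolate_matrixset(sx, sy, p)
  # recovery of the planted limit
  for (cc in names(lim$components)) {
    expect_equal(ext$components[[cc]], lim$components[[cc]],
                 tolerance = 1e-7, info = cc)
  }
  # cellwise equivalence with the scalar formulas
  expect_equal(ext$components$elstat,
               cbs_reference(sx$components$elstat, sy$components$elstat, p),
               tolerance = 1e-12)
  expect_equal(ext$components$disp,
               cbs_correlation(sx$components$disp, sy$components$disp, p),
               tolerance = 1e-12)
  # total closure after extrapolation
  closure <- ext$components$elprep + ext$components$elstat +
    ext$components$exch + ext$components$no_disp + ext$components$disp
  expect_equal(closure, ext$components$total, tolerance = 1e-10)
  # extrapolation commutes with summation over cells
  expect_equal(matrix_grand_total(ext),
               cbs_reference(
                 sum(diag(sx$components$elprep_ref)) +
                   sum(sx$components$elstat[upper.tri(sx$components$elstat)]) +
                   sum(sx$components$exch[upper.tri(sx$components$exch)]),
                 sum(diag(sy$components$elprep_ref)) +
                   sum(sy$components$elstat[upper.tri(sy$components$elstat)]) +
                   sum(sy$components$exch[upper.tri(sy$components$exch)]), p) +
                 cbs_correlation(
                   sum(diag(sx$components$elprep_corr)) +
                     sum(sx$components$no_disp[upper.tri(sx$components$no_disp)]) +
                     sum(sx$components$disp[upper.tri(sx$components$disp)]),
                   sum(diag(sy$components$elprep_corr)) +
                     sum(sy$components$no_disp[upper.tri(sy$components$no_disp)]) +
                     sum(sy$components$disp[upper.tri(sy$components$disp)]), p),
               tolerance = 1e-8)
  # fixed point on identical inputs
  same <- extrapolate_matrixset(sy, sy, p)
  for (cc in names(sy$components)) {
    expect_equal(same$components[[cc]], sy$components[[cc]],
                 tolerance = 1e-10)
  }
})

test_that("CPS matrix extrapolation touches correlation components only", {
  gt <- generate_ground_truth(2, c(2, 1), seed = 93)
  p <- extrapolation_params("CPS", 6, 7, F = 1.5)
  ser <- ground_truth_series(gt, p, seed = 6)
  sx <- build_nbody_sets(ser$x)
  sy <- build_nbody_sets(ser$y)
  lim <- build_nbody_sets(gt)
  ext <- extrapolate_matrixset(sx, sy, p)
  # reference components pass through from the tighter-threshold set
  expect_identical(ext$components$elstat, sy$components$elstat)
  expect_identical(ext$components$exch, sy$components$exch)
  # correlation components land on the limit
  expect_equal(ext$components$disp, lim$components$disp, tolerance = 1e-7)
  expect_equal(ext$components$total, lim$components$total, tolerance = 1e-7)
  # mask mismatch refused
  bad <- sx
  bad$absent[1, 2] <- TRUE
  expect_error(extrapolate_matrixset(bad, sy, p), "alignment error")
})
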