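test_that("reference tabulations load with published values", {
  h <- load_reference_basis("H", "STO-3G")
  expect_length(h, 1)
  expect_length(h[[1]]$exponents, 3)
  expect_equal(max(h[[1]]$exponents), 3.42525091, tolerance = 1e-8)
  c6 <- load_reference_basis("C", "STO-6G")
  expect_true(any(vapply(c6, function(s) s$type != "S", TRUE)))
  expect_error(load_reference_basis("Fe", "STO-3G"), "not available")
})

test_that("the Slater-expansion fitter reproduces the universal 1s table", {
  f <- fit_sto_expansion(1, 0, 3)
  expect_equal(sort(f$exponents),
               sort(c(2.227660584, 0.405771156, 0.109818)),
               tolerance = 2e-4)
  expect_equal(sort(abs(f$coefficients)),
               sort(c(0.15432897, 0.53532814, 0.44463454)), tolerance = 2e-4)
  expect_gt(f$overlap, 0.9985)
})

test_that("the shared-exponent sp fitter reproduces the published 2sp table", {
  f <- fit_sto_expansion_sp(2, 3L)
  expect_equal(f$exponents, c(0.994203, 0.231031, 0.0751386),
               tolerance = 1e-4)
  expect_equal(f$coef_s, c(-0.09996723, 0.39951283, 0.70011547),
               tolerance = 1e-4)
  expect_equal(f$coef_p, c(0.15591627, 0.60768372, 0.39195739),
               tolerance = 1e-4)
})

test_that("basis sizes follow the minimal-basis element counts", {
  expect_equal(build_basis(make_named_small("H2O"))$n_bf, 7)
  expect_equal(build_basis(make_named_small("H2"))$n_bf, 2)
  expect_equal(count_basis_functions(c(C = 40, H = 56)), 256)
  expect_error(count_basis_functions(c(Fe = 1)), "unsupported")
  b <- build_basis(make_named_small("H2O"))
  ## atom-major ordering, shells 1s 2s 2px 2py 2pz on oxygen
  expect_equal(b$fn$label[1:5], c("1s", "2s", "2px", "2py", "2pz"))
  expect_equal(b$fn$atom, c(1, 1, 1, 1, 1, 2, 3))
  ## valence flags: O 1s core, everything else valence
  expect_equal(b$fn$valence, c(FALSE, rep(TRUE, 6)))
})

test_that("every contraction is renormalized to unit self-overlap", {
  b <- build_basis(make_named_small("H2O"))
  S <- one_electron_matrices(b)$S
  expect_equal(diag(S), rep(1, 7), tolerance = 1e-8)
})

test_that("cached lobe p functions are odd, accurate and normalized", {
  lp <- lobehf:::get_lobe_params("C", 2L)
  shell <- Filter(function(s) s$type != "S" && s$n_quantum == 2,
                  load_reference_basis("C", "STO-6G"))[[1]]
  ## dense-grid quadrature oracle for the relative L2 error
  g <- lobehf:::.lobe_grid(shell, 41L)
  ref <- lobehf:::.ref_p_eval(shell, g$x, g$y, g$z)
  lobe_eval <- function(x, y, z) {
    v <- 0
    for (a in 1:3) {
      v <- v + lp$lobe$A[a] *
        (exp(-lp$lobe$alpha[a] * ((x - lp$lobe$d[a])^2 + y^2 + z^2)) -
           exp(-lp$lobe$alpha[a] * ((x + lp$lobe$d[a])^2 + y^2 + z^2)))
    }
    v
  }
  fit <- lobe_eval(g$x, g$y, g$z)
  expect_lt(sqrt(sum((fit - ref)^2) / sum(ref^2)), 0.02)
  ## exact odd parity: zero on the nodal plane by construction
  expect_equal(lobe_eval(0, 0.7, -0.3), 0)
  expect_equal(lobe_eval(0.5, 0.2, 0.1), -lobe_eval(-0.5, 0.2, 0.1))
  ## displacements below the 2 bohr bound
  expect_true(all(abs(lp$lobe$d) < 2))
  ## unit self-overlap after renormalization, to grid-quadrature accuracy
  ## (the exact analytic check is diag(S) = 1 in the overlap tests)
  expect_equal(sum(fit^2) * g$h3, 1, tolerance = 0.02)
})

test_that("the all-positive per-lobe representation meets its budgets", {
  lp <- lobehf:::get_lobe_params("C", 2L)
  shell <- Filter(function(s) s$type != "S" && s$n_quantum == 2,
                  load_reference_basis("C", "STO-6G"))[[1]]
  g <- lobehf:::.lobe_grid(shell, 41L)
  ref <- lobehf:::.ref_p_eval(shell, g$x, g$y, g$z)
  lobe <- function(sgn) {
    v <- 0
    for (a in seq_along(lp$abs$A)) {
      v <- v + lp$abs$A[a] *
        exp(-lp$abs$ax[a] * (g$x - sgn * lp$abs$x0[a])^2 -
              lp$abs$ap[a] * (g$y^2 + g$z^2))
    }
    v
  }
  m1 <- lobe(1); m2 <- lobe(-1)
  ## each lobe is non-negative everywhere by construction
  expect_true(all(m1 >= 0) && all(m2 >= 0))
  ## signed combination reproduces the p orbital; the achievable error
  ## of an all-positive two-lobe split is floored by Gaussian leakage
  ## across the nodal plane at ~7% (see the methods vignette)
  expect_lt(sum(abs((m1 - m2) - ref)) / sum(abs(ref)), 0.08)
  ## its absolute value reproduces |p| at the same level
  expect_lt(sum(abs(abs(m1 - m2) - abs(ref))) / sum(abs(ref)), 0.08)
  ## mirror symmetry of the two lobes is exact by construction
  expect_equal(sum(m1^2), sum(m2^2), tolerance = 1e-12)
})

test_that("refitting a lobe shell from scratch converges to the target", {
  shell <- Filter(function(s) s$type != "S" && s$n_quantum == 2,
                  load_reference_basis("C", "STO-6G"))[[1]]
  lf <- fit_lobe_p_orbital(shell, n_grid = 31L)
  expect_lt(lf$rel_l2, 0.02)
  expect_true(all(lf$A > 0))
  expect_equal(lf$d, lf$k / sqrt(lf$alpha))
})

test_that("s-only basis construction matches the standard tabulation", {
  ## for H/He systems the lobe machinery must not alter anything
  b <- build_basis(make_h_chain(2, 1.4))
  expect_equal(length(b$prim_coef), 6)
  expect_true(all(b$fn$label == "1s"))
  expect_equal(unname(b$prim_alpha[1:3]),
               c(3.42525091, 0.62391373, 0.16885540), tolerance = 1e-8)
})
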