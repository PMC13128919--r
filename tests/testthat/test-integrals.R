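test_that("pair factors follow the closed form", {
  g1 <- gaussian_primitive(1, 1, c(0, 0, 0))
  p <- pair_factor(g1, g1)
  expect_equal(p$O, sqrt(2) * pi^1.25 * 2^-1.5, tolerance = 1e-12)
  expect_equal(p$center, c(0, 0, 0))
  ## composite center on the segment, symmetric in the arguments
  g2 <- gaussian_primitive(0.5, 2, c(0, 0, 1))
  p12 <- pair_factor(g1, g2)
  p21 <- pair_factor(g2, g1)
  expect_equal(p12$O, p21$O)
  expect_equal(p12$center, c(0, 0, 2 / 3))
  ## monotone decay with separation
  Os <- vapply(c(1, 2, 4, 8), function(d) {
    pair_factor(g1, gaussian_primitive(1, 1, c(0, 0, d)))$O
  }, numeric(1))
  expect_true(all(diff(Os) < 0))
})

test_that("the rational erf approximation meets its error bounds", {
  x <- seq(0, 6, length.out = 1e5)
  expect_lt(max(abs(erf_approx(x) - exact_erf(x))), 2e-7)
  expect_lt(abs(erf_approx(0)), 1.5e-7)
  ## large-argument shortcut: exactly 1 at and beyond 4
  expect_identical(erf_approx(c(4, 5, 10)), c(1, 1, 1))
  ## the shortcut's own error is the true erf tail
  expect_equal(signif(1 - exact_erf(4), 2), 1.5e-8)
  expect_lt(abs(1 - exact_erf(4)), 1.6e-8)
})

test_that("the 1F1(1/2,3/2,-x) kernel matches erf and its series limit", {
  expect_equal(f11_half(0), 1)
  expect_equal(f11_half(1), sqrt(pi) * exact_erf(1) / 2, tolerance = 1e-10)
  expect_equal(f11_half(1), 0.7468241328, tolerance = 1e-9)
  x <- seq(0, 50, length.out = 2000)
  expect_true(all(diff(f11_half(x)) < 0))
  ## series/closed-form junction is smooth
  expect_equal(f11_half(9.9e-9), f11_half(1.01e-8), tolerance = 1e-8)
})

test_that("primitive ERIs agree with the integral-transform oracle", {
  cases <- list(
    list(a = c(1, 1), c = c(1, 1), d = c(0, 0, 0)),      # all coincident
    list(a = c(0.3, 1.7), c = c(0.8, 0.5), d = c(0, 0, 2)),
    list(a = c(2.5, 0.2), c = c(0.9, 1.1), d = c(1, -1, 3)),
    list(a = c(1, 1), c = c(1, 1), d = c(0, 0, 12)))     # well separated
  for (cs in cases) {
    p1 <- pair_factor(gaussian_primitive(1, cs$a[1], c(0, 0, 0)),
                      gaussian_primitive(1, cs$a[2], c(0.3, 0, 0)))
    p2 <- pair_factor(gaussian_primitive(1, cs$c[1], cs$d),
                      gaussian_primitive(1, cs$c[2], cs$d + c(0, 0.4, 0)))
    v <- eri_primitive(p1, p2)
    ref <- eri_transform_oracle(p1, p2)
    expect_equal(v, ref, tolerance = 1e-6)
  }
  ## coincident composite centers: kernel at zero is exactly 1
  p <- pair_factor(gaussian_primitive(1, 1, c(0, 0, 0)),
                   gaussian_primitive(1, 1, c(0, 0, 0)))
  P <- 1 / (1 / p$p + 1 / p$p)
  expect_equal(eri_primitive(p, p), p$O^2 * sqrt(P))
  ## invariance under global translation of all four centers
  shift <- c(2, -3, 5)
  p1 <- pair_factor(gaussian_primitive(1, 0.7, c(0, 0, 0)),
                    gaussian_primitive(1, 1.1, c(1, 0, 0)))
  p2 <- pair_factor(gaussian_primitive(1, 0.4, c(0, 2, 0)),
                    gaussian_primitive(1, 0.9, c(0, 2, 1)))
  q1 <- pair_factor(gaussian_primitive(1, 0.7, shift),
                    gaussian_primitive(1, 1.1, c(1, 0, 0) + shift))
  q2 <- pair_factor(gaussian_primitive(1, 0.4, c(0, 2, 0) + shift),
                    gaussian_primitive(1, 0.9, c(0, 2, 1) + shift))
  expect_equal(eri_primitive(p1, p2), eri_primitive(q1, q2),
               tolerance = 1e-12)
})

test_that("contracted ERIs are 8-fold symmetric and s-shell exact", {
  b <- build_basis(make_named_small("H2O"))
  v1 <- eri_contracted(3, 1, 6, 7, b)
  expect_identical(eri_contracted(1, 3, 6, 7, b), v1)
  expect_identical(eri_contracted(6, 7, 3, 1, b), v1)
  ## H2 (11|11): frozen conventional STO-3G value (s shells are exactly
  ## the standard contraction)
  bh <- build_basis(make_named_small("H2"))
  expect_equal(eri_contracted(1, 1, 1, 1, bh), 0.7746059439,
               tolerance = 1e-9)
  ## lobe p ERIs against the conventional Cartesian reference: the
  ## difference is the lobe-expansion budget
  bc <- build_basis(molecular_system("C", matrix(0, 1, 3)))
  expect_equal(eri_contracted(3, 3, 3, 3, bc), oracle$c_eri$pppp,
               tolerance = 2e-3)
  expect_equal(eri_contracted(3, 3, 4, 4, bc), oracle$c_eri$ppqq,
               tolerance = 2e-3)
  expect_equal(eri_contracted(1, 3, 1, 3, bc), oracle$c_eri$sps,
               tolerance = 2e-2)
  ## and against the transform oracle, which checks the machinery itself
  ## at full precision on the same lobe primitives
  idx <- (bc$fn_ptr[3] + 1):bc$fn_ptr[4]
  acc <- 0
  for (m in idx) for (n in idx) {
    pmn <- pair_factor(
      gaussian_primitive(bc$prim_coef[m], bc$prim_alpha[m], bc$prim_center[m, ]),
      gaussian_primitive(bc$prim_coef[n], bc$prim_alpha[n], bc$prim_center[n, ]))
    for (o in idx) for (p_ in idx) {
      pop <- pair_factor(
        gaussian_primitive(bc$prim_coef[o], bc$prim_alpha[o], bc$prim_center[o, ]),
        gaussian_primitive(bc$prim_coef[p_], bc$prim_alpha[p_], bc$prim_center[p_, ]))
      acc <- acc + eri_transform_oracle(pmn, pop)
    }
  }
  expect_equal(eri_contracted(3, 3, 3, 3, bc), acc, tolerance = 1e-6)
})

test_that("one-electron matrices match the conventional reference for H2", {
  b <- build_basis(make_named_small("H2"))
  one <- one_electron_matrices(b)
  expect_equal(one$S[1, 2], oracle$h2$S12, tolerance = 1e-9)
  expect_equal(one$T[1, 1], oracle$h2$T11, tolerance = 1e-9)
  expect_equal(one$T[1, 2], oracle$h2$T12, tolerance = 1e-9)
  expect_equal(one$V[1, 1], oracle$h2$V11, tolerance = 1e-9)
  expect_equal(one$V[1, 2], oracle$h2$V12, tolerance = 1e-9)
  expect_equal(diag(one$S), c(1, 1), tolerance = 1e-10)
  ## kinetic energy is a positive-definite quadratic form
  expect_true(all(eigen(one$T, symmetric = TRUE)$values > 0))
  expect_equal(one$H, one$T + one$V)
})

test_that("unique-ERI counting follows the 8-fold symmetry formula", {
  expect_equal(count_unique_eris(256), 541089856)
  expect_equal(count_unique_eris(1), 1)
  ## n_bf = 2 by explicit enumeration of canonical quadruples
  quads <- expand.grid(i = 1:2, j = 1:2, k = 1:2, l = 1:2)
  canon <- unique(t(apply(quads, 1, function(q) {
    ij <- sort(q[1:2], decreasing = TRUE)
    kl <- sort(q[3:4], decreasing = TRUE)
    a <- ij[1] * (ij[1] + 1) / 2 + ij[2]
    b <- kl[1] * (kl[1] + 1) / 2 + kl[2]
    if (a >= b) c(ij, kl) else c(kl, ij)
  })))
  expect_equal(count_unique_eris(2), nrow(canon))
  expect_equal(count_unique_eris(2), 6)
})
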