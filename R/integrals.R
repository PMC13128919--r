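## One- and two-electron integrals over displaced s-type Gaussians.
##
## Because the lobe construction reduces every basis function to a sum of
## s primitives, all integrals have a single closed form each: the
## Gaussian product theorem for overlap/kinetic and an erf kernel (the
## confluent hypergeometric function 1F1(1/2, 3/2, -x)) for nuclear
## attraction and electron repulsion. No angular-momentum recursion
## exists anywhere in the code.

#' Rational approximation of the error function
#'
#' The five-term rational approximation (Abramowitz-Stegun 7.1.26) with
#' an exp(-x^2) factor, plus the large-argument shortcut erf(x >= 4) = 1
#' (which introduces at most 1 - erf(4) ~ 1.5e-8). Absolute error below
#' 2e-7 on [0, 4]. This is the documented fast path of the ERI kernel;
#' the engine's default kernel uses the C library erf, which is exact to
#' machine precision at comparable cost on modern hardware.
#'
#' @param x non-negative numeric vector.
#' @return approximate erf(x).
#' @examples
#' erf_approx(c(0, 1, 4))
#' @export
erf_approx <- function(x) {
  stopifnot(all(x >= 0))
  cpp_erf_approx(as.numeric(x))
}

#' Confluent hypergeometric kernel 1F1(1/2, 3/2, -x)
#'
#' Equal to sqrt(pi) erf(sqrt(x)) / (2 sqrt(x)); the x -> 0 limit is
#' handled by its Taylor series below 1e-8.
#'
#' @param x non-negative numeric vector.
#' @export
f11_half <- function(x) {
  stopifnot(all(x >= 0))
  cpp_f11_half(as.numeric(x))
}

#' An s-type Gaussian primitive
#' @param coef coefficient A (including normalization), a.u.
#' @param alpha exponent, bohr^-2.
#' @param center 3-vector, bohr.
#' @export
gaussian_primitive <- function(coef, alpha, center) {
  stopifnot(alpha > 0, length(center) == 3)
  list(coef = coef, alpha = alpha, center = as.numeric(center))
}

#' Pair overlap factor and composite center of two s primitives
#'
#' The precomputable per-pair quantities of the ERI factorization: the
#' pair overlap factor O = sqrt(2) pi^(5/4) A_a A_b (alpha_a+alpha_b)^(-3/2)
#' exp(-mu |r_a - r_b|^2) and the exponent-weighted composite center.
#'
#' @param g_a,g_b primitives from [gaussian_primitive()].
#' @return list with `O`, `center` (composite center r_ab, bohr) and
#'   `p` (exponent sum).
#' @export
pair_factor <- function(g_a, g_b) {
  p <- g_a$alpha + g_b$alpha
  d2 <- sum((g_a$center - g_b$center)^2)
  O <- sqrt(2) * pi^1.25 * g_a$coef * g_b$coef / p^1.5 *
    exp(-g_a$alpha * g_b$alpha / p * d2)
  list(O = O,
       center = (g_a$alpha * g_a$center + g_b$alpha * g_b$center) / p,
       p = p)
}

#' Primitive electron repulsion integral from two pair records
#'
#' (g_a g_b | g_c g_d) = O_ab O_cd sqrt(P) 1F1(1/2, 3/2, -P d^2) with the
#' reduced exponent P = 1/(1/(alpha_a+alpha_b) + 1/(alpha_c+alpha_d)) and
#' d the distance between the composite centers.
#'
#' @param pair_ab,pair_cd pair records from [pair_factor()].
#' @return the ERI value in hartree.
#' @export
eri_primitive <- function(pair_ab, pair_cd) {
  P <- 1 / (1 / pair_ab$p + 1 / pair_cd$p)
  d2 <- sum((pair_ab$center - pair_cd$center)^2)
  pair_ab$O * pair_cd$O * sqrt(P) * f11_half(P * d2)
}

#' Contracted ERI over four basis functions
#'
#' Sums [eri_primitive()] over all primitive products of the two density
#' pairs; exactly symmetric under the 8-fold index permutation group by
#' construction.
#'
#' @param i,j,k,l basis-function indices (1-based).
#' @param basis a `lobe_basis`.
#' @export
eri_contracted <- function(i, j, k, l, basis) {
  ## canonicalize so every member of the 8-fold orbit takes the same
  ## summation path and returns a bit-identical value
  if (i < j) { t <- i; i <- j; j <- t }
  if (k < l) { t <- k; k <- l; l <- t }
  if (i * (i + 1) / 2 + j < k * (k + 1) / 2 + l) {
    t <- i; i <- k; k <- t
    t <- j; j <- l; l <- t
  }
  pr <- function(i) {
    idx <- (basis$fn_ptr[i] + 1):basis$fn_ptr[i + 1]
    list(coef = basis$prim_coef[idx], alpha = basis$prim_alpha[idx],
         center = basis$prim_center[idx, , drop = FALSE])
  }
  acc <- 0
  fa <- pr(i); fb <- pr(j); fc <- pr(k); fd <- pr(l)
  for (a in seq_along(fa$coef)) for (b in seq_along(fb$coef)) {
    pab <- pair_factor(gaussian_primitive(fa$coef[a], fa$alpha[a], fa$center[a, ]),
                       gaussian_primitive(fb$coef[b], fb$alpha[b], fb$center[b, ]))
    for (cc in seq_along(fc$coef)) for (d in seq_along(fd$coef)) {
      pcd <- pair_factor(gaussian_primitive(fc$coef[cc], fc$alpha[cc], fc$center[cc, ]),
                         gaussian_primitive(fd$coef[d], fd$alpha[d], fd$center[d, ]))
      acc <- acc + eri_primitive(pab, pcd)
    }
  }
  acc
}

#' Number of permutationally unique ERIs
#'
#' M(M+1)/2 with M = n_bf(n_bf+1)/2, the count of canonical quadruples
#' under the 8-fold permutational symmetry.
#'
#' @param n_bf number of basis functions.
#' @return the count (as a double; exact for all practically occurring
#'   sizes).
#' @examples
#' count_unique_eris(256)
#' @export
count_unique_eris <- function(n_bf) {
  stopifnot(n_bf >= 1)
  M <- n_bf * (n_bf + 1) / 2
  M * (M + 1) / 2
}

#' ERI bookkeeping report for a structure
#'
#' The theoretical (n_bf^4) and permutationally distinct ERI counts for a
#' system's minimal basis, plus (optionally) the numbers surviving the
#' density and Coulomb screening tiers. The screened counts require
#' building the relevance matrix and task list.
#'
#' @param system a [molecular_system()].
#' @param screening optional [screening_config()]; when supplied the
#'   screened pair/task counts are included.
#' @return list with `n_bf`, `theoretical`, `distinct`, and when
#'   screening is given `relevant_pairs` and `screened_tasks`.
#' @export
eri_count_report <- function(system, screening = NULL) {
  counts <- table(system$atoms$element)
  n_bf <- count_basis_functions(counts)
  out <- list(n_bf = n_bf, theoretical = n_bf^4,
              distinct = count_unique_eris(n_bf))
  if (!is.null(screening)) {
    tk <- build_task_list(build_basis(system), screening)
    out$relevant_pairs <- length(tk$pair_i)
    out$screened_tasks <- length(tk$p1)
  }
  out
}

#' One-electron integral matrices
#'
#' Overlap, kinetic and nuclear-attraction matrices over the lobe basis,
#' via the closed s-Gaussian forms; the nuclear attraction uses the same
#' erf kernel as the ERIs, evaluated once per primitive pair and nucleus.
#'
#' @param basis a `lobe_basis` from [build_basis()].
#' @return list with matrices `S`, `T`, `V` and `H` (= T + V), all in
#'   hartree/atomic units.
#' @export
one_electron_matrices <- function(basis) {
  np <- length(basis$prim_coef)
  n <- basis$n_bf
  ia <- rep(seq_len(np), times = np)
  ib <- rep(seq_len(np), each = np)
  aa <- basis$prim_alpha[ia]; ab <- basis$prim_alpha[ib]
  p <- aa + ab
  mu <- aa * ab / p
  dxyz <- basis$prim_center[ia, , drop = FALSE] -
    basis$prim_center[ib, , drop = FALSE]
  d2 <- rowSums(dxyz^2)
  cc <- basis$prim_coef[ia] * basis$prim_coef[ib]
  K <- exp(-mu * d2)
  Sp <- cc * (pi / p)^1.5 * K
  Tp <- mu * (3 - 2 * mu * d2) * Sp
  ## composite centers
  rp <- (aa * basis$prim_center[ia, , drop = FALSE] +
           ab * basis$prim_center[ib, , drop = FALSE]) / p
  Vp <- numeric(np * np)
  for (c_at in seq_len(nrow(basis$atom_pos))) {
    rc2 <- (rp[, 1] - basis$atom_pos[c_at, 1])^2 +
      (rp[, 2] - basis$atom_pos[c_at, 2])^2 +
      (rp[, 3] - basis$atom_pos[c_at, 3])^2
    Vp <- Vp - basis$atom_z[c_at] * cc * (2 * pi / p) * K *
      f11_half(p * rc2)
  }
  fa <- basis$prim_fn[ia]; fb <- basis$prim_fn[ib]
  acc <- function(vals) {
    m <- matrix(0, n, n)
    mm <- rowsum(vals, group = (fa - 1) * n + fb - 1)
    idx <- as.integer(rownames(mm))
    m[idx + 1] <- mm
    m <- (m + t(m)) / 2  # exact symmetry
    m
  }
  S <- acc(Sp); Tm <- acc(Tp); V <- acc(Vp)
  list(S = S, T = Tm, V = V, H = Tm + V)
}

#' Dipole integral matrices over the lobe basis
#'
#' Matrices of x, y, z position operators, needed for the dipole coupling
#' and dipole recording of real-time propagation.
#'
#' @param basis a `lobe_basis`.
#' @return list of three n_bf x n_bf matrices (bohr).
#' @export
dipole_matrices <- function(basis) {
  np <- length(basis$prim_coef)
  n <- basis$n_bf
  ia <- rep(seq_len(np), times = np)
  ib <- rep(seq_len(np), each = np)
  aa <- basis$prim_alpha[ia]; ab <- basis$prim_alpha[ib]
  p <- aa + ab
  mu <- aa * ab / p
  dxyz <- basis$prim_center[ia, , drop = FALSE] -
    basis$prim_center[ib, , drop = FALSE]
  d2 <- rowSums(dxyz^2)
  cc <- basis$prim_coef[ia] * basis$prim_coef[ib]
  Sp <- cc * (pi / p)^1.5 * exp(-mu * d2)
  rp <- (aa * basis$prim_center[ia, , drop = FALSE] +
           ab * basis$prim_center[ib, , drop = FALSE]) / p
  fa <- basis$prim_fn[ia]; fb <- basis$prim_fn[ib]
  acc <- function(vals) {
    m <- matrix(0, n, n)
    mm <- rowsum(vals, group = (fa - 1) * n + fb - 1)
    m[as.integer(rownames(mm)) + 1] <- mm
    (m + t(m)) / 2
  }
  list(x = acc(Sp * rp[, 1]), y = acc(Sp * rp[, 2]), z = acc(Sp * rp[, 3]))
}
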