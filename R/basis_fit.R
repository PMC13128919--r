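## Gaussian expansions of Slater-type orbitals.
##
## Minimal bases of the STO-nG family approximate each (node-less) Slater
## orbital by a fixed contraction of n Gaussians whose exponents scale as
## zeta^2 with the Slater exponent. The universal zeta = 1 expansions are
## obtained here by maximizing the overlap between the normalized
## contraction and the normalized Slater radial function, the same
## criterion that defines the published tabulations. The overlap-optimal
## contraction coefficients for fixed exponents are a linear subproblem,
## so only the exponents are optimized nonlinearly.

## radial inner product <f|g> = int f(r) g(r) r^(2+2l) dr on [0, rmax]
.radial_grid <- function(rmax = 60, n = 6000) {
  h <- rmax / n
  r <- seq(h / 2, rmax - h / 2, by = h)  # midpoint rule
  list(r = r, w = rep(h, n))
}

## radial profile h(r) of a node-less Slater orbital for zeta = 1, in
## the convention phi = h(r) * (angular polynomial of degree l): the
## r^l carried by the angular part is NOT included here, it lives in
## the integration weight r^(2+2l)
.slater_radial <- function(n_quantum, r, l = 0L) {
  r^(n_quantum - 1L - l) * exp(-r)
}

#' Fit the universal STO-nG expansion of a Slater orbital
#'
#' Finds `n_gauss` Gaussian exponents and contraction coefficients (for
#' unit Slater exponent) that maximize the overlap with the node-less
#' Slater orbital of principal quantum number `n_quantum` and angular
#' momentum `l` (0 = s, 1 = p). Coefficients refer to normalized
#' primitives, the convention of published minimal-basis tables.
#'
#' @param n_quantum principal quantum number (1, 2 or 3).
#' @param l angular momentum (0 or 1).
#' @param n_gauss number of primitive Gaussians (3 or 6).
#' @return list with `exponents`, `coefficients` (normalized-primitive
#'   convention, contraction normalized to unit self-overlap) and
#'   `overlap` (the achieved <fit|Slater>).
#' @export
fit_sto_expansion <- function(n_quantum, l = 0L, n_gauss = 3L) {
  stopifnot(n_quantum %in% 1:3, l %in% 0:1, n_gauss %in% c(3L, 6L))
  g <- .radial_grid()
  r <- g$r; w <- g$w * r^(2 + 2 * l)
  sl <- .slater_radial(n_quantum, r, l)
  sl <- sl / sqrt(sum(w * sl^2))
  ## normalized radial profile of an l-type Gaussian primitive (the
  ## angular r^l is part of the weight, not the profile)
  gnorm <- function(a) {
    f <- exp(-a * r^2)
    f / sqrt(sum(w * f^2))
  }
  score <- function(loga) {
    a <- exp(loga)
    if (any(!is.finite(a)) || any(a > 1e7) || any(a < 1e-4)) return(1e3)
    G <- vapply(a, gnorm, numeric(length(r)))
    Sg <- crossprod(G * w, G) / 1  # <gi|gj>
    Sg <- crossprod(G, w * G)
    v <- drop(crossprod(G, w * sl))
    ch <- tryCatch(chol(Sg + diag(1e-12, length(a))), error = function(e) NULL)
    if (is.null(ch)) return(1e3)
    x <- backsolve(ch, forwardsolve(t(ch), v))
    -sqrt(max(sum(v * x), 0))
  }
  init <- log(exp(seq(log(0.06), log(60), length.out = n_gauss)) *
                (1 / n_quantum)^2)
  opt <- stats::optim(init, score, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  opt <- stats::optim(opt$par, score, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-13))
  a <- sort(exp(opt$par), decreasing = TRUE)
  G <- vapply(a, gnorm, numeric(length(r)))
  Sg <- crossprod(G, w * G)
  v <- drop(crossprod(G, w * sl))
  c0 <- solve(Sg, v)
  c0 <- c0 / sqrt(drop(crossprod(c0, Sg %*% c0)))  # unit self-overlap
  if (sum(c0 * v) < 0) c0 <- -c0
  list(exponents = a, coefficients = c0, overlap = sum(c0 * v))
}

#' Fit a shared-exponent sp expansion of Slater orbitals
#'
#' The published minimal-basis tabulations constrain the ns and np
#' shells of a period to share one exponent set (which shapes the p
#' contraction noticeably relative to an unconstrained fit). This fits
#' `n_gauss` common exponents maximizing the summed squared overlaps
#' with the node-less ns and np Slater orbitals, with the
#' per-shell coefficients as exact inner linear solves.
#'
#' @inheritParams fit_sto_expansion
#' @return list with `exponents`, `coef_s`, `coef_p` (normalized-
#'   primitive convention, each contraction normalized) and the two
#'   achieved overlaps.
#' @export
fit_sto_expansion_sp <- function(n_quantum, n_gauss = 3L) {
  stopifnot(n_quantum %in% 2:3, n_gauss %in% c(3L, 6L))
  g <- .radial_grid()
  r <- g$r
  w_s <- g$w * r^2
  w_p <- g$w * r^4
  sl_s <- .slater_radial(n_quantum, r, 0L)
  sl_s <- sl_s / sqrt(sum(w_s * sl_s^2))
  sl_p <- .slater_radial(n_quantum, r, 1L)
  sl_p <- sl_p / sqrt(sum(w_p * sl_p^2))
  gnorm <- function(a, l) {
    f <- exp(-a * r^2)
    wl <- if (l == 0) w_s else w_p
    f / sqrt(sum(wl * f^2))
  }
  shell_fit <- function(a, l) {
    wl <- if (l == 0) w_s else w_p
    sll <- if (l == 0) sl_s else sl_p
    G <- vapply(a, gnorm, numeric(length(r)), l = l)
    Sg <- crossprod(G, wl * G)
    v <- drop(crossprod(G, wl * sll))
    ch <- tryCatch(chol(Sg + diag(1e-12, length(a))),
                   error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    x <- backsolve(ch, forwardsolve(t(ch), v))
    ov2 <- max(sum(v * x), 0)
    list(Sg = Sg, v = v, overlap = sqrt(ov2))
  }
  score <- function(loga) {
    a <- exp(loga)
    if (any(!is.finite(a)) || any(a > 1e7) || any(a < 1e-4)) return(1e3)
    fs <- shell_fit(a, 0); fp <- shell_fit(a, 1)
    if (is.null(fs) || is.null(fp)) return(1e3)
    2 - fs$overlap^2 - fp$overlap^2
  }
  init <- log(exp(seq(log(0.05), log(10), length.out = n_gauss)) *
                (1 / n_quantum)^2)
  opt <- stats::optim(init, score, method = "Nelder-Mead",
                      control = list(maxit = 6000, reltol = 1e-13))
  opt <- stats::optim(opt$par, score, method = "Nelder-Mead",
                      control = list(maxit = 6000, reltol = 1e-13))
  a <- exp(opt$par)
  ord <- order(a, decreasing = TRUE)
  a <- a[ord]
  solve_shell <- function(l) {
    sf <- shell_fit(a, l)
    c0 <- solve(sf$Sg, sf$v)
    c0 <- c0 / sqrt(drop(crossprod(c0, sf$Sg %*% c0)))
    if (sum(c0 * sf$v) < 0) c0 <- -c0
    list(coef = c0, overlap = sf$overlap)
  }
  s <- solve_shell(0); p <- solve_shell(1)
  list(exponents = a, coef_s = s$coef, coef_p = p$coef,
       overlap_s = s$overlap, overlap_p = p$overlap)
}
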