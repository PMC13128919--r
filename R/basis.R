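## Lobe-function basis construction.
##
## Every basis function in this package is a contraction of s-type
## Gaussian primitives. s orbitals are the standard minimal-basis
## contractions; p orbitals are represented by six displaced s primitives,
## three with coefficient +A displaced by +d along the orbital axis and
## three mirrored with -A, which reproduces the nodal structure without
## Cartesian prefactors. As a result every integral in the code is an
## s-Gaussian integral and a single formula covers all shell pairs.

.basis_env <- new.env(parent = emptyenv())

.basis_file <- function(family) {
  fname <- paste0(tolower(family), ".dat")
  p <- system.file("extdata", "basis", fname, package = "lobehf")
  if (!nzchar(p)) {
    ## during in-source development
    p <- file.path("inst", "extdata", "basis", fname)
  }
  if (!file.exists(p)) stop("no basis tabulation for family ", family)
  p
}

#' Load a reference minimal-basis tabulation
#'
#' Parses the shipped Gaussian-dialect basis tables. Coefficients refer to
#' normalized primitives; contraction renormalization to exact unit
#' self-overlap is applied when a basis is built.
#'
#' @param element element symbol (H, He, C, N, O, S, P).
#' @param family `"STO-3G"` or `"STO-6G"`.
#' @return list of shells; each shell is a list with `type` (`"S"` or
#'   `"SP"`), `n_quantum`, `exponents`, `coef_s` and (for SP) `coef_p`.
#' @examples
#' load_reference_basis("H", "STO-3G")
#' @export
load_reference_basis <- function(element, family = c("STO-3G", "STO-6G")) {
  family <- match.arg(family)
  key <- paste0("ref:", family)
  if (is.null(.basis_env[[key]])) {
    .basis_env[[key]] <- .parse_basis_file(.basis_file(family))
  }
  tab <- .basis_env[[key]]
  if (is.null(tab[[element]])) {
    stop("element ", element, " not available in ", family, " tabulation")
  }
  tab[[element]]
}

.parse_basis_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*!", lines) & nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    el <- hdr[1]
    i <- i + 1L
    shells <- list()
    n_q <- 0L
    while (i <= length(lines) && trimws(lines[i]) != "****") {
      sh <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      type <- sh[1]; nprim <- as.integer(sh[2])
      rows <- do.call(rbind, lapply(lines[(i + 1):(i + nprim)], function(l) {
        as.numeric(strsplit(trimws(gsub("D", "E", l)), "\\s+")[[1]])
      }))
      ## principal quantum number: advances with each s-bearing shell; a
      ## bare P shell belongs to the preceding s shell's n
      if (type != "P") n_q <- n_q + 1L
      shells[[length(shells) + 1L]] <- list(
        type = type, n_quantum = n_q,
        exponents = rows[, 1], coef_s = rows[, 2],
        coef_p = if (ncol(rows) >= 3) rows[, 3] else NULL)
      i <- i + nprim + 1L
    }
    out[[el]] <- shells
    i <- i + 1L
  }
  out
}

## primitive normalization constants
.norm_s <- function(a) (2 * a / pi)^0.75
.norm_p <- function(a) (2 * a / pi)^0.75 * 2 * sqrt(a)

## overlap of two s primitives with unit coefficients
.s_prim_overlap <- function(a, b, d2 = 0) {
  (pi / (a + b))^1.5 * exp(-a * b / (a + b) * d2)
}

## normalized conventional p contraction evaluated as h(r)*x
.ref_p_eval <- function(shell, X, Y, Z) {
  a <- shell$exponents
  c_p <- shell$coef_p %||% shell$coef_s
  cN <- c_p * .norm_p(a)
  ## renormalize the contraction analytically
  S <- outer(a, a, function(ai, aj)
    (pi / (ai + aj))^1.5 / (2 * (ai + aj)))
  nrm <- sqrt(drop(crossprod(cN, S %*% cN)))
  cN <- cN / nrm
  r2 <- X^2 + Y^2 + Z^2
  val <- 0
  for (k in seq_along(a)) val <- val + cN[k] * exp(-a[k] * r2)
  val * X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.lobe_grid <- function(shell, n_grid) {
  L <- 6 / sqrt(min(shell$exponents))
  g <- seq(-L, L, length.out = n_grid)
  ex <- expand.grid(x = g, y = g, z = g)
  list(x = ex$x, y = ex$y, z = ex$z, h3 = diff(g)[1]^3)
}

#' Fit the displaced-lobe representation of a p orbital
#'
#' Approximates a conventional p contraction by six s-type primitives:
#' three with coefficient +A displaced by +d along the orbital axis and
#' three mirrored with -A, where the displacement follows d_a =
#' k/sqrt(alpha_a) with a single dimensionless k shared by the shell (the
#' standard lobe-function construction, which keeps odd parity exact).
#' The exponents and k are optimized by nonlinear least squares on a 3D
#' real-space grid; the coefficients are the exact linear least-squares
#' solution at each step. The fitted contraction is renormalized to unit
#' self-overlap.
#'
#' @param shell a p (or SP) shell from [load_reference_basis()], normally
#'   the STO-6G tabulation (six reference Gaussians).
#' @param n_grid grid points per axis of the fitting cube (half-width
#'   6/sqrt(min exponent)).
#' @return list with `alpha` (3 exponents), `A` (3 positive coefficients,
#'   normalized), `k`, `d` (3 displacements, bohr) and `rel_l2` (relative
#'   L2 error against the reference on the grid).
#' @export
fit_lobe_p_orbital <- function(shell, n_grid = 61L) {
  make_score <- function(g, ref) {
    refnorm <- sqrt(sum(ref^2))
    design <- function(alpha, k) {
      vapply(alpha, function(a) {
        d <- k / sqrt(a)
        exp(-a * ((g$x - d)^2 + g$y^2 + g$z^2)) -
          exp(-a * ((g$x + d)^2 + g$y^2 + g$z^2))
      }, numeric(length(g$x)))
    }
    list(design = design, score = function(par) {
      alpha <- exp(par[1:3]); k <- par[4]
      ## k is bounded away from zero: the k -> 0 derivative limit fits
      ## equally well but needs divergent coefficients, which would eat
      ## precision through signed cancellation in every integral
      if (any(alpha > 1e4) || any(alpha < 1e-4) ||
          k <= 0.02 || any(k / sqrt(alpha) >= 2)) return(1e6)
      B <- design(alpha, k)
      fit <- stats::lm.fit(B, ref)
      sqrt(sum(fit$residuals^2)) / refnorm
    })
  }
  ## coarse exploration on a subsampled grid, then polish on the full grid
  gc_ <- .lobe_grid(shell, 31L)
  sc_coarse <- make_score(gc_, .ref_p_eval(shell, gc_$x, gc_$y, gc_$z))
  g <- .lobe_grid(shell, n_grid)
  ref <- .ref_p_eval(shell, g$x, g$y, g$z)
  sc_full <- make_score(g, ref)
  init_alpha <- sort(shell$exponents, decreasing = TRUE)
  init_alpha <- init_alpha[round(seq(2, length(init_alpha) - 1,
                                     length.out = 3))]
  best <- NULL
  for (k0 in c(0.05, 0.2)) {
    opt <- stats::optim(c(log(init_alpha), k0), sc_coarse$score,
                        method = "Nelder-Mead",
                        control = list(maxit = 1200, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  best <- stats::optim(best$par, sc_full$score, method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-10))
  design <- sc_full$design
  if (best$value > 0.02) {
    stop("lobe fit did not reach the 2% L2 target (got ",
         signif(best$value, 3), ")")
  }
  alpha <- exp(best$par[1:3]); k <- best$par[4]
  B <- design(alpha, k)
  A <- stats::lm.fit(B, ref)$coefficients
  ## enforce positive A with the +d lobe positive along +x
  if (sum(A) < 0) A <- -A
  ord <- order(alpha, decreasing = TRUE)
  alpha <- alpha[ord]; A <- A[ord]
  d <- k / sqrt(alpha)
  ## renormalize: self-overlap of the signed 6-primitive set
  self <- 0
  sgn <- c(1, 1, 1, -1, -1, -1)
  aa <- c(alpha, alpha); cc <- c(A, -A); dd <- c(d, -d)
  for (i in 1:6) for (j in 1:6) {
    self <- self + cc[i] * cc[j] *
      .s_prim_overlap(aa[i], aa[j], (dd[i] - dd[j])^2)
  }
  A <- A / sqrt(self)
  list(alpha = alpha, A = A, k = k, d = d, rel_l2 = best$value)
}

#' Fit the all-positive per-lobe representation of a p orbital
#'
#' For density-relevance screening the integral over the absolute value
#' of a p orbital is needed. The signed displaced-lobe expansion is not
#' usable there (its term-wise absolute values do not reproduce the
#' absolute orbital), so each lobe of the reference p function is
#' represented by all-positive axially symmetric Gaussians
#' exp(-ax (x-x0)^2 - ap (y^2+z^2)); the mirrored lobe carries the
#' opposite sign and offset. The least-squares objective is evaluated
#' entirely from closed-form inner products (no fitting grid): the
#' signed combination (lobe minus mirror) must reproduce the p orbital
#' and the positive sum (lobe plus mirror) its absolute value, which
#' together prevent the lobes from degenerating into an overlapping
#' derivative-like pair, and the analytic norms leave no room for
#' spuriously sharp primitives that a sampled objective cannot see.
#' Four Gaussians per lobe are used: the absolute orbital has a
#' derivative kink at the nodal plane and needs one more primitive than
#' the smooth signed fit. Axial symmetry keeps the representation
#' exactly rotation-covariant.
#'
#' @param shell reference p shell (see [fit_lobe_p_orbital()]).
#' @param lobe optional signed lobe fit (accepted for interface
#'   compatibility; initialization uses a scale-covariant ladder).
#' @param n_grid grid points per axis of the validation grid on which
#'   the reported L1 errors are measured.
#' @param n_prim Gaussians per lobe.
#' @return list with per-primitive positive `A`, `ax` (axial exponent),
#'   `ap` (perpendicular exponent), `x0` (axial offset, bohr), the
#'   relative L2 errors of the signed and absolute reconstructions
#'   (`rel_l2_signed`, `rel_l2_abs`), the validation-grid L1 errors and
#'   the analytic `self_norm_ratio`.
#' @export
fit_abs_lobe_representation <- function(shell, lobe = NULL, n_grid = 41L,
                                        n_prim = 6L) {
  ## the problem is exactly scale-covariant (exponents ~ zeta^2, offsets
  ## ~ 1/zeta, amplitudes ~ zeta^(3/2)); fitting at a canonical scale
  ## and transforming back makes scaled shells give identical-quality
  ## representations and keeps the initialization calibrated
  zhat2 <- stats::median(shell$exponents) / 0.7206
  if (abs(log(zhat2)) > 1e-12) {
    sc <- shell
    sc$exponents <- shell$exponents / zhat2
    q0 <- fit_abs_lobe_representation(sc, lobe = lobe, n_grid = n_grid,
                                      n_prim = n_prim)
    zhat <- sqrt(zhat2)
    q0$ax <- q0$ax * zhat2
    q0$ap <- q0$ap * zhat2
    q0$x0 <- q0$x0 / zhat
    q0$A <- q0$A * zhat^1.5
    return(q0)
  }
  b <- shell$exponents
  cN <- (shell$coef_p %||% shell$coef_s) * .norm_p(b)
  Sref <- outer(b, b, function(bi, bj) (pi / (bi + bj))^1.5 / (2 * (bi + bj)))
  cN <- cN / sqrt(drop(crossprod(cN, Sref %*% cN)))  # <ref|ref> = 1
  erfv <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  unpack <- function(par) {
    prm <- matrix(par, nrow = 4)
    list(A = exp(prm[4, ]), ax = exp(prm[1, ]), ap = exp(prm[2, ]),
         x0 = prm[3, ])
  }
  ## closed-form inner products of axially symmetric Gaussians with each
  ## other, with the reference x-Gaussians, and with their absolute value
  gg <- function(A, ax, ap, u) {
    n <- length(A)
    acc <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      px <- ax[i] + ax[j]
      acc <- acc + A[i] * A[j] * sqrt(pi / px) *
        exp(-ax[i] * ax[j] / px * (u[i] - u[j])^2) * pi / (ap[i] + ap[j])
    }
    acc
  }
  g_ref <- function(A, ax, ap, u, absolute = FALSE) {
    acc <- 0
    for (i in seq_along(A)) for (k in seq_along(b)) {
      p <- ax[i] + b[k]
      cc <- ax[i] * u[i] / p
      pref <- exp(-ax[i] * b[k] * u[i]^2 / p)
      one_d <- if (absolute) {
        exp(-p * cc^2) / p + cc * sqrt(pi / p) * erfv(cc * sqrt(p))
      } else {
        cc * sqrt(pi / p)
      }
      acc <- acc + A[i] * cN[k] * pref * one_d * pi / (ap[i] + b[k])
    }
    acc
  }
  objective <- function(par) {
    q <- unpack(par)
    if (any(!is.finite(unlist(q))) || any(q$ax > 1e5) || any(q$ax < 1e-4) ||
        any(q$ap > 1e5) || any(q$ap < 1e-4) || any(abs(q$x0) > 8)) {
      return(1e6)
    }
    ## signed block: lobes +A at +x0 and -A at -x0
    As <- c(q$A, -q$A); us <- c(q$x0, -q$x0)
    ax2 <- c(q$ax, q$ax); ap2 <- c(q$ap, q$ap)
    obj_signed <- gg(As, ax2, ap2, us) -
      2 * g_ref(As, ax2, ap2, us, absolute = FALSE) + 1
    ## absolute block: the positive sum must reproduce |p|, which pins
    ## the relevance integrals and forbids the overlapping
    ## derivative-pair degeneracy (whose norm diverges)
    Aa <- c(q$A, q$A)
    obj_abs <- gg(Aa, ax2, ap2, us) -
      2 * g_ref(Aa, ax2, ap2, us, absolute = TRUE) + 1
    obj_signed + obj_abs
  }
  ## scale-covariant multistart (exponents ~ zeta^2, offsets ~ 1/zeta,
  ## amplitudes ~ zeta^(3/2)); the reference ladder is calibrated on the
  ## carbon 2p median exponent
  run <- function(t) {
    al <- exp(seq(log(1.6), log(0.12), length.out = n_prim)) * t
    init <- as.numeric(vapply(seq_len(n_prim), function(a) {
      c(log(al[a]), log(al[a]), (0.3 + 0.2 * a) / sqrt(t),
        log(0.5 * t^0.75))
    }, numeric(4)))
    o <- stats::optim(init, objective, method = "Nelder-Mead",
                      control = list(maxit = 8000, reltol = 1e-12))
    stats::optim(o$par, objective, method = "Nelder-Mead",
                 control = list(maxit = 8000, reltol = 1e-12))
  }
  fits <- lapply(c(1, 0.5, 2), run)
  fit <- fits[[which.min(vapply(fits, function(f) f$value, 1))]]
  q <- unpack(fit$par)
  ord <- order(q$ax, decreasing = TRUE)
  q <- lapply(q, `[`, ord)
  ## analytic quality metrics
  As <- c(q$A, -q$A); Aa <- c(q$A, q$A)
  us <- c(q$x0, -q$x0); ax2 <- c(q$ax, q$ax); ap2 <- c(q$ap, q$ap)
  rel_l2_signed <- sqrt(max(
    gg(As, ax2, ap2, us) - 2 * g_ref(As, ax2, ap2, us, FALSE) + 1, 0))
  rel_l2_abs <- sqrt(max(
    gg(Aa, ax2, ap2, us) - 2 * g_ref(Aa, ax2, ap2, us, TRUE) + 1, 0))
  nrm <- gg(Aa, ax2, ap2, us)
  if (abs(nrm - 1) > 0.1) {
    stop("per-lobe fit failed: analytic self-norm off by ",
         signif(100 * (nrm - 1), 3), "%")
  }
  ## validation-grid L1 errors (reported; the optimization is grid-free)
  g <- .lobe_grid(shell, n_grid)
  ref <- .ref_p_eval(shell, g$x, g$y, g$z)
  lob <- function(sgn) {
    v <- 0
    for (a in seq_len(n_prim)) {
      v <- v + q$A[a] * exp(-q$ax[a] * (g$x - sgn * q$x0[a])^2 -
                              q$ap[a] * (g$y^2 + g$z^2))
    }
    v
  }
  m1 <- lob(1); m2 <- lob(-1)
  c(q, list(rel_l2_signed = rel_l2_signed, rel_l2_abs = rel_l2_abs,
            rel_l1_signed = sum(abs((m1 - m2) - ref)) / sum(abs(ref)),
            rel_l1_abs = sum(abs(abs(m1 - m2) - abs(ref))) / sum(abs(ref)),
            self_norm_ratio = nrm))
}

#' Displaced-lobe representation by primitive splitting
#'
#' Builds the six-primitive lobe set for a p shell by splitting each of
#' its Cartesian primitives x exp(-alpha r^2) into a mirrored pair of s
#' primitives +/-A exp(-alpha |r -/+ d e|^2) with d = k/sqrt(alpha) and
#' A chosen so the pair reproduces the primitive to leading order in k
#' (exactly: the pair equals 2 A e^(-alpha d^2) e^(-alpha r^2)
#' sinh(2 alpha d x), which approaches the Cartesian primitive as k ->
#' 0 with relative error O(k^2)). The contraction is renormalized to
#' exact unit self-overlap. This deterministic construction inherits the
#' tabulated exponents and coefficients of the shell, so the basis
#' deviates from its conventional counterpart only at O(k^2); it is the
#' default energy representation of p shells.
#'
#' @param shell an SP or P shell from [load_reference_basis()].
#' @param k dimensionless displacement parameter (default 0.03: small
#'   enough for sub-mHa fidelity, large enough that the signed
#'   amplitudes stay O(10) and no precision is lost to cancellation).
#' @return list with `alpha`, `A`, `d`, `k` as in
#'   [fit_lobe_p_orbital()].
#' @export
split_p_shell <- function(shell, k = 0.03) {
  stopifnot(!is.null(shell$coef_p) || shell$type != "S")
  alpha <- shell$exponents
  cp <- shell$coef_p %||% shell$coef_s
  cN <- cp * .norm_p(alpha)
  d <- k / sqrt(alpha)
  A <- cN / (4 * alpha * d)
  if (sum(A) < 0) A <- -A
  aa <- c(alpha, alpha); cc <- c(A, -A); dd <- c(d, -d)
  self <- 0
  for (i in seq_along(aa)) for (j in seq_along(aa)) {
    self <- self + cc[i] * cc[j] *
      .s_prim_overlap(aa[i], aa[j], (dd[i] - dd[j])^2)
  }
  list(alpha = alpha, A = A / sqrt(self), d = d, k = k)
}

## ---- lobe parameter cache -------------------------------------------------

.lobe_table_path <- function() {
  p <- system.file("extdata", "basis", "lobes.dat", package = "lobehf")
  if (!nzchar(p)) p <- file.path("inst", "extdata", "basis", "lobes.dat")
  p
}

## fitted lobe parameters, keyed by element + principal quantum number;
## read from the versioned on-disk table (generated by the fitting code
## above), fitted on the fly for entries not present
get_lobe_params <- function(element, n_quantum) {
  key <- sprintf("lobe:%s:%d", element, n_quantum)
  if (!is.null(.basis_env[[key]])) return(.basis_env[[key]])
  tabp <- .lobe_table_path()
  if (file.exists(tabp)) {
    tab <- utils::read.table(tabp, header = TRUE, stringsAsFactors = FALSE)
    row <- tab[tab$element == element & tab$n_quantum == n_quantum, ]
    if (nrow(row) == 1) {
      res <- list(
        lobe = list(alpha = as.numeric(row[paste0("alpha", 1:3)]),
                    A = as.numeric(row[paste0("A", 1:3)]),
                    k = row$k,
                    d = row$k / sqrt(as.numeric(row[paste0("alpha", 1:3)]))),
        abs = local({
          nn <- sum(grepl("^absA[0-9]+$", names(tab)))
          list(A = as.numeric(row[paste0("absA", seq_len(nn))]),
               ax = as.numeric(row[paste0("absax", seq_len(nn))]),
               ap = as.numeric(row[paste0("absap", seq_len(nn))]),
               x0 = as.numeric(row[paste0("absx0", seq_len(nn))]))
        }))
      .basis_env[[key]] <- res
      return(res)
    }
  }
  ## fall back to fitting now (uses the STO-6G reference tabulation)
  shells <- load_reference_basis(element, "STO-6G")
  sh <- Filter(function(s) s$n_quantum == n_quantum && s$type != "S", shells)
  if (!length(sh)) stop("no p shell with n=", n_quantum, " for ", element)
  lobe <- fit_lobe_p_orbital(sh[[1]])
  absr <- fit_abs_lobe_representation(sh[[1]], lobe)
  res <- list(lobe = lobe, abs = absr)
  .basis_env[[key]] <- res
  res
}

## ---- basis construction ---------------------------------------------------

#' Build the lobe-function basis for a molecular system
#'
#' Constructs the full minimal basis: per atom, s shells as standard
#' contractions of co-centered s primitives and p shells as displaced
#' six-primitive lobe sets (see [fit_lobe_p_orbital()]). Function order is
#' atom-major with shell order 1s, 2s, 2p_x, 2p_y, 2p_z (then 3s, 3p for
#' third-row elements). All centers are stored in bohr; every contraction
#' is renormalized to exact unit self-overlap.
#'
#' @param system a [molecular_system()].
#' @param family `"STO-3G"` (default) or `"STO-6G"` for the s shells; p
#'   shells always use the six-lobe expansion fitted against the STO-6G
#'   reference (the construction that corresponds to STO-3G accuracy).
#' @param axes 3x3 rotation matrix whose rows are the global directions of
#'   the p lobes (default identity). Rotating a molecule and passing the
#'   same rotation here leaves all energies invariant.
#' @return an object of class `lobe_basis`.
#' @export
build_basis <- function(system, family = "STO-3G", axes = diag(3)) {
  pos <- positions(system, "bohr")
  fn_atom <- integer(0); fn_label <- character(0); fn_valence <- logical(0)
  prim_coef <- numeric(0); prim_alpha <- numeric(0)
  prim_center <- matrix(numeric(0), 0, 3); prim_fn <- integer(0)
  rel_A <- numeric(0); rel_M <- matrix(numeric(0), 0, 6)
  rel_center <- matrix(numeric(0), 0, 3); rel_fn <- integer(0)
  nfn <- 0L

  add_fn <- function(atom, label, valence, coef, alpha, centers,
                     relA, relM, relC) {
    nfn <<- nfn + 1L
    fn_atom <<- c(fn_atom, atom); fn_label <<- c(fn_label, label)
    fn_valence <<- c(fn_valence, valence)
    prim_coef <<- c(prim_coef, coef); prim_alpha <<- c(prim_alpha, alpha)
    prim_center <<- rbind(prim_center, centers)
    prim_fn <<- c(prim_fn, rep(nfn, length(coef)))
    rel_A <<- c(rel_A, relA); rel_M <<- rbind(rel_M, relM)
    rel_center <<- rbind(rel_center, relC)
    rel_fn <<- c(rel_fn, rep(nfn, length(relA)))
  }

  for (ia in seq_len(n_atoms(system))) {
    el <- system$atoms$element[ia]
    shells <- load_reference_basis(el, family)
    nmax <- max(vapply(shells, `[[`, 0L, "n_quantum"))
    for (sh in shells) {
      valence <- sh$n_quantum == nmax
      a <- sh$exponents
      if (sh$type %in% c("S", "SP")) {
        cs <- sh$coef_s * .norm_s(a)
        S <- sum(outer(cs, cs) * outer(a, a, function(x, y) .s_prim_overlap(x, y)))
        cs <- cs / sqrt(S)
        add_fn(ia, paste0(sh$n_quantum, "s"), valence,
               cs, a, matrix(pos[ia, ], length(a), 3, byrow = TRUE),
               relA = abs(cs),
               relM = cbind(a, a, a, 0, 0, 0),
               relC = matrix(pos[ia, ], length(a), 3, byrow = TRUE))
      }
      ## p part
      if (sh$type == "SP" || sh$type == "P") {
        lp <- get_lobe_params(el, sh$n_quantum)
        ## energy representation: for three-primitive tabulations the
        ## deterministic primitive-splitting construction (six lobes,
        ## O(k^2)-exact); wider contractions use the fitted six-lobe set
        ## so every p function keeps n_G = 6
        sig <- if (length(sh$exponents) == 3) split_p_shell(sh) else lp$lobe
        for (ax_i in 1:3) {
          e <- axes[ax_i, ]
          coef <- c(sig$A, -sig$A)
          alpha <- c(sig$alpha, sig$alpha)
          offs <- rbind(outer(sig$d, e), outer(-sig$d, e))
          centers <- sweep(offs, 2, pos[ia, ], `+`)
          ## relevance representation: two mirrored all-positive lobes
          relA <- c(lp$abs$A, lp$abs$A)
          axv <- c(lp$abs$ax, lp$abs$ax); apv <- c(lp$abs$ap, lp$abs$ap)
          M <- t(vapply(seq_along(axv), function(q) {
            Mm <- apv[q] * diag(3) + (axv[q] - apv[q]) * tcrossprod(e)
            c(Mm[1, 1], Mm[2, 2], Mm[3, 3], Mm[1, 2], Mm[1, 3], Mm[2, 3])
          }, numeric(6)))
          relC <- sweep(rbind(outer(lp$abs$x0, e), outer(-lp$abs$x0, e)),
                        2, pos[ia, ], `+`)
          add_fn(ia, sprintf("%dp%s", sh$n_quantum, c("x", "y", "z")[ax_i]),
                 valence, coef, alpha, centers, relA, M, relC)
        }
      }
    }
  }
  fn_ptr <- c(0L, cumsum(tabulate(prim_fn, nfn)))
  rel_ptr <- c(0L, cumsum(tabulate(rel_fn, nfn)))
  structure(list(
    family = family, n_bf = nfn,
    fn = data.frame(atom = fn_atom, label = fn_label, valence = fn_valence,
                    stringsAsFactors = FALSE),
    prim_coef = prim_coef, prim_alpha = prim_alpha,
    prim_center = prim_center, prim_fn = prim_fn, fn_ptr = fn_ptr,
    rel_A = rel_A, rel_M = rel_M, rel_center = rel_center,
    rel_ptr = rel_ptr,
    atom_pos = pos, atom_z = system$atoms$z, axes = axes
  ), class = "lobe_basis")
}

#' @export
print.lobe_basis <- function(x, ...) {
  cat(sprintf("<lobe_basis> %s: %d functions, %d primitives over %d atoms\n",
              x$family, x$n_bf, length(x$prim_coef), nrow(x$atom_pos)))
  invisible(x)
}

#' Number of basis functions for an element composition
#'
#' @param counts named integer vector of element counts, e.g.
#'   `c(C = 40, H = 56)`.
#' @return total number of contracted basis functions in the minimal
#'   basis (H/He: 1; C/N/O: 5; S/P: 9).
#' @export
count_basis_functions <- function(counts) {
  per <- c(H = 1L, He = 1L, C = 5L, N = 5L, O = 5L, S = 9L, P = 9L)
  bad <- setdiff(names(counts), names(per))
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  sum(per[names(counts)] * as.integer(counts))
}
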