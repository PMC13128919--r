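## Deterministic synthetic-structure generators. Every downstream module
## (basis, SCF, divide-and-conquer, spectra, dynamics) is exercised on
## these fixtures, so no structure download is ever required for testing.
## All geometries are idealized textbook geometries; all stochastic
## placement is reproducible from an integer seed.

.rigid_water_geom <- function(r_oh = 0.9572, angle = 104.52) {
  ## rigid three-site water geometry (r(OH), HOH angle as in TIP3P)
  a <- (angle / 2) * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = c(r_oh * sin(a), 0, r_oh * cos(a)),
        H2 = c(-r_oh * sin(a), 0, r_oh * cos(a)))
}

.rot2 <- function(theta) {
  t <- theta * pi / 180
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

## uniform random 3D rotation matrix (uses the current RNG stream)
.random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Idealized small-molecule fixtures
#'
#' Deterministic textbook geometries for a handful of closed-shell
#' molecules; coordinates in Angstrom.
#'
#' @param name one of `"H2"`, `"He"`, `"H2O"`, `"CH4"`, `"NH3"`,
#'   `"C2H4"`, `"C6H6"`.
#' @return a [molecular_system()].
#' @examples
#' make_named_small("H2O")
#' @export
make_named_small <- function(name) {
  b <- bohr_to_ang(1.4)  # H2 bond, the standard minimal-basis test distance
  sys <- switch(
    name,
    H2 = molecular_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, b))),
    He = molecular_system("He", matrix(0, 1, 3)),
    H2O = {
      a <- (104.5 / 2) * pi / 180; r <- 0.958
      molecular_system(c("O", "H", "H"),
                       rbind(c(0, 0, 0),
                             c(r * sin(a), 0, r * cos(a)),
                             c(-r * sin(a), 0, r * cos(a))))
    },
    CH4 = {
      r <- 1.087; s <- r / sqrt(3)
      molecular_system(c("C", "H", "H", "H", "H"),
                       rbind(c(0, 0, 0), c(s, s, s), c(s, -s, -s),
                             c(-s, s, -s), c(-s, -s, s)))
    },
    NH3 = {
      r <- 1.012; ang <- 106.7 * pi / 180
      ## pyramidal: three H on a cone around z
      cosb <- cos(ang); u <- (1 - cosb) * 2 / 3  # 1 - cos(angle between projections)=...
      ## solve H-N-H angle: place H at polar angle t: cos(ang)=cos^2? do directly
      t <- acos(sqrt((1 + 2 * cosb) / 3))  # polar angle from -z axis
      ph <- c(0, 2, 4) * pi / 3
      molecular_system(c("N", "H", "H", "H"),
                       rbind(c(0, 0, 0),
                             t(vapply(ph, function(p)
                               r * c(sin(t) * cos(p), sin(t) * sin(p), -cos(t)),
                               numeric(3)))))
    },
    C2H4 = {
      rcc <- 1.339; rch <- 1.087; ang <- 121.3
      C1 <- c(0, 0); C2 <- c(rcc, 0)
      hs <- list(C1 + rch * drop(.rot2(ang) %*% c(1, 0)),
                 C1 + rch * drop(.rot2(-ang) %*% c(1, 0)),
                 C2 + rch * drop(.rot2(ang) %*% c(-1, 0)),
                 C2 + rch * drop(.rot2(-ang) %*% c(-1, 0)))
      xy <- rbind(C1, C2, do.call(rbind, hs))
      molecular_system(c("C", "C", rep("H", 4)), cbind(xy, 0))
    },
    C6H6 = {
      rcc <- 1.39; rch <- 1.09
      th <- (0:5) * pi / 3
      C <- cbind(rcc * cos(th), rcc * sin(th), 0)
      H <- cbind((rcc + rch) * cos(th), (rcc + rch) * sin(th), 0)
      molecular_system(rep(c("C", "H"), each = 6), rbind(C, H))
    },
    stop("unknown fixture name: ", name)
  )
  sys$label <- name
  sys
}

#' Random rigid-water cluster
#'
#' `n` rigid waters placed with random positions and orientations such
#' that all O-O distances are at least 2.5 Angstrom; reproducible from the
#' seed.
#'
#' @param n number of waters (>= 1).
#' @param seed integer RNG seed.
#' @param oo_min minimum O-O distance (Angstrom).
#' @param max_tries placement attempts per water before giving up.
#' @return a [molecular_system()].
#' @export
make_water_cluster <- function(n, seed = 1L, oo_min = 2.5, max_tries = 2000L) {
  stopifnot(n >= 1)
  w <- .rigid_water_geom()
  ## box edge from a loose liquid-like density so packing succeeds easily
  edge <- max(4, (n * 30)^(1 / 3) + 2)
  with_seed(seed, {
    ocenters <- matrix(numeric(0), 0, 3)
    blocks <- list()
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        o <- stats::runif(3, 0, edge)
        if (nrow(ocenters) == 0 ||
            min(sqrt(colSums((t(ocenters) - o)^2))) >= oo_min) {
          R <- .random_rotation()
          blocks[[i]] <- sweep(w %*% t(R), 2, o, `+`)
          ocenters <- rbind(ocenters, o)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("water-cluster packing failed after placing ",
                        i - 1L, " of ", n, " waters")
    }
    xyz <- do.call(rbind, blocks)
    xyz <- sweep(xyz, 2, colMeans(xyz))
    molecular_system(rep(c("O", "H", "H"), n), xyz,
                     label = sprintf("water cluster n=%d seed=%d", n, seed))
  })
}

#' Add a shell of explicit water around a solute
#'
#' Emulates the "solvation shell" protocol: rigid waters are placed so
#' that each oxygen lies within `thickness` of at least one solute atom,
#' with no heavy-atom clash below `clash` and no O-O contact below 2.5
#' Angstrom. Solute atoms come first in the output ordering.
#'
#' @param solute a [molecular_system()].
#' @param thickness shell thickness in Angstrom (> 0).
#' @param seed integer RNG seed.
#' @param clash minimum heavy-atom distance to the solute (Angstrom).
#' @param n_candidates number of random candidate placements examined.
#' @return a [molecular_system()] with the solute first, then the waters.
#' @export
make_water_shell <- function(solute, thickness, seed = 1L, clash = 2.2,
                             n_candidates = 4000L) {
  stopifnot(thickness > 0)
  sx <- positions(solute)
  w <- .rigid_water_geom()
  lo <- apply(sx, 2, min) - thickness
  hi <- apply(sx, 2, max) + thickness
  heavy <- sx[solute$atoms$z > 1, , drop = FALSE]
  if (nrow(heavy) == 0) heavy <- sx
  with_seed(seed, {
    ocenters <- matrix(numeric(0), 0, 3)
    blocks <- list()
    for (k in seq_len(n_candidates)) {
      o <- stats::runif(3, lo, hi)
      dsol <- sqrt(colSums((t(sx) - o)^2))
      if (min(dsol) > thickness) next
      if (min(sqrt(colSums((t(heavy) - o)^2))) < clash) next
      if (nrow(ocenters) > 0 &&
          min(sqrt(colSums((t(ocenters) - o)^2))) < 2.5) next
      R <- .random_rotation()
      blocks[[length(blocks) + 1L]] <- sweep(w %*% t(R), 2, o, `+`)
      ocenters <- rbind(ocenters, o)
    }
    nw <- length(blocks)
    xyz <- rbind(sx, do.call(rbind, blocks))
    molecular_system(c(solute$atoms$element, rep(c("O", "H", "H"), nw)), xyz,
                     net_charge = solute$net_charge,
                     label = sprintf("%s + %d-water shell", solute$label, nw))
  })
}

#' All-trans polyene chain
#'
#' Planar conjugated C2nH2n+2 chain with alternating double (1.35
#' Angstrom) and single (1.46 Angstrom) carbon-carbon bonds; a desk-scale
#' stand-in for long conjugated chromophores such as beta-carotene.
#'
#' @param n_units number of C2H2 units (>= 1); `n_units = 1` gives an
#'   ethene-like C2H4.
#' @param r_double,r_single,r_ch bond lengths in Angstrom.
#' @return a [molecular_system()].
#' @export
make_polyene <- function(n_units, r_double = 1.35, r_single = 1.46,
                         r_ch = 1.09) {
  stopifnot(n_units >= 1)
  nc <- 2L * n_units
  C <- matrix(0, nc, 2)
  for (i in seq_len(nc - 1)) {
    len <- if (i %% 2 == 1) r_double else r_single
    ang <- if (i %% 2 == 1) 30 else -30
    d <- drop(.rot2(ang) %*% c(1, 0))
    C[i + 1, ] <- C[i, ] + len * d
  }
  H <- list()
  for (i in seq_len(nc)) {
    nbr <- list()
    if (i > 1) nbr <- c(nbr, list(C[i - 1, ] - C[i, ]))
    if (i < nc) nbr <- c(nbr, list(C[i + 1, ] - C[i, ]))
    nbr <- lapply(nbr, function(v) v / sqrt(sum(v^2)))
    if (length(nbr) == 2) {
      d <- -(nbr[[1]] + nbr[[2]]); d <- d / sqrt(sum(d^2))
      H[[length(H) + 1L]] <- C[i, ] + r_ch * d
    } else {
      d <- -nbr[[1]]  # outward along the chain
      for (s in c(120, -120)) {
        H[[length(H) + 1L]] <- C[i, ] + r_ch * drop(.rot2(s) %*% (-d))
      }
    }
  }
  xy <- rbind(C, do.call(rbind, H))
  molecular_system(c(rep("C", nc), rep("H", nc + 2)), cbind(xy, 0),
                   label = sprintf("all-trans C%dH%d polyene", nc, nc + 2))
}

#' Capped polyglycine chain in extended conformation
#'
#' An ACE/NME-capped all-glycine peptide (CH3CO-(NHCH2CO)n-NHCH3) built in
#' an idealized extended (all-trans) conformation; always has an even
#' electron count at net charge zero. The test substrate for
#' divide-and-conquer peptide-fragment calculations.
#'
#' @param n_res number of glycine residues (>= 1).
#' @param seed accepted for interface uniformity; the builder is fully
#'   deterministic and ignores it.
#' @return a [molecular_system()] with residue metadata.
#' @export
make_peptide_chain <- function(n_res, seed = 1L) {
  stopifnot(n_res >= 1)
  ## idealized internal coordinates (Angstrom / degrees)
  b_cn <- 1.33; b_nca <- 1.46; b_cac <- 1.52; b_co <- 1.23
  b_ch <- 1.09; b_nh <- 1.01
  a_ccn <- 114; a_cnca <- 121; a_ncac <- 110
  el <- character(0); xyz <- matrix(numeric(0), 0, 3)
  res_name <- character(0); res_seq <- integer(0); atom_name <- character(0)
  add <- function(e, p, an, rn, rs) {
    el <<- c(el, e); xyz <<- rbind(xyz, p)
    atom_name <<- c(atom_name, an); res_name <<- c(res_name, rn)
    res_seq <<- c(res_seq, rs)
  }
  nrm <- function(v) v / sqrt(sum(v^2))
  ## planar backbone zigzag: each new bond turns by (180 - angle) with
  ## alternating sense; substituents follow trigonal/tetrahedral rules
  theta <- 0; sgn <- 1
  step <- function(from, len, angle) {
    theta <<- theta + sgn * (180 - angle)
    sgn <<- -sgn
    from + len * c(cos(theta * pi / 180), sin(theta * pi / 180), 0)
  }
  ## trigonal substituent: opposite the two existing neighbors, in plane
  trig <- function(center, nb1, nb2, len) {
    d <- -(nrm(nb1 - center) + nrm(nb2 - center))
    center + len * nrm(d)
  }
  ## two tetrahedral hydrogens completing an sp3 center
  tetra2 <- function(center, nb1, nb2, len) {
    b <- -(nrm(nb1 - center) + nrm(nb2 - center))
    b <- nrm(b)
    p <- nrm(cross3(nrm(nb1 - center), nrm(nb2 - center)))
    a <- 53.5 * pi / 180
    list(center + len * (b * cos(a) + p * sin(a)),
         center + len * (b * cos(a) - p * sin(a)))
  }
  ## methyl tripod off a single neighbor direction
  methyl <- function(center, nb, len) {
    u <- nrm(nb - center)
    q1 <- nrm(if (abs(u[3]) < 0.9) cross3(u, c(0, 0, 1))
              else cross3(u, c(1, 0, 0)))
    q2 <- cross3(u, q1)
    lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
      center + len * (-u * 0.33381 + 0.94264 * (q1 * cos(phi) + q2 * sin(phi)))
    })
  }
  ## ACE: CH3 - C(=O); backbone first, substituents once neighbors exist
  ch3 <- c(0, 0, 0)
  cpos <- ch3 + b_cac * c(1, 0, 0)
  add("C", ch3, "CH3", "ACE", 0L)
  for (h in methyl(ch3, cpos, b_ch)) add("H", h, "H", "ACE", 0L)
  add("C", cpos, "C", "ACE", 0L)
  i_c <- length(el)  # index of the current carbonyl carbon
  prev_for_c <- ch3  # its backbone predecessor
  for (r in seq_len(n_res + 1L)) {
    is_nme <- r == n_res + 1L
    rn <- if (is_nme) "NME" else "GLY"
    npos <- step(cpos, b_cn, a_ccn)
    ## carbonyl O of the preceding C, trigonal against both neighbors
    add("O", trig(cpos, prev_for_c, npos, b_co), "O",
        res_name[i_c], res_seq[i_c])
    add("N", npos, "N", rn, r)
    ca <- step(npos, b_nca, a_cnca)
    add("H", trig(npos, cpos, ca, b_nh), "H", rn, r)
    if (is_nme) {
      add("C", ca, "CH3", rn, r)
      for (h in methyl(ca, npos, b_ch)) add("H", h, "H", rn, r)
      break
    }
    add("C", ca, "CA", rn, r)
    cnew <- step(ca, b_cac, a_ncac)
    for (h in tetra2(ca, npos, cnew, b_ch)) add("H", h, "HA", rn, r)
    add("C", cnew, "C", rn, r)
    prev_for_c <- ca
    i_c <- length(el)
    cpos <- cnew
  }
  molecular_system(el, xyz, label = sprintf("ACE-(GLY)%d-NME extended", n_res),
                   meta = data.frame(atom_name = atom_name,
                                     res_name = res_name, res_seq = res_seq,
                                     stringsAsFactors = FALSE))
}

## 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
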