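## Divide-and-conquer: spatial partitioning into core regions, buffered
## clusters with chemically informed hydrogen capping, independent
## per-cluster SCF (processed sequentially, bounding peak memory), and
## interpolation of the cluster density matrices into a global density.

## double-bond distance thresholds (Angstrom) by element pair
.double_bond_max <- list("C|C" = 1.40, "C|O" = 1.28, "O|C" = 1.28,
                         "C|N" = 1.32, "N|C" = 1.32)

#' Detect covalent bonds from interatomic distances
#'
#' Atom pairs within 1.3x the sum of their covalent radii count as
#' bonded; bonds shorter than an element-pair threshold (C-C 1.40, C-O
#' 1.28, C-N 1.32 Angstrom) are classified as double bonds for the
#' capping rules.
#'
#' @param system a [molecular_system()].
#' @return data.frame with columns `a`, `b` (atom indices), `d`
#'   (distance, Angstrom) and `double`.
#' @export
detect_bonds <- function(system) {
  pos <- positions(system)
  n <- n_atoms(system)
  rc <- element_rcov(system$atoms$element)
  out <- list()
  for (a in seq_len(n - 1)) {
    d <- sqrt(colSums((t(pos[(a + 1):n, , drop = FALSE]) - pos[a, ])^2))
    cut <- 1.3 * (rc[a] + rc[(a + 1):n])
    hit <- which(d <= cut)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(a = a, b = a + hit, d = d[hit])
    }
  }
  if (!length(out)) {
    return(data.frame(a = integer(0), b = integer(0), d = numeric(0),
                      double = logical(0)))
  }
  bonds <- do.call(rbind, out)
  key <- paste(system$atoms$element[bonds$a], system$atoms$element[bonds$b],
               sep = "|")
  thr <- vapply(key, function(k) {
    v <- .double_bond_max[[k]]
    if (is.null(v)) -Inf else v
  }, numeric(1))
  bonds$double <- bonds$d < thr
  bonds
}

.new_cluster <- function(id, core) {
  list(id = id, core = sort(core), buffer = integer(0),
       caps = data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                         parent_in = integer(0), parent_out = integer(0)),
       charge = 0L, centroid = NULL, cell = NULL)
}

#' Partition a system with k-means clustering of atom positions
#'
#' Seeded k-means++ initialization followed by Lloyd iterations to an
#' assignment fixpoint; the final assignments are the cluster cores.
#' Suited to heterogeneous systems with empty regions.
#'
#' @param system a [molecular_system()].
#' @param k number of clusters (1 <= k <= atom count).
#' @param seed integer RNG seed.
#' @return a `partition` object (cores only; see [build_buffer()]).
#' @export
partition_kmeans <- function(system, k, seed = 1L) {
  stopifnot(k >= 1, k <= n_atoms(system))
  pos <- positions(system)
  run <- function(seed) {
    with_seed(seed, {
      ## k-means++ seeding
      centers <- matrix(0, k, 3)
      centers[1, ] <- pos[sample.int(nrow(pos), 1), ]
      if (k > 1) {
        for (j in 2:k) {
          d2 <- apply(pos, 1, function(p) {
            min(colSums((t(centers[1:(j - 1), , drop = FALSE]) - p)^2))
          })
          centers[j, ] <- pos[sample.int(nrow(pos), 1, prob = pmax(d2, 1e-12)), ]
        }
      }
      stats::kmeans(pos, centers = centers, iter.max = 200L,
                    algorithm = "Lloyd")
    })
  }
  km <- tryCatch(suppressWarnings(run(seed)), error = function(e) NULL)
  if (is.null(km) || length(unique(km$cluster)) < k) {
    km <- tryCatch(suppressWarnings(run(seed + 1L)), error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < k) {
      stop("k-means produced an empty cluster even after re-seeding")
    }
  }
  clusters <- lapply(seq_len(k), function(j) {
    cl <- .new_cluster(j, which(km$cluster == j))
    cl$centroid <- km$centers[j, ]
    cl
  })
  structure(list(method = "kmeans", params = list(k = k, seed = seed),
                 clusters = clusters, system = system),
            class = "partition")
}

#' Partition a system on a uniform 3D grid
#'
#' Axis-aligned cells of the given edge anchored at the bounding-box
#' minimum; atoms are assigned by half-open intervals (an atom exactly on
#' a boundary goes to the higher cell); empty cells are dropped. Suited
#' to homogeneous systems such as solvated complexes.
#'
#' @param system a [molecular_system()].
#' @param cell_edge_A cell edge in Angstrom (default 12.5, the standard
#'   central-region size).
#' @return a `partition` object.
#' @export
partition_grid <- function(system, cell_edge_A = 12.5) {
  stopifnot(cell_edge_A > 0)
  pos <- positions(system)
  lo <- apply(pos, 2, min)
  idx <- floor(sweep(pos, 2, lo) / cell_edge_A)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  cells <- split(seq_len(nrow(pos)), key)
  clusters <- lapply(seq_along(cells), function(j) {
    cl <- .new_cluster(j, cells[[j]])
    ci <- as.numeric(strsplit(names(cells)[j], " ")[[1]])
    cl$cell <- list(index = ci, lo = lo + ci * cell_edge_A,
                    hi = lo + (ci + 1) * cell_edge_A)
    cl$centroid <- lo + (ci + 0.5) * cell_edge_A
    cl
  })
  structure(list(method = "grid",
                 params = list(cell_edge_A = cell_edge_A, origin = lo),
                 clusters = clusters, system = system),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  sizes <- vapply(x$clusters, function(c) length(c$core), 1L)
  cat(sprintf("<partition> %s: %d clusters, core sizes %s\n", x$method,
              length(x$clusters), paste(sizes, collapse = "/")))
  invisible(x)
}

#' Add a buffer region to a cluster
#'
#' The buffer contains every atom within `thickness_A` of any core atom
#' (excluding the core itself); afterwards cut covalent bonds are
#' repaired by [cap_cut_bonds()].
#'
#' @param cluster a cluster from a `partition`.
#' @param system the full [molecular_system()].
#' @param thickness_A buffer thickness in Angstrom (typically 8-10).
#' @param bonds optional precomputed bond table from [detect_bonds()].
#' @return the cluster with `buffer` and `caps` filled in.
#' @export
build_buffer <- function(cluster, system, thickness_A = 8, bonds = NULL) {
  stopifnot(thickness_A > 0)
  pos <- positions(system)
  core <- cluster$core
  d2min <- rep(Inf, nrow(pos))
  for (a in core) {
    d2 <- rowSums(sweep(pos, 2, pos[a, ])^2)
    d2min <- pmin(d2min, d2)
  }
  cluster$buffer <- setdiff(which(d2min <= thickness_A^2), core)
  cap_cut_bonds(cluster, system, bonds = bonds)
}

#' Repair cut covalent bonds at cluster boundaries
#'
#' Bonds are detected from interatomic distances (1.3x the sum of
#' covalent radii). When the cluster boundary intersects a double bond
#' (classified by element-pair distance thresholds), both bonded atoms
#' are pulled into the cluster, iterated to a fixpoint. A cut single
#' bond is terminated by replacing the outside atom with a hydrogen
#' placed along the former bond at the typical X-H length for the inside
#' atom's element.
#'
#' @param cluster cluster with core and buffer set.
#' @param system the full [molecular_system()].
#' @param bonds optional precomputed bond table.
#' @return the cluster with caps attached; errors if the capped cluster
#'   would have an odd electron count.
#' @export
cap_cut_bonds <- function(cluster, system, bonds = NULL) {
  if (is.null(bonds)) bonds <- detect_bonds(system)
  pos <- positions(system)
  inside <- sort(c(cluster$core, cluster$buffer))
  ## pull in atoms across cut double bonds, to fixpoint
  repeat {
    isin <- logical(n_atoms(system)); isin[inside] <- TRUE
    cutdb <- bonds$double & xor(isin[bonds$a], isin[bonds$b])
    if (!any(cutdb)) break
    pull <- unique(c(bonds$a[cutdb][!isin[bonds$a[cutdb]]],
                     bonds$b[cutdb][!isin[bonds$b[cutdb]]]))
    inside <- sort(c(inside, pull))
  }
  cluster$buffer <- setdiff(inside, cluster$core)
  ## cap cut single bonds
  isin <- logical(n_atoms(system)); isin[inside] <- TRUE
  cut <- which(!bonds$double & xor(isin[bonds$a], isin[bonds$b]))
  caps <- lapply(cut, function(q) {
    a <- bonds$a[q]; b <- bonds$b[q]
    if (!isin[a]) { tmp <- a; a <- b; b <- tmp }  # a inside, b outside
    u <- pos[b, ] - pos[a, ]
    u <- u / sqrt(sum(u^2))
    len <- .xh_bond_length[[system$atoms$element[a]]]
    if (is.null(len) || is.na(len)) len <- 1.09
    p <- pos[a, ] + len * u
    data.frame(x = p[1], y = p[2], z = p[3], parent_in = a, parent_out = b)
  })
  cluster$caps <- if (length(caps)) do.call(rbind, caps) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               parent_in = integer(0), parent_out = integer(0))
  ne <- sum(system$atoms$z[inside]) + nrow(cluster$caps) - cluster$charge
  if (ne %% 2 != 0) {
    stop("cluster ", cluster$id, " has an odd electron count (", ne,
         ") after capping")
  }
  cluster
}

#' Assemble a cluster's capped subsystem
#' @param cluster a capped cluster.
#' @param system the full [molecular_system()].
#' @return list with `system` (the subsystem; cluster atoms first, cap
#'   hydrogens last) and `map` (global atom index per subsystem atom, NA
#'   for caps).
#' @export
cluster_system <- function(cluster, system) {
  idx <- sort(c(cluster$core, cluster$buffer))
  pos <- positions(system)
  el <- c(system$atoms$element[idx], rep("H", nrow(cluster$caps)))
  xyz <- rbind(pos[idx, , drop = FALSE],
               as.matrix(cluster$caps[, c("x", "y", "z")]))
  sub <- molecular_system(el, xyz, net_charge = cluster$charge,
                          label = sprintf("cluster %d", cluster$id),
                          is_cap_hydrogen = c(rep(FALSE, length(idx)),
                                              rep(TRUE, nrow(cluster$caps))))
  list(system = sub, map = c(idx, rep(NA_integer_, nrow(cluster$caps))))
}

#' Run SCF on every cluster of a partition, sequentially
#'
#' Clusters are buffered, capped and solved one at a time (peak memory is
#' bounded by the largest cluster). Failures are recorded and the run
#' continues.
#'
#' @param partition a `partition`.
#' @param buffer_A buffer thickness in Angstrom.
#' @param family basis family.
#' @param screening a [screening_config()].
#' @param scf an [scf_config()].
#' @return list with per-cluster results (`cluster`, `map`, `state`) in
#'   cluster-id order and a `failed` index vector.
#' @export
run_clusters <- function(partition, buffer_A = 8, family = "STO-3G",
                         screening = screening_config(),
                         scf = scf_config()) {
  system <- partition$system
  bonds <- detect_bonds(system)
  results <- vector("list", length(partition$clusters))
  failed <- integer(0)
  for (j in seq_along(partition$clusters)) {
    cl <- build_buffer(partition$clusters[[j]], system, buffer_A,
                       bonds = bonds)
    cs <- cluster_system(cl, system)
    st <- tryCatch(
      scf_solve(cs$system, basis = build_basis(cs$system, family),
                screening = screening, scf = scf),
      error = function(e) e)
    if (inherits(st, "error") || !st$converged) failed <- c(failed, j)
    results[[j]] <- list(cluster = cl, map = cs$map,
                         state = if (inherits(st, "error")) NULL else st,
                         error = if (inherits(st, "error"))
                           conditionMessage(st) else NULL)
  }
  list(results = results, failed = failed, partition = partition,
       buffer_A = buffer_A, family = family, screening = screening)
}

## parameter t in [0,1] where segment pa->pb crosses the border between
## two clusters; NA when no crossing is defined
.border_crossing <- function(part, c1, c2, pa, pb) {
  cl1 <- part$clusters[[c1]]; cl2 <- part$clusters[[c2]]
  if (part$method == "grid" && !is.null(cl1$cell)) {
    dif <- which(cl1$cell$index != cl2$cell$index)
    if (length(dif) == 1) {
      ax <- dif
      bound <- max(cl1$cell$lo[ax], cl2$cell$lo[ax])
      den <- pb[ax] - pa[ax]
      if (abs(den) < 1e-12) return(NA_real_)
      t <- (bound - pa[ax]) / den
      return(if (t >= 0 && t <= 1) t else NA_real_)
    }
  }
  ## k-means (and non-adjacent grid cells): perpendicular bisector plane
  ## of the two centroids
  m1 <- cl1$centroid; m2 <- cl2$centroid
  nrm <- m2 - m1
  den <- sum((pb - pa) * nrm)
  if (abs(den) < 1e-12) return(NA_real_)
  t <- sum(((m1 + m2) / 2 - pa) * nrm) / den
  if (t >= 0 && t <= 1) t else NA_real_
}

#' Merge cluster density matrices into a global density matrix
#'
#' Elements whose two host atoms share a core come verbatim from that
#' cluster. Elements spanning two cores are interpolated: the segment
#' between the two atoms is cut by the border between the clusters, the
#' two sub-lengths are normalized to sum to one, and each cluster's
#' contribution is weighted by the *other* side's normalized length (an
#' atom close to the border contributes little through its own cluster).
#' Where no border crossing is defined the arithmetic mean is used.
#'
#' @param run output of [run_clusters()].
#' @param basis global `lobe_basis` of the full system.
#' @param relevance_threshold only elements whose density relevance
#'   reaches this value are merged (others stay zero, matching the
#'   screened evaluation of the total density).
#' @return a `merged_density` with the global matrix `P` and a
#'   provenance table.
#' @export
merge_densities <- function(run, basis = NULL,
                            relevance_threshold = 1e-4) {
  part <- run$partition
  system <- part$system
  if (is.null(basis)) basis <- build_basis(system, run$family)
  n <- basis$n_bf
  ## which core does each atom belong to
  core_of <- integer(n_atoms(system))
  for (j in seq_along(part$clusters)) core_of[part$clusters[[j]]$core] <- j
  ## per cluster: map global fn -> cluster fn index
  fn_map <- vector("list", length(part$clusters))
  for (j in seq_along(run$results)) {
    res <- run$results[[j]]
    if (is.null(res$state)) next
    sub_atom_of_global <- rep(NA_integer_, n_atoms(system))
    sub_atom_of_global[res$map[!is.na(res$map)]] <- which(!is.na(res$map))
    subfn <- res$state$basis$fn
    m <- rep(NA_integer_, n)
    for (g in seq_len(n)) {
      ga <- basis$fn$atom[g]
      sa <- sub_atom_of_global[ga]
      if (is.na(sa)) next
      cand <- which(subfn$atom == sa & subfn$label == basis$fn$label[g])
      if (length(cand) == 1) m[g] <- cand
    }
    fn_map[[j]] <- m
  }
  rel <- relevance_matrix(basis)
  pos <- positions(system)
  P <- matrix(0, n, n)
  prov <- list()
  for (a in seq_len(n)) {
    for (b in seq_len(a)) {
      A <- basis$fn$atom[a]; B <- basis$fn$atom[b]
      c1 <- core_of[A]; c2 <- core_of[B]
      ## same-core elements are copied verbatim whatever their size (a
      ## degenerate single-cluster partition must reproduce the full
      ## density matrix exactly); only split elements are gated by the
      ## relevance indicator
      if (c1 != c2 && rel[a, b] < relevance_threshold) next
      val <- NA_real_
      if (c1 == c2) {
        m <- fn_map[[c1]]
        if (!is.null(m) && !is.na(m[a]) && !is.na(m[b])) {
          val <- run$results[[c1]]$state$P[m[a], m[b]]
        }
      } else {
        t <- .border_crossing(part, c1, c2, pos[A, ], pos[B, ])
        w1 <- if (is.na(t)) 0.5 else (1 - t)  # other side's length for c1
        w2 <- 1 - w1
        v1 <- v2 <- NA_real_
        m1 <- fn_map[[c1]]; m2 <- fn_map[[c2]]
        if (!is.null(m1) && !is.na(m1[a]) && !is.na(m1[b])) {
          v1 <- run$results[[c1]]$state$P[m1[a], m1[b]]
        }
        if (!is.null(m2) && !is.na(m2[a]) && !is.na(m2[b])) {
          v2 <- run$results[[c2]]$state$P[m2[a], m2[b]]
        }
        if (!is.na(v1) && !is.na(v2)) {
          val <- w1 * v1 + w2 * v2
        } else if (!is.na(v1)) {
          val <- v1
        } else if (!is.na(v2)) {
          val <- v2
        }
        if (a != b && !is.na(v1) && !is.na(v2)) {
          prov[[length(prov) + 1L]] <- data.frame(
            i = a, j = b, cluster1 = c1, cluster2 = c2, w1 = w1, w2 = w2)
        }
      }
      if (is.na(val)) {
        stop("density element (", a, ",", b,
             ") has no contributing cluster; increase the buffer")
      }
      P[a, b] <- val
      P[b, a] <- val
    }
  }
  structure(list(P = P, n_bf = n, basis = basis,
                 provenance = if (length(prov)) do.call(rbind, prov) else NULL,
                 relevance_threshold = relevance_threshold),
            class = "merged_density")
}

#' Divide-and-conquer in one call
#'
#' Partition, buffer, cap, solve sequentially, and merge.
#'
#' @param system a [molecular_system()].
#' @param method `"kmeans"` or `"grid"`.
#' @param k clusters for k-means.
#' @param cell_edge_A cell edge for grid partitioning.
#' @param buffer_A buffer thickness.
#' @param seed k-means seed.
#' @inheritParams run_clusters
#' @return list with `merged` (a `merged_density`) and `run` (the
#'   per-cluster results).
#' @export
dnc_solve <- function(system, method = c("kmeans", "grid"), k = 2L,
                      cell_edge_A = 12.5, buffer_A = 8, seed = 1L,
                      family = "STO-3G", screening = screening_config(),
                      scf = scf_config()) {
  method <- match.arg(method)
  part <- if (method == "kmeans") partition_kmeans(system, k, seed)
          else partition_grid(system, cell_edge_A)
  run <- run_clusters(part, buffer_A, family, screening, scf)
  if (length(run$failed)) {
    warning("SCF failed/unconverged for cluster(s) ",
            paste(run$failed, collapse = ", "))
  }
  merged <- merge_densities(
    run, relevance_threshold = max(screening$density_cutoff, 1e-6))
  list(merged = merged, run = run)
}

#' Evaluate the total electron density on a uniform grid
#'
#' rho(r) = sum_ab r(a,b) P_ab phi_a(r) phi_b(r) with r(a,b) the 0/1
#' density-relevance indicator at the screening threshold.
#'
#' @param P density matrix (from an `scf_state` or `merged_density`).
#' @param basis the matching `lobe_basis`.
#' @param spacing grid spacing in bohr (default 1.5, the standard
#'   visualization resolution; use ~0.3 for quantitative integrals).
#' @param margin_bohr grid margin beyond the atoms, bohr.
#' @param valence_only restrict both basis indices to valence functions.
#' @param relevance_threshold indicator threshold (0 keeps every pair).
#' @return a [density_grid()].
#' @export
total_density_on_grid <- function(P, basis, spacing = 1.5, margin_bohr = 5,
                                  valence_only = FALSE,
                                  relevance_threshold = 0) {
  if (inherits(P, "scf_state")) { basis <- P$basis; P <- P$P }
  if (inherits(P, "merged_density")) { basis <- P$basis; P <- P$P }
  lo <- apply(basis$atom_pos, 2, min) - margin_bohr
  hi <- apply(basis$atom_pos, 2, max) + margin_bohr
  shape <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  gx <- lo[1] + (seq_len(shape[1]) - 1) * spacing
  gy <- lo[2] + (seq_len(shape[2]) - 1) * spacing
  gz <- lo[3] + (seq_len(shape[3]) - 1) * spacing
  pts <- cbind(rep(gx, times = shape[2] * shape[3]),
               rep(rep(gy, each = shape[1]), times = shape[3]),
               rep(gz, each = shape[1] * shape[2]))
  rel <- if (relevance_threshold > 0) relevance_matrix(basis) else NULL
  keep_fn <- if (valence_only) basis$fn$valence else rep(TRUE, basis$n_bf)
  vals <- numeric(nrow(pts))
  for (i in seq_len(basis$n_bf)) {
    if (!keep_fn[i]) next
    for (j in seq_len(i)) {
      if (!keep_fn[j]) next
      if (!is.null(rel) && rel[i, j] < relevance_threshold) next
      pij <- P[i, j]
      if (abs(pij) < 1e-12) next
      fac <- if (i == j) 1 else 2
      for (m in (basis$fn_ptr[i] + 1):basis$fn_ptr[i + 1]) {
        for (nn in (basis$fn_ptr[j] + 1):basis$fn_ptr[j + 1]) {
          am <- basis$prim_alpha[m]; an <- basis$prim_alpha[nn]
          p <- am + an
          dmn <- basis$prim_center[m, ] - basis$prim_center[nn, ]
          K <- exp(-am * an / p * sum(dmn^2))
          cc <- basis$prim_coef[m] * basis$prim_coef[nn] * K * fac * pij
          if (abs(cc) < 1e-14) next
          rp <- (am * basis$prim_center[m, ] + an * basis$prim_center[nn, ]) / p
          d2 <- (pts[, 1] - rp[1])^2 + (pts[, 2] - rp[2])^2 +
            (pts[, 3] - rp[3])^2
          vals <- vals + cc * exp(-p * d2)
        }
      }
    }
  }
  density_grid(lo, spacing, shape, vals)
}
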