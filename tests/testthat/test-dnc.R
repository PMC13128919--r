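two_waters_apart <- function(sep = 12) {
  w <- make_named_small("H2O")
  p <- positions(w)
  molecular_system(rep(w$atoms$element, 2),
                   rbind(p, sweep(p, 2, c(sep, 0, 0), `+`)),
                   label = "two separated waters")
}

test_that("k-means partitioning is seeded, exhaustive and separable", {
  w <- make_water_cluster(4, seed = 2)
  p1 <- partition_kmeans(w, 1, seed = 1)
  expect_length(p1$clusters, 1)
  expect_equal(p1$clusters[[1]]$core, seq_len(n_atoms(w)))
  sep <- two_waters_apart(15)
  p2 <- partition_kmeans(sep, 2, seed = 1)
  cores <- lapply(p2$clusters, `[[`, "core")
  expect_setequal(unlist(cores), 1:6)
  expect_true(setequal(cores[[1]], 1:3) || setequal(cores[[1]], 4:6))
  p2b <- partition_kmeans(sep, 2, seed = 1)
  expect_identical(lapply(p2b$clusters, `[[`, "core"), cores)
  ## every atom in exactly one core
  expect_equal(sort(unlist(cores)), 1:6)
})

test_that("grid partitioning uses half-open cells from the box minimum", {
  w <- make_water_cluster(3, seed = 5)
  pg <- partition_grid(w, cell_edge_A = 1e4)
  expect_length(pg$clusters, 1)
  ## atom exactly on a cell boundary goes to the higher cell
  s <- molecular_system(c("H", "H", "H", "H"),
                        rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)))
  pg2 <- partition_grid(s, cell_edge_A = 2)
  cores <- lapply(pg2$clusters, `[[`, "core")
  expect_length(cores, 2)
  expect_true(any(vapply(cores, function(cc) setequal(cc, c(1, 2)), TRUE)))
  expect_true(any(vapply(cores, function(cc) setequal(cc, c(3, 4)), TRUE)))
  ## full coverage
  expect_setequal(unlist(lapply(partition_grid(w, 3)$clusters, `[[`, "core")),
                  seq_len(n_atoms(w)))
})

test_that("buffers collect surroundings without splitting molecules", {
  sep <- two_waters_apart(12)
  part <- partition_kmeans(sep, 2, seed = 1)
  cl <- build_buffer(part$clusters[[1]], sep, thickness_A = 8)
  expect_length(cl$buffer, 0)        # the other water is 12 A away
  cl2 <- build_buffer(part$clusters[[1]], sep, thickness_A = 1e6)
  expect_setequal(c(cl2$core, cl2$buffer), 1:6)
  ## a whole water 5 A from the core enters the buffer intact, no caps
  sep5 <- two_waters_apart(5)
  part5 <- partition_kmeans(sep5, 2, seed = 1)
  cl5 <- build_buffer(part5$clusters[[1]], sep5, thickness_A = 8)
  expect_setequal(c(cl5$core, cl5$buffer), 1:6)
  expect_equal(nrow(cl5$caps), 0)
})

test_that("bond capping follows the chemically informed rules", {
  ## butane-like heavy-atom chain with explicit hydrogens
  but <- {
    ## C-C single bonds at 1.53 A along x; terminal CH3, inner CH2
    cpos <- cbind(c(0, 1.53, 3.06, 4.59), 0, 0)
    hof <- function(i, n3) {
      if (n3) rbind(cpos[i, ] + c(0, 1.0, 0.4), cpos[i, ] + c(0, -1.0, 0.4),
                    cpos[i, ] + c(0, 0, -1.09))
      else rbind(cpos[i, ] + c(0, 1.0, 0.4), cpos[i, ] + c(0, -1.0, 0.4))
    }
    hpos <- rbind(hof(1, TRUE), hof(2, FALSE), hof(3, FALSE), hof(4, TRUE))
    molecular_system(c(rep("C", 4), rep("H", 10)), rbind(cpos, hpos))
  }
  cl <- lobehf:::.new_cluster(1L, c(1L, 2L, which(but$atoms$element == "H")[1:5]))
  capped <- cap_cut_bonds(cl, but)
  ## one cap at 1.09 A from C2 along the former C2-C3 bond
  expect_equal(nrow(capped$caps), 1)
  expect_equal(capped$caps$parent_in, 2)
  expect_equal(capped$caps$parent_out, 3)
  d <- sqrt(sum((as.numeric(capped$caps[1, c("x", "y", "z")]) -
                   positions(but)[2, ])^2))
  expect_equal(d, 1.09, tolerance = 1e-10)

  ## cutting ethene across the double bond pulls both carbons in
  eth <- make_named_small("C2H4")
  cl2 <- lobehf:::.new_cluster(1L, c(1L, 3L, 4L))  # C1 and its hydrogens
  capped2 <- cap_cut_bonds(cl2, eth)
  expect_true(2 %in% c(capped2$core, capped2$buffer))

  ## cutting an O-H bond caps at the O-H length 0.96
  w <- make_named_small("H2O")
  cl3 <- lobehf:::.new_cluster(1L, c(1L, 2L))
  capped3 <- cap_cut_bonds(cl3, w)
  expect_equal(nrow(capped3$caps), 1)
  d3 <- sqrt(sum((as.numeric(capped3$caps[1, c("x", "y", "z")]) -
                    positions(w)[1, ])^2))
  expect_equal(d3, 0.96, tolerance = 1e-10)
  ## capped clusters always end up even-electron
  cs <- cluster_system(capped3, w)
  expect_equal(n_electrons(cs$system) %% 2, 0)
})

test_that("a degenerate partition reproduces the full SCF exactly", {
  w <- make_water_cluster(2, seed = 8)
  full <- scf_solve(w, screening = screening_config())
  part <- partition_kmeans(w, 1, seed = 1)
  run <- run_clusters(part, buffer_A = 50)
  expect_length(run$failed, 0)
  merged <- merge_densities(run)
  expect_equal(merged$P, full$P, tolerance = 1e-12)
  expect_equal(run$results[[1]]$state$E_total, full$E_total,
               tolerance = 1e-12)
})

test_that("disjoint clusters solve independently to the monomer energy", {
  sep <- two_waters_apart(25)
  Ew <- scf_solve(make_named_small("H2O"),
                  screening = screening_config())$E_total
  part <- partition_kmeans(sep, 2, seed = 1)
  run <- run_clusters(part, buffer_A = 8)
  expect_length(run$failed, 0)
  for (r in run$results) {
    expect_equal(r$state$E_total, Ew, tolerance = 1e-7)
  }
  ## deterministic ordering by cluster id
  expect_equal(vapply(run$results, function(r) r$cluster$id, 1L), 1:2)
})

test_that("merged densities interpolate split elements with unit weights", {
  sep <- two_waters_apart(4.5)
  part <- partition_kmeans(sep, 2, seed = 1)
  run <- run_clusters(part, buffer_A = 8)
  merged <- merge_densities(run, relevance_threshold = 1e-6)
  expect_lt(max(abs(merged$P - t(merged$P))), 1e-12)
  if (!is.null(merged$provenance)) {
    expect_true(all(abs(merged$provenance$w1 + merged$provenance$w2 - 1) <
                      1e-12))
    expect_true(all(merged$provenance$w1 >= 0 & merged$provenance$w1 <= 1))
  }
  ## both-atoms-in-one-core elements come verbatim from that cluster
  b <- merged$basis
  res1 <- run$results[[1]]
  core1 <- run$partition$clusters[[1]]$core
  gfns <- which(b$fn$atom %in% core1)
  sub_atom <- match(b$fn$atom[gfns[1]], sort(c(res1$cluster$core,
                                               res1$cluster$buffer)))
  expect_true(is.finite(merged$P[gfns[1], gfns[1]]))
})

test_that("divide-and-conquer densities track the full calculation", {
  ## hydrogen-bond-range water dimer, 2 clusters
  sep <- two_waters_apart(3.0)
  full <- scf_solve(sep, screening = screening_config())
  part <- partition_kmeans(sep, 2, seed = 1)
  run <- run_clusters(part, buffer_A = 8)
  merged <- merge_densities(run, relevance_threshold = 1e-6)
  g_full <- total_density_on_grid(full$P, full$basis, spacing = 0.7)
  g_dnc <- total_density_on_grid(merged$P, merged$basis, spacing = 0.7)
  expect_lt(max(abs(g_full$values - g_dnc$values)), 1e-3)
  ## analytic electron count of the merged density is exact
  S <- one_electron_matrices(merged$basis)$S
  expect_equal(sum(merged$P * S), n_electrons(sep), tolerance = 1e-4)
  ## the grid quadrature reproduces the analytic integral of the same
  ## (valence-only) density within 1%; core 1s products are far sharper
  ## than any practical grid and are excluded from this check
  val <- merged$basis$fn$valence
  expected <- sum((merged$P * S)[val, val])
  g_fine <- total_density_on_grid(merged$P, merged$basis, spacing = 0.3,
                                  margin_bohr = 7, valence_only = TRUE)
  expect_equal(integrate_grid(g_fine), expected, tolerance = 0.01)
})

test_that("grid densities integrate to the electron count for H2", {
  st <- scf_solve(make_named_small("H2"), screening = no_screening())
  g <- total_density_on_grid(st$P, st$basis, spacing = 0.25, margin_bohr = 7)
  expect_equal(integrate_grid(g), 2, tolerance = 0.01)
  ## hydrogen has no core functions: valence-only equals the full density
  gv <- total_density_on_grid(st$P, st$basis, spacing = 0.25,
                              margin_bohr = 7, valence_only = TRUE)
  expect_equal(gv$values, g$values)
})
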