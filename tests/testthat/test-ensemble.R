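test_that("pairwise RMSD behaves as a superposed metric", {
  base <- matrix(c(0, 0, 0, 1, 0, 0, 0, 2, 0), 3, 3, byrow = TRUE)
  pool_same <- conformation_pool(list(base, base, base))
  D <- pairwise_rmsd(pool_same)
  expect_lt(max(abs(D)), 1e-12)
  # rigid translate: superposition removes it
  shifted <- base + matrix(c(5, -3, 2), 3, 3, byrow = TRUE)
  D2 <- pairwise_rmsd(conformation_pool(list(base, shifted)),
                      superpose = TRUE)
  expect_lt(D2[1, 2], 1e-10)
  # without superposition, the brute-force arithmetic oracle applies
  displaced <- base
  displaced[2, ] <- displaced[2, ] + c(0, 3, 4)  # one bead moved by 5
  D3 <- pairwise_rmsd(conformation_pool(list(base, displaced)),
                      superpose = FALSE)
  expect_equal(D3[1, 2], sqrt(25 / 3))
  expect_true(isSymmetric(D3))
  expect_error(pairwise_rmsd(pool_same, selection = integer(0)), "selection")
})

test_that("diameter-bounded clustering recovers planted blobs exactly", {
  pb <- planted_blob_pool(n_per = 8, spread = 0.15)
  cl <- cluster_conformations(pb$pool, diameter = 3.0)
  expect_identical(cl$n_clusters, 2L)
  # partition matches the planted labels (brute-force relabel check)
  tab <- table(cl$membership, pb$labels)
  expect_identical(sort(as.integer(tab)), c(0L, 0L, 8L, 8L))
  # diameter invariant certified against the RMSD matrix directly
  for (g in 1:2) {
    idx <- which(cl$membership == g)
    expect_lte(max(cl$rmsd[idx, idx]), 3.0)
  }
  # degenerate cases
  one <- conformation_pool(list(diag(3), diag(3), diag(3)))
  expect_identical(cluster_conformations(one, 3)$n_clusters, 1L)
  pb2 <- planted_blob_pool(n_per = 3, spread = 0.3, seed = 5)
  expect_identical(cluster_conformations(pb2$pool, 0)$n_clusters,
                   pb2$pool$n_frames)
})

test_that("clustering is invariant to frame order up to relabeling", {
  pb <- planted_blob_pool(n_per = 6, spread = 0.4, seed = 7)
  cl <- cluster_conformations(pb$pool, diameter = 3.0)
  set.seed(8)
  perm <- sample(pb$pool$n_frames)
  shuffled <- conformation_pool(pb$pool$coords[perm, , , drop = FALSE])
  cl_perm <- cluster_conformations(shuffled, diameter = 3.0)
  # same partition: co-membership matrices agree under the permutation
  co <- function(m) outer(m, m, `==`)
  expect_identical(co(cl$membership)[perm, perm], co(cl_perm$membership))
})

test_that("network edges follow the link threshold and linkage mode", {
  pb <- planted_blob_pool(n_per = 5, n_blobs = 3, spread = 0.5, seed = 12)
  cl <- cluster_conformations(pb$pool, diameter = 3.0)
  for (mode in c("single", "representative")) {
    for (link in c(2, 6, 12)) {
      net <- build_network(cl, link = link, mode = mode)
      expect_true(isSymmetric(net$adjacency))
      expect_true(all(!diag(net$adjacency)))
      # exhaustive member-pair / representative oracle
      for (a in seq_len(cl$n_clusters - 1))
        for (b in seq((a + 1), cl$n_clusters)) {
          ia <- which(cl$membership == a); ib <- which(cl$membership == b)
          d <- if (mode == "single") min(cl$rmsd[ia, ib])
               else cl$rmsd[cl$representative[a], cl$representative[b]]
          expect_identical(net$adjacency[a, b], d <= link)
        }
    }
  }
})

test_that("geometric criteria use strict inequalities and named aggregates", {
  # 10 frames of 3 particles; particle 2 within 8 A of particle 1 in 6/10
  frames <- lapply(1:10, function(f) {
    m <- matrix(0, 3, 3)
    m[2, 1] <- if (f <= 6) 5 else 12
    m[3, ] <- c(0, 9, 0)
    m
  })
  coords <- conformation_pool(frames)$coords
  crit <- geom_criterion("atom-atom", i = 1, j = 2, threshold = 8,
                         direction = "less", aggregate = "fraction", p = 0.5)
  expect_true(criterion_satisfied(crit, coords))   # 60% > 50%
  # exactly 50%: strictly "more than" fails
  coords50 <- coords[c(1:5, 7:10, 7), , , drop = FALSE]
  expect_false(criterion_satisfied(crit, coords50))
  # mean-aggregate: mean distance 8.5 against "greater than 8"
  far <- lapply(1:4, function(f) {
    m <- matrix(0, 2, 3); m[2, 1] <- 8.5; m
  })
  crit_mean <- geom_criterion("atom-atom", i = 1, j = 2, threshold = 8,
                              direction = "greater", aggregate = "mean")
  expect_true(criterion_satisfied(crit_mean,
                                  conformation_pool(far)$coords))
  # com-atom distances and missing-atom errors
  crit_com <- geom_criterion("com-atom", group = c(1, 2), j = 3,
                             threshold = 5, direction = "greater",
                             aggregate = "mean")
  expect_true(criterion_satisfied(crit_com, coords))
  crit_bad <- geom_criterion("atom-atom", i = 1, j = 9, threshold = 5)
  expect_error(criterion_satisfied(crit_bad, coords), "particle 9")
})

test_that("cluster classification applies the first fully-satisfied set", {
  pb <- planted_blob_pool(n_per = 4, spread = 0.1, seed = 31)
  cl <- cluster_conformations(pb$pool, diameter = 3.0)
  # blob 2 is displaced by +10 on every coordinate: classify on particle 1 x
  spec <- list(
    list(label = "displaced",
         criteria = list(geom_criterion("atom-atom", i = 1, j = 2,
                                        threshold = 1e-3,
                                        direction = "greater",
                                        aggregate = "fraction", p = 0.9))))
  labels <- classify_clusters(pb$pool, cl, spec, default = "base")
  expect_identical(sort(unique(labels)), "displaced")  # both blobs qualify
  net <- build_network(cl, link = 3.8)
  net <- classify_clusters(pb$pool, net, spec)
  expect_identical(net$labels, labels)
})

test_that("nearest-reference distances average with self-exclusion", {
  pb <- planted_blob_pool(n_per = 4, n_blobs = 4, spread = 0.6, seed = 44)
  cl <- cluster_conformations(pb$pool, diameter = 3.0)
  k <- cl$n_clusters
  skip_if(k < 3, "fixture collapsed to fewer than 3 clusters")
  rep_d <- function(a, b) cl$rmsd[cl$representative[a], cl$representative[b]]
  # one query, one reference -> their representative distance
  expect_equal(mean_nearest_neighbor_distance(cl, 1, 2), rep_d(1, 2))
  # query set == reference set: nearest OTHER cluster, brute force
  oracle <- mean(vapply(seq_len(k), function(q)
    min(vapply(setdiff(seq_len(k), q), function(r) rep_d(q, r), 0)), 0))
  expect_equal(mean_nearest_neighbor_distance(cl, seq_len(k), seq_len(k)),
               oracle)
  expect_error(mean_nearest_neighbor_distance(cl, 1, 1), "self-exclusion")
})

test_that("density maps are normalized histograms with fixed-interval levels", {
  one_bin <- matrix(c(0.5, 0.5), 1, 2)
  dm <- density_contours(one_bin, xlim = c(0, 1), ylim = c(0, 1), nbins = 10)
  expect_equal(sum(dm$density), 1)
  expect_equal(max(dm$density), 1)
  expect_equal(dm$levels, seq(0.005, 1, by = 0.005))
  # uniform points fill bins evenly
  set.seed(9)
  u <- cbind(runif(20000), runif(20000))
  dmu <- density_contours(u, xlim = c(0, 1), ylim = c(0, 1), nbins = 5)
  expect_lt(max(dmu$density) - min(dmu$density), 0.02)
  # planted bimodal sample has modes in the planted bins
  bi <- rbind(cbind(rnorm(500, -2, 0.1), rnorm(500, 0, 0.1)),
              cbind(rnorm(500, 2, 0.1), rnorm(500, 0, 0.1)))
  dmb <- density_contours(bi, xlim = c(-3, 3), ylim = c(-1, 1), nbins = 30)
  colsum <- rowSums(dmb$density)   # marginal over x
  x_left <- dmb$x[dmb$x < 0][which.max(colsum[dmb$x < 0])]
  x_right <- dmb$x[dmb$x > 0][which.max(colsum[dmb$x > 0])]
  expect_lt(abs(x_left + 2), 0.3)
  expect_lt(abs(x_right - 2), 0.3)
  expect_error(density_contours(one_bin, nbins = 1), "degenerate")
})

test_that("RMSF matches statics, rigid motion and equipartition", {
  base <- matrix(rnorm(12), 4, 3)
  static <- conformation_pool(list(base, base, base))
  expect_true(all(compute_rmsf(static)$rmsf == 0))
  # rigidly translated copies vanish after superposition
  moved <- lapply(0:4, function(s) base + s)
  expect_lt(max(compute_rmsf(conformation_pool(moved),
                             superpose = TRUE)$rmsf), 1e-10)
  # isotropic harmonic restraint: RMSF -> sqrt(3 kB T / k) within 5%
  k <- 2
  sys <- toy_system("harmonic", center = c(0, 0, 0), stiffness = k,
                    temperature = 300, friction = 10, timestep = 0.004)
  tr <- run_langevin(sys, 120000, x0 = matrix(0, 1, 3), seed = 61,
                     stride = 4)
  expected <- sqrt(3 * sim_constants()$kB * 300 / k)
  expect_equal(compute_rmsf(tr)$rmsf, expected, tolerance = 0.05)
})
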