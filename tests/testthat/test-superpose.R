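# Kabsch superposition and the domain-decomposed RMSD observables.

test_that("kabsch recovers rigid motions exactly", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  same <- kabsch(X, X)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$transform$rotation, diag(3), tolerance = 1e-9)

  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sweep(X %*% t(R), 2, -c(5, 0, 0))
  fit <- kabsch(moved, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(apply_transform(moved, fit$transform), X, tolerance = 1e-9)

  expect_error(kabsch(X, X[1:5, ]), class = "selection_mismatch_error")
  expect_error(kabsch(X[1:2, ], X[1:2, ]), class = "degenerate_geometry_error")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line), class = "degenerate_geometry_error")
})

test_that("kabsch matches a rotation-grid search on the stretched triangle", {
  A <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0))
  B <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1.5, 0))
  got <- kabsch(A, B)$rmsd
  # oracle: coarse axis grid x 1 degree angle grid, centroids matched
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  best <- Inf
  set.seed(2)
  axes <- rbind(diag(3), matrix(rnorm(3 * 400), ncol = 3))
  axes <- axes / sqrt(rowSums(axes^2))
  for (k in seq_len(nrow(axes))) {
    a <- axes[k, ]
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    for (deg in seq(0, 359, by = 1)) {
      th <- deg * pi / 180
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      v <- sqrt(sum((Ac %*% t(R) - Bc)^2) / 3)
      if (v < best) best <- v
    }
  }
  expect_lt(abs(got - best), 1e-3)
  expect_lte(got, best + 1e-12)
})

test_that("kabsch agrees with the quaternion oracle and is rigid-motion invariant", {
  set.seed(3)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    P <- matrix(rnorm(3 * n, sd = 3), n, 3)
    Q <- P + matrix(rnorm(3 * n, sd = 0.7), n, 3)
    expect_equal(kabsch(P, Q)$rmsd, horn_superpose(P, Q)$rmsd,
                 tolerance = 1e-9)
    # invariance under rigid pre-motion of either argument
    expect_equal(kabsch(rigid_move(P), Q)$rmsd, kabsch(P, Q)$rmsd,
                 tolerance = 1e-9)
    expect_equal(kabsch(P, rigid_move(Q))$rmsd, kabsch(P, Q)$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("apply_transform composes and inverts as a group action", {
  set.seed(4)
  X <- matrix(rnorm(21), 7, 3)
  tr <- rigid_transform(random_rotation_matrix(), rnorm(3))
  expect_equal(apply_transform(apply_transform(X, tr), invert_transform(tr)),
               X, tolerance = 1e-12)
  ident <- rigid_transform()
  expect_equal(apply_transform(X, ident), X)
  expect_equal(apply_transform(matrix(0, 1, 3),
                               rigid_transform(diag(3), c(1, 1, 1))),
               matrix(1, 1, 3))
  expect_error(rigid_transform(-diag(3)), class = "invalid_transform_error")
})

test_that("ensemble average removes rigid motion and recovers the generator mean", {
  b <- small_bundle()
  sm <- b$segmap
  # identical frames: the average is that frame after one pass
  ens <- structure_ensemble(b$frame$atoms,
                            list(b$frame$xyz, b$frame$xyz, b$frame$xyz))
  avg <- ensemble_average(ens, sm)
  expect_equal(avg$xyz, b$frame$xyz, tolerance = 1e-9)
  expect_true(attr(avg, "converged"))

  # two frames differing by a pure translation
  ens2 <- structure_ensemble(b$frame$atoms,
                             list(b$frame$xyz, sweep(b$frame$xyz, 2, -c(3, 0, 0))))
  avg2 <- ensemble_average(ens2, sm)
  expect_equal(kabsch(b$frame$xyz, avg2$xyz)$rmsd, 0, tolerance = 1e-8)

  # Monte-Carlo: isotropic noise about a known reference
  spec <- motion_spec(atom_noise_sd = 0.3, seed = 11)
  ens3 <- make_ensemble(b$frame, sm, spec, 20)
  avg3 <- ensemble_average(ens3, sm)
  expect_lt(kabsch(avg3$xyz, b$frame$xyz)$rmsd, 0.3 / sqrt(20) * 3)
})

test_that("rmsd decomposition separates receptor and fusion-domain motion", {
  b <- small_bundle()
  sm <- b$segmap
  fr <- b$frame
  zero <- rmsd_decomposition(fr, fr, sm)
  expect_equal(unlist(zero), c(rmsd_all = 0, rmsd_tm = 0, rmsd_t4l = 0,
                               rmsd_t4l_prime = 0), tolerance = 1e-12)

  # fusion domain rigidly translated 4 A, receptor untouched
  idx <- select_atom_indices(fr$atoms, sm, "T4L", "heavy")
  shifted <- fr
  shifted$xyz[idx, 1] <- shifted$xyz[idx, 1] + 4
  dec <- rmsd_decomposition(shifted, fr, sm)
  expect_equal(dec$rmsd_tm, 0, tolerance = 1e-9)
  expect_equal(dec$rmsd_t4l, 0, tolerance = 1e-9)
  expect_equal(dec$rmsd_t4l_prime, 4, tolerance = 1e-9)

  # whole-complex rigid motion plus 1 A fusion offset
  set.seed(5)
  moved <- fr
  moved$xyz[idx, 2] <- moved$xyz[idx, 2] + 1
  moved$xyz <- rigid_move(moved$xyz)
  dec2 <- rmsd_decomposition(moved, fr, sm)
  expect_equal(dec2$rmsd_t4l_prime, 1, tolerance = 1e-9)
  expect_equal(dec2$rmsd_tm, 0, tolerance = 1e-9)
  expect_equal(dec2$rmsd_t4l, 0, tolerance = 1e-9)
})

test_that("fusion-domain transfer RMSD dominates its refit counterpart", {
  b <- small_bundle()
  spec <- motion_spec(domain_rot_sd = list(T4L = 10, TM2 = 3),
                      domain_trans_sd = list(T4L = 2, TM5 = 1),
                      global_rot_sd = 10, global_trans_sd = 3,
                      atom_noise_sd = 0.3, seed = 12)
  ens <- make_ensemble(b$frame, b$segmap, spec, 15)
  rep <- rmsd_report(ens, b$segmap)
  expect_true(all(rep$rmsd_t4l_prime >= rep$rmsd_t4l - 1e-9))
  expect_true(all(rep$rmsd_all >= 0))
  expect_equal(rep$frame_index, 1:15)
})

test_that("the 7x7 matrix reports within-helix and packing differences", {
  b <- small_bundle()
  sm <- b$segmap
  fr <- b$frame
  expect_equal(max(abs(seven_by_seven(fr, fr, sm))), 0, tolerance = 1e-12)

  # TM3 rigidly translated by 2 A: column 3 reads 2 everywhere but (3,3);
  # row 3 off-diagonals read 2 as well
  idx3 <- select_atom_indices(fr$atoms, sm, "TM3", "heavy")
  tgt <- fr
  tgt$xyz[idx3, 3] <- tgt$xyz[idx3, 3] + 2
  M <- seven_by_seven(fr, tgt, sm)
  expect_equal(M[3, 3], 0, tolerance = 1e-9)
  expect_equal(unname(M[-3, 3]), rep(2, 6), tolerance = 1e-9)
  expect_equal(unname(M[3, -3]), rep(2, 6), tolerance = 1e-9)
  off <- M[-3, -3]
  expect_equal(max(abs(off)), 0, tolerance = 1e-9)
})

test_that("7x7 agrees with an independent superposition path and has symmetric diagonals", {
  b <- small_bundle()
  sm <- b$segmap
  spec <- motion_spec(
    domain_rot_sd = as.list(setNames(rep(3, 7), sm$tm_names)),
    domain_trans_sd = as.list(setNames(rep(0.5, 7), sm$tm_names)),
    atom_noise_sd = 0.2, seed = 13)
  ens <- make_ensemble(b$frame, sm, spec, 2)
  A <- get_frame(ens, 1); B <- get_frame(ens, 2)
  M <- seven_by_seven(A, B, sm)
  expect_equal(unname(M), seven_by_seven_oracle(A, B, sm), tolerance = 1e-9)
  expect_equal(unname(diag(seven_by_seven(A, B, sm))),
               unname(diag(seven_by_seven(B, A, sm))), tolerance = 1e-9)
})

test_that("pooled TM-bundle comparison is symmetric and zero for identical bundles", {
  b <- small_bundle()
  expect_equal(compare_tm_bundles(b$frame, b$frame, b$segmap), 0,
               tolerance = 1e-12)
  set.seed(6)
  other <- b$frame
  other$xyz <- rigid_move(other$xyz) + matrix(rnorm(length(other$xyz), 0, 0.4),
                                              nrow(other$xyz), 3)
  d_ab <- compare_tm_bundles(b$frame, other, b$segmap)
  d_ba <- compare_tm_bundles(other, b$frame, b$segmap)
  expect_equal(d_ab, d_ba, tolerance = 1e-9)
  expect_gt(d_ab, 0)
})
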