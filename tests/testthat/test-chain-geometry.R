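test_that("builder reproduces internal coordinates exactly", {
  top <- chain_topology(11)
  set.seed(101)
  for (rep_i in 1:5) {
    d <- runif(top$n_dihedrals, -179.9, 180)
    conf <- build_cartesian(top, d)
    b <- diff(conf$coords)
    expect_lt(max(abs(sqrt(rowSums(b^2)) - top$bond_length)), 1e-9)
    ang <- vapply(2:(top$n_carbons - 1), function(i) {
      u <- conf$coords[i - 1, ] - conf$coords[i, ]
      v <- conf$coords[i + 1, ] - conf$coords[i, ]
      acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    }, numeric(1))
    expect_lt(max(abs(ang - top$bond_angle)), 1e-9)
    expect_lt(max(abs(measure_dihedrals(conf$coords) - d)), 1e-6)
  }
})

test_that("dihedral -> coords -> dihedral round trip is the identity", {
  top <- chain_topology(14)
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    d <- runif(top$n_dihedrals, -179.99, 180)
    conf <- build_cartesian(top, d)
    worst <- max(worst, max(abs(measure_dihedrals(conf$coords) - d)))
  }
  expect_lt(worst, 1e-6)
})

test_that("two-carbon chain is a single bond; wrong dihedral count errors", {
  conf <- build_cartesian(chain_topology(2))
  expect_equal(end_to_end(conf), 1.53)
  expect_error(build_cartesian(chain_topology(11), rep(180, 5)), "expected 8")
})

test_that("builder agrees with an explicit rotation-matrix construction", {
  for (d in list(c(180, 60), c(-60, 175), c(90, -90))) {
    conf <- build_cartesian(chain_topology(5), d)
    ref <- oracle_build_chain(d, 5)
    expect_lt(abs(end_to_end(conf) - sqrt(sum((ref[5, ] - ref[1, ])^2))), 1e-9)
    # full internal geometry agrees, not just the end-to-end distance
    expect_lt(max(abs(measure_dihedrals(ref) - d)), 1e-9)
  }
})

test_that("end_to_end is the Euclidean distance and symmetry-invariant", {
  expect_equal(end_to_end(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  top <- chain_topology(11)
  set.seed(3)
  d <- runif(8, -180, 180)
  conf <- build_cartesian(top, d)
  mirror <- conf$coords %*% diag(c(1, 1, -1))
  theta <- 0.83
  R <- matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3)
  expect_equal(end_to_end(mirror), end_to_end(conf))
  expect_equal(end_to_end(sweep(conf$coords %*% R, 2, c(3, -2, 7), "+")),
               end_to_end(conf))
  expect_error(end_to_end(matrix(0, 1, 3)), "at least 2")
})

test_that("closed-form all-trans length matches the builder for n = 2..30", {
  for (n in 2:30) {
    top <- chain_topology(n)
    built <- end_to_end(build_cartesian(top, all_trans(top)))
    expect_lt(abs(all_trans_length(top) - built), 1e-9)
  }
  # single bond collapses to the bond length
  expect_equal(all_trans_length(chain_topology(2)), 1.53)
})

test_that("all-trans C11 spans 12.6 +/- 0.2 Angstrom", {
  expect_equal(all_trans_length(chain_topology(11)), 12.6, tolerance = 0.2 / 12.6)
})

test_that("r_ee never exceeds the all-trans length", {
  top <- chain_topology(16)
  at <- all_trans_length(top)
  set.seed(11)
  for (i in 1:200) {
    d <- runif(top$n_dihedrals, -180, 180)
    expect_lte(end_to_end(build_cartesian(top, d)), at + 1e-9)
  }
})

test_that("dihedral classification follows the documented conventions", {
  expect_equal(classify_dihedrals(rep(180, 6))$gauche_fraction, 0)
  expect_equal(classify_dihedrals(rep(60, 6))$gauche_fraction, 1)
  res <- classify_dihedrals(c(180, 60, -60, 170))
  expect_equal(res$labels, c("t", "g+", "g-", "t"))
  expect_equal(res$gauche_fraction, 0.5)
  expect_equal(classify_dihedrals(0)$labels, "g+")   # documented tie-break
  expect_equal(classify_dihedrals(c(120, -120))$labels, c("t", "t"))
})

test_that("rms_end_to_end is the weighted quadratic mean", {
  expect_equal(rms_end_to_end(4.2), 4.2)
  expect_equal(rms_end_to_end(c(3, 4)), sqrt(12.5))
  expect_equal(rms_end_to_end(c(3, 4), c(1, 0)), 3)
  expect_error(rms_end_to_end(c(3, 4), c(0, 0)), "zero")
  expect_error(rms_end_to_end(c(3, 4), c(-1, 1)), "nonnegative")
})

test_that("sampled RIS ensemble reproduces the exact RMS end-to-end", {
  mod <- ris_model(5)
  exact <- ris_enumerate(mod, 298.15)$rms_ree
  run <- run_ris_mc(mod, n_steps = 2e5, stride = 2, seed = 31)
  sampled <- rms_end_to_end(run$r_ee)
  expect_lt(abs(sampled - exact) / exact, 0.005)
})

test_that("Monte Carlo volume brackets analytic sphere volumes", {
  one <- data.frame(element = "C", x = 0, y = 0, z = 0)
  v1 <- vdw_volume(one, n_points = 2e5, seed = 1)
  expect_lt(abs(v1$volume - 4 / 3 * pi * 1.7^3), 3 * v1$stderr)

  two_far <- data.frame(element = c("C", "C"), x = c(0, 10), y = 0, z = 0)
  v2 <- vdw_volume(two_far, n_points = 2e5, seed = 2)
  expect_lt(abs(v2$volume - 8 / 3 * pi * 1.7^3), 3 * v2$stderr)

  two_near <- data.frame(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0)
  v3 <- vdw_volume(two_near, n_points = 2e5, seed = 3)
  expect_lt(abs(v3$volume - oracle_two_sphere_union(1.7, 1.7, 1.5)),
            3 * v3$stderr)
})

test_that("volume estimates are seed-reproducible and tighten with n", {
  conf <- build_cartesian(chain_topology(8, with_hydrogens = TRUE), rep(180, 5))
  a <- vdw_volume(conf, n_points = 2e5, seed = 9)
  b <- vdw_volume(conf, n_points = 2e5, seed = 9)
  expect_identical(a$volume, b$volume)
  big <- vdw_volume(conf, n_points = 8e5, seed = 9)
  expect_lt(big$stderr, a$stderr)        # ~1/sqrt(n) convergence
  expect_error(vdw_volume(conf, n_points = 100), ">= 1e5")
  expect_error(vdw_volume(data.frame(element = character(),
                                     x = numeric(), y = numeric(),
                                     z = numeric())), "empty")
})

test_that("packing fraction is the volume ratio with guarded inputs", {
  expect_equal(packing_fraction(740, 740), 1)
  expect_equal(packing_fraction(list(volume = 370), 740), 0.5)
  expect_error(packing_fraction(-1, 740), "positive")
  expect_error(packing_fraction(350, 0), "positive")
})

test_that("hydrogen placement yields correct C-H geometry", {
  top <- chain_topology(6, with_hydrogens = TRUE)
  conf <- build_cartesian(top, all_trans(top))
  expect_equal(nrow(conf$atoms), 6 + 2 * 4 + 6)      # CH2 x4 + 2 CH3
  hs <- conf$atoms[conf$atoms$element == "H", ]
  cs <- conf$atoms[conf$atoms$element == "C", ]
  dmin <- apply(as.matrix(hs[, 2:4]), 1, function(h)
    min(sqrt(colSums((t(as.matrix(cs[, 2:4])) - h)^2))))
  expect_lt(max(abs(dmin - 1.09)), 1e-9)
})
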