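test_that("omega handles degenerate and trivial configurations", {
  expect_error(omega(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "degenerate")
  # edges sharing an endpoint contribute exactly 0
  expect_identical(omega(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  # parallel coplanar edges
  expect_identical(omega(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  # any coplanar pair
  expect_identical(omega(c(0, 0, 0), c(1, 0, 0), c(3, -1, 0), c(2, 4, 0)), 0)
})

test_that("omega matches 2-D quadrature of the Gauss integrand", {
  set.seed(11)
  for (k in 1:10) {
    p <- random_edge_pair()
    om <- omega(p[1, ], p[2, ], p[3, ], p[4, ]) / (4 * pi)
    expect_equal(om, quad_gauss_pair(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-6)
  }
})

test_that("writhe and acn basic contracts", {
  expect_error(writhe(discrete_curve(cbind(0:3, 0, 0))), "at least 5")
  expect_error(acn(discrete_curve(cbind(0:3, 0, 0))), "at least 5")
  # planar curve: writhe identically 0
  set.seed(2)
  planar <- discrete_curve(cbind(cumsum(runif(12, 0.5, 2)),
                                 rnorm(12, sd = 3), 0))
  expect_lt(abs(writhe(planar)), 1e-10)
  # straight line: acn 0 as well
  expect_equal(acn(discrete_curve(cbind(0:6, 0, 0))), 0)
})

test_that("writhe/acn invariances hold on random curves", {
  for (seed in c(3, 17)) {
    cv <- make_random_walk(25, step = 1.5, seed = seed)
    wr <- writhe(cv)
    ac <- acn(cv)
    expect_gte(ac, abs(wr))
    moved <- rigid_motion(cv, seed = seed + 100)
    expect_equal(writhe(moved), wr, tolerance = 1e-10)
    expect_equal(acn(moved), ac, tolerance = 1e-10)
    scaled <- discrete_curve(curve_points(cv) * 7.3)
    expect_equal(writhe(scaled), wr, tolerance = 1e-10)
    expect_equal(acn(scaled), ac, tolerance = 1e-10)
    reversed <- discrete_curve(curve_points(cv)[25:1, ])
    expect_equal(writhe(reversed), wr, tolerance = 1e-10)
    expect_equal(writhe(mirror_curve(cv)), -wr, tolerance = 1e-12)
  }
})

test_that("fingerprint equals direct slice recomputation", {
  expect_error(fingerprint(discrete_curve(cbind(0:4, 0, 1:5))), "at least 6")
  cv <- make_random_walk(30, step = 1, seed = 8)
  fp <- fingerprint(cv)
  expect_equal(fp_wr(fp, 1, 30), writhe(cv), tolerance = 1e-10)
  expect_equal(fp_acn(fp, 1, 30), acn(cv), tolerance = 1e-10)
  for (i in seq_len(25)) {
    for (n in seq.int(i + 5L, 30L)) {
      sl <- curve_slice(cv, i, n)
      expect_equal(fp_wr(fp, i, n), writhe(sl), tolerance = 1e-10)
      expect_equal(fp_acn(fp, i, n), acn(sl), tolerance = 1e-10)
      expect_gte(fp_acn(fp, i, n), abs(fp_wr(fp, i, n)) - 1e-12)
    }
  }
  # undefined subsections are rejected
  expect_error(fp_wr(fp, 1, 5), "not stored")
  expect_error(fp_acn(fp, 26, 30), "not stored")
})

test_that("helix writhe profile rises almost linearly", {
  hx <- make_helix(7.58, 5.98, 7, 10)
  prof <- fp_profile(fingerprint(hx))
  interior <- prof[prof$n >= 15 & prof$n <= 60, ]
  fit <- stats::lm(wr ~ n, data = interior)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("MC projection estimate is reproducible and exact on a line", {
  line <- discrete_curve(cbind(0:9, 0, 0))
  mc <- mc_projection_estimate(line, 200, seed = 1)
  expect_identical(mc$wr, 0)
  expect_identical(mc$acn, 0)
  cv <- make_trefoil(60)
  a <- mc_projection_estimate(cv, 150, seed = 5)
  b <- mc_projection_estimate(cv, 150, seed = 5)
  expect_identical(a, b)
  expect_error(mc_projection_estimate(cv, 50), ">= 100")
})

test_that("strand passage changes writhe by about 2", {
  pp <- passage_pair()
  jump <- abs(writhe(pp$through) - writhe(pp$outside))
  expect_gt(jump, 1.5)
  expect_lt(jump, 2.5)
})

test_that("crossing_sign_sequence sees the trefoil's crossings", {
  tf <- make_trefoil(80)
  cs <- crossing_sign_sequence(tf, c(0.1, 0.15, 1))
  expect_gte(length(cs), 3)
  expect_true(all(cs %in% c(-1L, 1L)))
  # mirroring flips every crossing sign (same diagram, opposite chirality)
  cs_m <- crossing_sign_sequence(mirror_curve(tf), c(0.1, 0.15, -1))
  expect_equal(cs_m, -cs)
})
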