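test_that("segment_triangle_intersects implements the inclusive contract", {
  a <- c(0, 0, 0); b <- c(4, 0, 0); cc <- c(0, 4, 0)
  # orthogonal pierce through the interior
  expect_true(segment_triangle_intersects(a, b, cc, c(1, 1, -1), c(1, 1, 1)))
  # segment entirely on one side of the plane
  expect_false(segment_triangle_intersects(a, b, cc, c(1, 1, 0.5), c(1, 1, 3)))
  # passing outside the triangle
  expect_false(segment_triangle_intersects(a, b, cc, c(5, 5, -1), c(5, 5, 1)))
  # exactly through a vertex: touching counts
  expect_true(segment_triangle_intersects(a, b, cc, c(4, 0, -1), c(4, 0, 1)))
  # endpoint resting on the triangle counts
  expect_true(segment_triangle_intersects(a, b, cc, c(1, 1, 0), c(1, 1, 5)))
  # coplanar segment crossing the triangle
  expect_true(segment_triangle_intersects(a, b, cc, c(-1, 1, 0), c(5, 1, 0)))
  # coplanar segment fully outside
  expect_false(segment_triangle_intersects(a, b, cc, c(-1, 5, 0), c(5, 5, 0)))
  # degenerate (collinear) triangle never intersects
  expect_false(segment_triangle_intersects(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                           c(1, 0, -1), c(1, 0, 1)))
})

test_that("unpierced sections reduce to single edges", {
  mb <- make_mock_backbone(list(c("H", 12)), seed = 1)
  sk <- skmt(pair_backbone(mb$curve, mb$ss))
  expect_equal(skmt_length(sk), 2L)
  expect_equal(sk$provenance, c(1L, 12L))

  mb3 <- make_mock_backbone(list(c("H", 10), c("C", 5), c("H", 10)), seed = 2)
  sk3 <- skmt(pair_backbone(mb3$curve, mb3$ss))
  expect_equal(skmt_length(sk3), 4L)
  expect_equal(sk3$provenance, c(1L, 11L, 16L, 25L))

  mb2 <- make_mock_backbone(list(c("H", 10), c("C", 4), c("E", 6)), seed = 3)
  sk2 <- skmt(pair_backbone(mb2$curve, mb2$ss))
  # 4 section-boundary points plus any retained linker points
  expect_gte(skmt_length(sk2), 4L)
  expect_true(all(c(1L, 11L, 15L, 20L) %in% sk2$provenance))
})

test_that("skmt preserves endpoints, order and point count", {
  mb <- make_mock_backbone(list(c("H", 8), c("C", 6), c("E", 5), c("C", 4)),
                           seed = 9)
  bb <- pair_backbone(mb$curve, mb$ss)
  sk <- skmt(bb)
  expect_lte(skmt_length(sk), n_points(mb$curve))
  expect_true(all(diff(sk$provenance) > 0))
  expect_equal(sk$provenance[1], 1L)
  expect_equal(sk$provenance[length(sk$provenance)], n_points(mb$curve))
  expect_equal(curve_points(sk)[1, ], curve_points(mb$curve)[1, ])
  expect_equal(skmt_length(sk), length(sk$provenance))
})

test_that("threading is preserved: linker keeps its witnessing point", {
  tb <- threaded_backbone()
  sk <- skmt(tb)
  # the hook's interior (residue 11) survives; boundaries 1, 6, 10, 14, 17
  expect_true(11L %in% sk$provenance)
  expect_gte(skmt_length(sk), 6L)
  # whole-curve entanglement pattern preserved
  expect_equal(crossing_sign_sequence(sk), crossing_sign_sequence(tb$curve))
  expect_lt(abs(writhe(sk) - writhe(tb$curve)), 0.5)

  ub <- unthreaded_backbone()
  sku <- skmt(ub)
  expect_equal(sku$provenance, c(1L, 6L, 10L, 14L, 17L))
  expect_equal(crossing_sign_sequence(sku), crossing_sign_sequence(ub$curve))
  expect_lt(abs(writhe(sku) - writhe(ub$curve)), 0.5)
})

test_that("a sectioned trefoil keeps its writhe through smoothing", {
  tf <- make_trefoil(120, scale = 5)
  labels <- rep(rep(c("H", "C"), each = 10), length.out = 120)
  sk <- skmt(pair_backbone(tf, ss_assignment(labels)))
  expect_lt(abs(writhe(sk) - writhe(tf)), 0.5)
  expect_gt(skmt_length(sk), 2L)
})

test_that("chain breaks act as immovable section boundaries", {
  pts <- cbind(c(seq(0, 5) * 3.8, seq(0, 4) * 3.8 + 40), 0, 0)
  cv <- discrete_curve(pts)
  attr(cv, "breaks") <- 6L
  bb <- pair_backbone(cv, ss_assignment(rep("C", 11)))
  sk <- skmt(bb)
  expect_true(all(c(6L, 7L) %in% sk$provenance))
})

test_that("skmt is idempotent on its own output", {
  ub <- unthreaded_backbone()
  sk <- skmt(ub)
  labels2 <- ub$ss$labels[sk$provenance]
  sk2 <- skmt(pair_backbone(sk$curve, ss_assignment(labels2)))
  expect_equal(curve_points(sk2), curve_points(sk))
})

test_that("smoothed curves serialize to JSON with provenance", {
  mb <- make_mock_backbone(list(c("H", 8), c("C", 4)), seed = 5)
  sk <- skmt(pair_backbone(mb$curve, mb$ss))
  obj <- jsonlite::fromJSON(smoothed_to_json(sk))
  expect_equal(obj$skmt_length, skmt_length(sk))
  expect_equal(obj$provenance, sk$provenance)
})
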