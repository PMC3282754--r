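test_that("map similarity is a Pearson correlation on jointly valid pixels", {
  A <- gaussian_rate_map(c(6, 2), width = 4, arena_radius = 15)
  s <- map_similarity(A, A)
  expect_equal(s$r, 1)
  expect_true(is.finite(s$z))
  expect_equal(s$n_pixels, sum(A$valid))

  B <- A
  B$rate <- A$rate + 2      # affine shift leaves the correlation at 1
  expect_equal(map_similarity(A, B)$r, 1)

  expect_error(map_similarity(A, flat_map(matrix(1, 5, 5))),
               class = "pf_error_geometry")
  const <- A; const$rate[const$valid] <- 1
  expect_error(map_similarity(A, const), class = "pf_error_degenerate")
})

test_that("independent random maps correlate near zero on average", {
  set.seed(53)
  geom <- map_geometry(15, 1)
  rs <- replicate(100, {
    r1 <- matrix(rexp(900), 30, 30)
    r2 <- matrix(rexp(900), 30, 30)
    occ <- matrix(1, 30, 30); occ[!geom$in_arena] <- 0
    map_similarity(rate_map(r1, occ, geom, valid = geom$in_arena),
                   rate_map(r2, occ, geom, valid = geom$in_arena))$r
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("rotation search recovers constructed rotations of a smooth field", {
  rot2d <- function(p, th) {
    r <- th * pi / 180
    c(cos(r) * p[1] - sin(r) * p[2], sin(r) * p[1] + cos(r) * p[2])
  }
  ctr <- c(7, 0)
  A <- gaussian_rate_map(ctr, width = 4.5, arena_radius = 15)
  self <- best_rotation(A, A)
  expect_equal(self$best_angle, 0)
  expect_equal(self$max_r, 1)

  B <- gaussian_rate_map(rot2d(ctr, 90), width = 4.5, arena_radius = 15)
  r <- best_rotation(A, B)
  expect_lte(abs(r$abs_rotation - 90), 2)
  expect_lte(min(abs(r$best_angle - 270), 360 - abs(r$best_angle - 270)), 2)
  expect_gte(r$max_r, r$r_by_angle["0"])   # max is at least the unrotated r
})

test_that("an unstructured map cannot be rotated into a smooth field", {
  A <- gaussian_rate_map(c(7, 0), width = 4.5, arena_radius = 15)
  set.seed(59)
  B <- A
  B$rate[B$valid] <- 1 + rnorm(sum(B$valid), 0, 0.1)
  expect_lt(best_rotation(A, B)$max_r, 0.3)
})

test_that("cue classification follows the 90-degree-arc rule", {
  expect_equal(classify_cue_following(5, 90), "distal")
  expect_equal(classify_cue_following(88, 90), "local")
  expect_equal(classify_cue_following(180, 90), "remap")
  # exact 45-degree boundary falls to remap (half-open windows)
  expect_equal(classify_cue_following(45, 90), "remap")
  expect_equal(classify_cue_following(44.9, 90), "distal")
  # symmetric under the sign of the card rotation
  for (ang in c(5, 44, 88, 135, 200, 310)) {
    expect_equal(classify_cue_following(ang, 90),
                 classify_cue_following(-ang, -90))
  }
})

test_that("within-cell stability exceeds the random-pair baseline", {
  # stable distal cells over two identical-cue sessions
  co <- generate_cohort(8, group_params(),
                        cohort_protocol(card_angles = c(0, 0), duration = 400),
                        master_seed = 61)
  maps <- lapply(co, function(cell) lapply(cell$sessions, function(s)
    compute_rate_map(s$spikes, s$track, 15)))
  within <- vapply(maps, function(m) map_similarity(m[[1]], m[[2]])$z, numeric(1))
  baseline <- random_pair_baseline(lapply(maps, `[[`, 1), seed = 62)
  expect_lt(abs(mean(baseline)), 0.25)    # chance level
  expect_gt(min(within), quantile(baseline, 0.95))
  # two cells -> the single cross pair
  expect_length(random_pair_baseline(list(maps[[1]][[1]], maps[[2]][[1]])), 1)
})
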