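test_that("grid generation is deterministic, partitions regions and zones", {
  g1 <- generate_grid(4, 4, seed = 7)
  g2 <- generate_grid(4, 4, seed = 7)
  expect_identical(g1, g2)
  expect_false(identical(g1$grass_frac, generate_grid(4, 4, seed = 8)$grass_frac))

  g <- generate_grid(10, 10, seed = 1)
  expect_equal(nrow(g), 100)
  expect_equal(sum(table(g$zone)), 100)
  expect_true(all(g$zone %in% c("cold", "temperate", "mediterranean")))
  # every cell belongs to exactly one region and regions tile the grid
  expect_false(anyNA(g$region))
  expect_true(all(table(g$region) >= 1))
  expect_true(all(g$grass_frac >= 0 & g$grass_frac <= 1))
  expect_true(all(diff(unique(g$lat)) > 0))

  expect_error(generate_grid(0, 3), "dimensions")

  single <- generate_grid(1, 1, seed = 0)
  expect_equal(nrow(single), 1)
  expect_equal(length(unique(single$region)), 1)
})

test_that("meteorology honours its invariants and generator parameters", {
  g <- generate_grid(2, 2, seed = 4)
  met <- generate_meteo(g, 5, seed = 3)
  expect_equal(nrow(met$temp), 5 * 365)
  expect_true(all(met$precip >= 0))
  expect_true(all(met$rad >= 0))
  expect_true(all(met$rh >= 0 & met$rh <= 1))

  # sample mean temperature close to the profile mean for each cell's zone
  prof <- climate_profile()
  for (j in seq_len(nrow(g))) {
    expect_lt(abs(mean(met$temp[, j]) - prof[[g$zone[j]]]$t_mean), 0.5)
  }

  # degenerate profiles: no amplitude/noise -> constant; no wet days -> dry
  flat <- lapply(climate_profile(), function(p) {
    p$t_amp <- 0; p$t_sd <- 0; p$wet_prob <- 0; p
  })
  met0 <- generate_meteo(g, 1, seed = 1, profile = flat)
  for (j in seq_len(nrow(g))) {
    expect_equal(unique(met0$temp[, j]), prof[[g$zone[j]]]$t_mean)
  }
  expect_true(all(met0$precip == 0))

  expect_error(generate_meteo(g, 0), "years")
  expect_error(generate_meteo(g, 1, profile = list(cold = list(t_mean = 1))))
})

test_that("meteo generation is seed-reproducible", {
  g <- generate_grid(2, 1, seed = 1)
  m1 <- generate_meteo(g, 2, seed = 11)
  m2 <- generate_meteo(g, 2, seed = 11)
  m3 <- generate_meteo(g, 2, seed = 12)
  expect_identical(m1, m2)
  expect_false(identical(m1$precip, m3$precip))
})

test_that("CO2 trajectories follow their growth laws", {
  expect_equal(unname(co2_series(1900, 1950, 296, 0)), rep(296, 51))
  expect_equal(unname(co2_series(2000, 2002, 296, 1)), c(296, 297, 298))
  expect_equal(unname(co2_series(2000, 2001, 300, 0.005, "exponential")),
               c(300, 301.5))
  expect_true(all(diff(co2_series(1900, 2000, 296, 0.003, "exponential")) > 0))
  expect_error(co2_series(1900, 1950, -1), "positive")
  expect_error(co2_series(1950, 1900, 296), "end_year")
})

test_that("nitrogen timeline applies the historical reconstruction rules", {
  g <- generate_grid(1, 2, seed = 1)
  ref <- data.frame(organic = c(20, 0), mineral = c(50, 10),
                    deposition = c(8, 0))
  tl <- nitrogen_timeline(g, ref, 1940, 1970)
  c1 <- tl[tl$cell == 1, ]
  # mineral: zero before 1951, linear ramp 1951-1960, full level from 1961
  expect_equal(c1$mineral[c1$year == 1940], 0)
  expect_equal(c1$mineral[c1$year == 1951], 5)    # 1/10 of reference
  expect_equal(c1$mineral[c1$year == 1956], 30)   # 6/10 of reference
  expect_equal(c1$mineral[c1$year == 1961], 50)
  expect_equal(c1$mineral[c1$year == 1970], 50)
  # organic constant over time
  expect_equal(unique(c1$organic), 20)
  # totals are component sums and non-negative
  expect_equal(tl$n_amount, tl$organic + tl$mineral + tl$deposition)
  expect_true(all(tl$n_amount >= 0))

  # deposition anchors interpolated linearly between decade midpoints
  tl2 <- nitrogen_timeline(g, ref, 1950, 1970,
                           deposition_anchors = c("1945" = 0.5, "1955" = 1,
                                                  "1965" = 2))
  d1 <- tl2[tl2$cell == 1, ]
  expect_equal(d1$deposition[d1$year == 1955], 8)
  expect_equal(d1$deposition[d1$year == 1960], 8 * 1.5)
  expect_equal(d1$deposition[d1$year == 1970], 16)  # flat beyond last anchor

  expect_error(nitrogen_timeline(g, data.frame(organic = -1, mineral = 0,
                                               deposition = 0)[c(1, 1), ],
                                 1950, 1951), "non-negative")
})

test_that("mineral scaling after the ramp follows the supplied series", {
  g <- generate_grid(1, 1, seed = 1)
  ref <- data.frame(organic = 0, mineral = 40, deposition = 0)
  tl <- nitrogen_timeline(g, ref, 1960, 1980,
                          mineral_scaling = c("1961" = 1, "1980" = 2))
  expect_equal(tl$mineral[tl$year == 1961], 40)
  expect_equal(tl$mineral[tl$year == 1980], 80)
  # interpolated between scaling anchors
  expect_gt(tl$mineral[tl$year == 1970], 40)
  expect_lt(tl$mineral[tl$year == 1970], 80)
})

test_that("tiled meteo is exactly stationary", {
  g <- generate_grid(1, 1, seed = 1)
  m1 <- generate_meteo(g, 2, seed = 5)
  tiled <- tile_meteo(m1, 5, source_years = 1)
  expect_equal(tiled$years, 5)
  for (y in 2:5) {
    expect_identical(tiled$temp[1:365, ], tiled$temp[(y - 1) * 365 + 1:365, ])
  }
})
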