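# Quantification: thickness estimators, binned apical positions, turnover,
# transit, healing, stability statistics.

slab_fixture <- function(super_y, basal_y, W = 40, H = 60) {
  cfg <- tiny_config(W, H)
  cfg$geometry$stroma_depth <- 5L
  cfg$geometry$limbal_voxels <- 8L
  sim <- empty_state(W, H, cfg)
  add_cell(sim, "BASAL", rep(0:(W - 1), 2), rep(basal_y + 0:1 - 0L, each = W))
  add_cell(sim, "SUPER", rep(0:(W - 1), 2), rep(super_y + 0:1, each = W))
  sim
}

test_that("COM thickness equals the layer-centroid separation in micrometers", {
  # SUPER slab centered at y = 35 (rows 34-35 -> 34.5), BASAL at y = 10
  sim <- slab_fixture(super_y = 34, basal_y = 10)
  sim$cells$sumy[] <- sim$cells$sumy[]  # no-op; state already consistent
  # centroids: super 34.5, basal 10.5 -> (34.5 - 10.5) * 2 = 48; shift the
  # slabs so the separation is exactly 25 rows -> 50 um
  sim2 <- slab_fixture(super_y = 35, basal_y = 10)
  expect_equal(thickness_com(sim2, x_range = c(0, 39)), 25 * 2)
  # equal centroid depth -> zero (layers side by side in x)
  sim3 <- empty_state(40, 60, tiny_config(40, 60))
  add_cell(sim3, "BASAL", rep(0:19, 2), rep(10:11, each = 20))
  add_cell(sim3, "SUPER", rep(20:39, 2), rep(10:11, each = 20))
  expect_equal(thickness_com(sim3, x_range = c(0, 39)), 0)
  # missing layer -> sentinel
  sim4 <- empty_state(10, 10)
  add_cell(sim4, "BASAL", 0:9, rep(2L, 10))
  expect_true(is.na(thickness_com(sim4)))
})

test_that("segment top positions partition the axis and track step fixtures", {
  # flat fixture: uniform top row at y = 30 -> all bins 60 um
  sim <- slab_fixture(super_y = 29, basal_y = 10)
  segs <- segment_top_positions(sim, n_bins = 10)
  expect_identical(segs$bin, 0:9)
  expect_true(all(segs$top_um == 60))
  # step fixture: left half top y = 40, right half top y = 25
  cfg <- tiny_config(40, 60)
  sim2 <- empty_state(40, 60, cfg)
  add_cell(sim2, "WING", rep(0:19, 2), rep(39:40, each = 20))
  add_cell(sim2, "WING", rep(20:39, 2), rep(24:25, each = 20))
  segs2 <- segment_top_positions(sim2, n_bins = 10)
  expect_true(all(segs2$top_um[1:5] == 80))
  expect_true(all(segs2$top_um[6:10] == 50))
  expect_error(segment_top_positions(sim2, n_bins = 7), "divide")
})

test_that("bin thickness and COM thickness agree on flat synthetic tissue", {
  cfg <- tiny_config(40, 60)
  cfg$geometry$stroma_depth <- 10L
  sim <- empty_state(40, 60, cfg)
  add_cell(sim, "MEMB", 0:39, rep(10L, 40))
  add_cell(sim, "BASAL", 0:39, rep(11L, 40))
  add_cell(sim, "WING", rep(0:39, 10), rep(12:21, each = 40))
  add_cell(sim, "SUPER", 0:39, rep(22L, 40))
  com <- thickness_com(sim, x_range = c(0, 39))
  bins <- segment_top_positions(sim)$thickness_um
  expect_lt(abs(mean(bins) - com) / mean(bins), 0.2)
})

test_that("turnover time finds the 95% substitution day per region", {
  mk_census <- function(day, limbal, peripheral)
    list(day = day, limbal = limbal, peripheral = peripheral)
  # peripheral ids fully replaced by day 3; limbal immortal
  cens <- list(
    mk_census(0, 1:10, 101:120),
    mk_census(1, 1:10, c(101:110, 201:210)),
    mk_census(2, 1:10, c(101:104, 211:226)),
    mk_census(3, 1:10, 301:320),
    mk_census(4, 1:10, 401:420)
  )
  expect_equal(turnover_time(cens, "peripheral", reference_day = 0), 3)
  expect_true(is.na(turnover_time(cens, "limbal", reference_day = 0)))
  ss <- substitution_series(cens, "peripheral", 0)
  expect_true(all(diff(ss$substituted) >= 0))
  expect_equal(ss$substituted[1], 0)
})

test_that("layer transit time averages lifetime over layers traversed", {
  ev <- tibble::tibble(
    mcs = c(0, 0, 240 * 1, 240 * 3, 240 * 5, 240 * 7,
            240 * 2, 240 * 6, 240 * 14),
    id = c(1L, 2L, 1L, 1L, 1L, 1L, 2L, 2L, 2L),
    event = c("divide", "divide", "differentiate", "differentiate",
              "differentiate", "slough", "differentiate", "differentiate",
              "slough"),
    old_type = NA_character_, new_type = NA_character_
  )
  # cell 1: born day 0, 3 transitions -> 4 layers, sloughed day 7 -> 1.75
  # cell 2: born day 0, 2 transitions -> 3 layers, sloughed day 14 -> 14/3
  out <- layer_transit_time(ev, day_to_mcs = 240)
  expect_equal(out$n_trajectories, 2L)
  expect_equal(out$mean_days_per_layer, mean(c(7 / 4, 14 / 3)))
  empty <- layer_transit_time(ev[0, ])
  expect_true(is.na(empty$mean_days_per_layer))
})

test_that("healing time combines closure with the thickness band and counts
           recurrences", {
  base <- tibble::tibble(
    mcs = seq(0, 240 * 3, by = 120),
    day = mcs / 240,
    thickness_um = 50, wound_open = 0
  )
  # closes (and recovers thickness) at day 4 post-injury
  post <- tibble::tibble(
    mcs = 240 * 3 + seq(120, 240 * 6, by = 120),
    day = mcs / 240,
    thickness_um = c(30, 32, 35, 38, 42, 44, 44, 44, 50, 50, 50, 50),
    wound_open = c(0.4, 0.3, 0.2, 0.2, 0.1, 0.05, 0, 0, 0, 0, 0, 0)
  )
  m <- rbind(base, post)
  h <- healing_time(m, injury_mcs = 240 * 3)
  expect_equal(h$baseline_thickness, 50)
  expect_equal(h$closure_days, 3.5)
  expect_equal(h$healing_days, 4.5)   # thickness re-enters the band later
  expect_equal(h$recurrences, 0L)
  # a series with no injury effect heals immediately
  h0 <- healing_time(base, injury_mcs = 120)
  expect_equal(h0$healing_days, 0.5)
  # reopening after closure counts as a recurrence
  post2 <- post
  post2$wound_open[9:10] <- c(0.2, 0.1)
  h2 <- healing_time(rbind(base, post2), injury_mcs = 240 * 3)
  expect_gte(h2$recurrences, 1L)
  expect_error(healing_time(base, injury_mcs = 1e6), "before")
})

test_that("stability statistics: constant, alternating, and replicate series", {
  m <- tibble::tibble(day = rep(1:10, each = 2),
                      n_stem = 7, n_basal = 12,
                      n_wing = rep(c(10, 12), 10),
                      n_super = 50)
  st <- population_stability_stats(m, from_day = 1)
  expect_equal(st$sd[st$type == "STEM"], 0)
  expect_equal(st$mean[st$type == "WING"], 11)
  expect_equal(st$sd[st$type == "WING"], sd(rep(c(10, 12), 10)))
})

test_that("stratification and homeostasis detectors behave on synthetic series", {
  mk <- function(day, s, b, w, sp, yb, yw, ys, th) tibble::tibble(
    mcs = day * 240, day = day, n_stem = s, n_basal = b, n_wing = w,
    n_super = sp, thickness_um = th, wound_open = 0,
    y_basal = yb, y_wing = yw, y_super = ys,
    bin_top = list(rep(50, 10)), bin_thickness = list(rep(30, 10)))
  m <- dplyr::bind_rows(
    mk(1, 5, 0, 0, 0, 24, NA, NA, NA),
    mk(2, 5, 3, 2, 0, 24, 27, NA, NA),
    mk(3, 5, 4, 3, 2, 24, 30, 26, 20),   # present but mis-ordered
    mk(4, 5, 5, 6, 3, 24, 28, 33, 30),   # ordered: first stratified day
    mk(5, 5, 5, 8, 5, 24, 28, 34, 32)
  )
  expect_equal(stratification_day(m), 4)
  # homeostasis: counts and thickness flat from day 4 onward
  flat <- dplyr::bind_rows(lapply(1:12, function(d)
    mk(d, 7, 12, min(10 * d, 40), min(12 * d, 50), 24, 30, 40,
       min(20 + 5 * d, 48))))
  hd <- homeostasis_day(flat)
  expect_true(hd >= 6 && hd <= 10)
})
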