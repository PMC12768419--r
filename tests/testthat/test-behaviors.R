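# Cell rules: Hill factors, pressure, growth calibration, mitosis,
# differentiation truth table, sloughing statistics, chemical death.

test_that("Hill growth factors: midpoints, limits, and derived values", {
  expect_equal(egf_growth_factor(3.5, 3.5), 0.5)
  expect_equal(egf_growth_factor(0, 3.5), 0)
  # EGF at twice the stem half-max: 7^4 / (3.5^4 + 7^4) = 2401/2551.0625
  expect_equal(egf_growth_factor(7, 3.5), 2401 / 2551.0625)
  expect_equal(egf_growth_factor(7, 3.5), 0.941176, tolerance = 1e-6)
  expect_equal(density_growth_factor(0, 125), 1)
  expect_equal(density_growth_factor(125, 125), 0.5)
  # pressure at twice the half-max: 125^4/(125^4 + 250^4) = 1/17
  expect_equal(density_growth_factor(250, 125), 1 / 17)
  expect_error(egf_growth_factor(-1, 3.5), ">= 0")
  expect_error(density_growth_factor(10, 0), "> 0")
  # both factors bounded in [0, 1] over a sweep
  x <- seq(0, 1e3, length.out = 200)
  expect_true(all(egf_growth_factor(x, 7) >= 0 & egf_growth_factor(x, 7) <= 1))
  expect_true(all(density_growth_factor(x, 125) >= 0 &
                    density_growth_factor(x, 125) <= 1))
})

test_that("pressure proxy clamps at zero and scales with the volume deficit", {
  expect_equal(cell_pressure(25, 25, 25), 0)
  expect_equal(cell_pressure(30, 25, 25), 0)     # overfilled -> clamped
  expect_equal(cell_pressure(25, 30, 2), 10)
  expect_true(all(diff(cell_pressure(25, 25 + 0:10, 25)) >= 0))
})

test_that("a fully stimulated, uncrowded cell doubles its target volume in 80 MCS", {
  sim <- empty_state(12, 12)
  id <- add_cell(sim, "BASAL", rep(3:7, 5), rep(3:7, each = 5), tvol = 25)
  sim$fields$egf <- rep(1e4, 144)   # saturating EGF
  # keep volume pinned at target so pressure stays ~0 (uncrowded)
  n80 <- 0
  for (i in 1:81) {
    sim$cells$volume[id] <- sim$cells$tvol[id]
    apply_growth(sim)
    if (sim$cells$tvol[id] >= 50 && n80 == 0) n80 <- i
  }
  expect_true(abs(n80 - 80) <= 1)
  # zero EGF: no growth at all
  sim2 <- empty_state(12, 12)
  id2 <- add_cell(sim2, "BASAL", rep(3:7, 5), rep(3:7, each = 5), tvol = 25)
  sim2$fields$egf <- numeric(144)
  apply_growth(sim2)
  expect_equal(sim2$cells$tvol[id2], 25)
})

test_that("mitosis triggers at 50 voxels and splits volumes within one voxel", {
  set.seed(8)
  for (type in c("STEM", "BASAL")) {
    for (nvox in c(49, 50, 51, 57)) {
      sim <- empty_state(16, 16)
      vox <- expand.grid(x = 3:10, y = 3:10)[seq_len(nvox), ]
      id <- add_cell(sim, type, vox$x, vox$y, tvol = 50)
      sim$mcs <- 5L
      daughters <- apply_mitosis(sim)
      if (nvox < 50) {
        expect_length(daughters, 0)
        expect_true(sim$cells$alive[id])
      } else {
        expect_length(daughters, 2)
        v <- sim$cells$volume[daughters]
        expect_equal(sum(v), nvox)                 # conservation
        expect_lte(abs(v[1] - v[2]), 1)            # equal within one voxel
        expect_false(sim$cells$alive[id])
        expect_equal(sim$cells$tvol[daughters], c(25, 25))
        if (type == "STEM") {
          # vertical cleavage: daughters separated along x
          cx <- sim$cells$sumx[daughters] / v
          expect_gt(abs(cx[1] - cx[2]), 1)
        }
      }
    }
  }
})

test_that("differentiation truth table including the contact-area boundary", {
  # STEM -> BASAL iff no limbal-membrane contact
  sim <- mini_tissue()
  on_limb <- add_cell(sim, "STEM", rep(1:5, 2), rep(5:6, each = 5), tvol = 10)
  off_limb <- add_cell(sim, "STEM", rep(8:12, 2), rep(7:8, each = 5), tvol = 10)
  sim$mcs <- 3L
  changed <- apply_differentiation(sim)
  expect_false(on_limb %in% changed)
  expect_true(off_limb %in% changed)
  expect_equal(type_name(sim$cells$ctype[off_limb]), "BASAL")

  # BASAL -> WING at membrane face-contact area <= 5; stays basal at 6
  for (w in c(5L, 6L)) {
    sim <- mini_tissue()
    id <- add_cell(sim, "BASAL", rep(7:(6 + w), 2), rep(5:6, each = w), tvol = 2 * w)
    sim$mcs <- 3L
    apply_differentiation(sim)
    expect_equal(type_name(sim$cells$ctype[id]),
                 if (w <= 5) "WING" else "BASAL")
  }

  # WING -> SUPER needs tear AND wing contact AND no basal/membrane/stem
  mk_wing <- function(neighbors) {
    sim <- empty_state(14, 14)
    id <- add_cell(sim, "WING", rep(5:7, 2), rep(5:6, each = 3), tvol = 6)
    if ("TEAR" %in% neighbors) add_cell(sim, "TEAR", 5:7, rep(7L, 3))
    if ("WING" %in% neighbors) add_cell(sim, "WING", rep(3:4, 2), rep(5:6, each = 2))
    if ("BASAL" %in% neighbors) add_cell(sim, "BASAL", 5:7, rep(4L, 3))
    if ("SUPER" %in% neighbors) add_cell(sim, "SUPER", rep(8L, 2), 5:6)
    sim$mcs <- 3L
    apply_differentiation(sim)
    type_name(sim$cells$ctype[id])
  }
  expect_equal(mk_wing(c("TEAR", "WING", "SUPER")), "SUPER")
  expect_equal(mk_wing(c("TEAR", "BASAL", "WING")), "WING")   # lower contact
  expect_equal(mk_wing(c("TEAR"))[1], "WING")                 # no wing neighbor
  expect_equal(mk_wing(c("WING"))[1], "WING")                 # no tear contact
})

test_that("differentiation never reverses and skips newborns", {
  sim <- mini_tissue()
  id <- add_cell(sim, "STEM", rep(10:12, 2), rep(7:8, each = 3), tvol = 6)
  sim$mcs <- 0L  # birth == mcs: must be skipped
  expect_length(apply_differentiation(sim), 0)
  sim$mcs <- 1L
  apply_differentiation(sim)
  expect_equal(type_name(sim$cells$ctype[id]), "BASAL")
  # a SUPER cell has no outgoing rule
  sup <- add_cell(sim, "SUPER", 14:16, rep(8L, 3), tvol = 3)
  sim$mcs <- 5L
  apply_differentiation(sim)
  expect_equal(type_name(sim$cells$ctype[sup]), "SUPER")
})

test_that("sloughing probability, exposure requirement, and geometric lifetimes", {
  expect_equal(slough_probability(list(lifetime_days = 3, day_to_mcs = 240L)),
               1 / 720)
  # a SUPER cell without tear contact never sloughs
  set.seed(2)
  sim <- empty_state(10, 10)
  id <- add_cell(sim, "SUPER", rep(4:6, 2), rep(4:5, each = 3), tvol = 6)
  sim$mcs <- 10L
  for (i in 1:300) expect_length(apply_sloughing(sim), 0)
  expect_true(sim$cells$alive[id])

  # lifetimes under the per-MCS rule are geometric with mean 720 MCS:
  # simulate 1e4 exposed lifetimes with the engine's probability
  set.seed(123)
  p <- 1 / 720
  n <- 1e4
  alive <- rep(TRUE, n)
  life <- integer(n)
  t <- 0L
  while (any(alive) && t < 2e4) {
    t <- t + 1L
    die <- alive & runif(n) < p
    life[die] <- t
    alive[alive & die] <- FALSE
    alive <- alive & !die
  }
  life <- life[life > 0]
  expect_gt(length(life), 9900)
  expect_lt(abs(mean(life) - 720) / 720, 0.02)
  # chi-square goodness of fit against the geometric distribution
  brk <- c(0, 240, 480, 720, 1080, 1440, 2160, Inf)
  obs <- table(cut(life, brk))
  pr <- diff(pgeom(brk, p))
  chi <- suppressWarnings(chisq.test(as.vector(obs), p = pr / sum(pr)))
  expect_gt(chi$p.value, 0.001)
})

test_that("chemical death marks, shrinks, and removes cells above threshold", {
  sim <- mini_tissue()
  cfg <- sim$config
  cfg$injury <- injury_spec("chemical", trigger_mcs = 0, dose = 1,
                            cell_threshold = 0.5, death_rate = 2)
  sim$config <- cfg
  id <- add_cell(sim, "WING", rep(8:10, 2), rep(7:8, each = 3), tvol = 6)
  safe <- add_cell(sim, "WING", rep(13:15, 2), rep(7:8, each = 3), tvol = 6)
  sim$fields$chem <- numeric(sim$W * sim$H)
  sim$fields$chem[which(sim$spin == id)] <- 1.0   # above threshold
  sim$mcs <- 2L
  apply_injury_death(sim)
  expect_true(sim$cells$dying[id])
  expect_false(sim$cells$dying[safe])
  tv <- sim$cells$tvol[id]
  apply_injury_death(sim)
  expect_equal(sim$cells$tvol[id], max(0, tv - 2))  # strictly decreasing
  # once the Potts dynamics have shrunk it below 3 voxels it is removed
  sim$spin[sim$spin == id][-(1:2)] <- 0L
  refresh_stats(sim)
  removed <- apply_injury_death(sim)
  expect_true(id %in% removed)
  expect_false(sim$cells$alive[id])
  # infinite threshold: nothing ever dies
  sim$config$injury$cell_threshold <- Inf
  sim$fields$chem[] <- 100
  expect_length(apply_injury_death(sim), 0)
})
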