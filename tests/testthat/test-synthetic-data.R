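test_that("acquisition arithmetic and validation", {
  cfg <- acquisition_config()
  expect_equal(cfg$n_cycles, 400L)
  expect_equal(cfg$field_side, 236)
  expect_equal(acquisition_config(interval = 5, duration = 1)$n_cycles, 12L)
  expect_error(acquisition_config(field_side = -1), "field_side")
  expect_error(acquisition_config(interval = 0), "interval")
  expect_error(acquisition_config(initial_cells_min = 10,
                                  initial_cells_max = 5),
               "initial_cells_min")
})

test_that("archetype_spec rejects invalid specifications", {
  a <- builtin_archetypes()$control
  bad <- a$knots
  bad$area[1, "value"] <- 5000        # outside the 0-1000 calibration range
  expect_error(archetype_spec("x", bad), "calibration range")
  unsorted <- a$knots
  unsorted$area <- unsorted$area[nrow(unsorted$area):1, , drop = FALSE]
  expect_error(archetype_spec("x", unsorted), "sorted")
  expect_error(archetype_spec("x", a$knots, noise_autocorr = 1), "0, 1")
  expect_error(archetype_spec("x", a$knots, division_rate = -0.1),
               "division_rate")
  expect_error(archetype_spec("x", a$knots, death_hazard = 1.5),
               "death_hazard")
})

test_that("noise-free simulation reproduces the archetype mean exactly", {
  cfg <- acquisition_config(duration = 2, initial_cells_min = 3,
                            initial_cells_max = 3)
  rec <- simulate_trajectories(cfg, noiseless(builtin_archetypes()$control),
                               seed = 1)
  # all cells identical at every cycle
  by_cycle <- split(rec$area, rec$cycle)
  expect_true(all(vapply(by_cycle, function(v) diff(range(v)) == 0,
                         logical(1))))
  # knot interpolation: control area runs 400 -> 550 over 20 h
  h <- rec$cycle[rec$cell_id == "c001"] * cfg$interval / 60
  expect_equal(rec$area[rec$cell_id == "c001"], 400 + (550 - 400) * h / 20,
               tolerance = 1e-12)
})

test_that("derived record identities hold exactly", {
  cfg <- acquisition_config()
  rec <- simulate_trajectories(cfg, builtin_archetypes()$stabilizer,
                               seed = 4)
  expect_equal(rec$area_pct, 100 * rec$area / cfg$field_side^2)
  expect_lt(max(abs(rec$form_factor * rec$compactness - 1)), 1e-12)
  expect_equal(rec$mean_ri, 1.333 + 0.19 * rec$dmd)
  # conservation: dmd * volume = dry mass to 1e-9 relative
  expect_lt(max(abs(rec$dmd * rec$volume - rec$dry_mass) / rec$dry_mass),
            1e-9)
  expect_true(all(rec$eccentricity >= 0 & rec$eccentricity <= 1))
  expect_true(all(rec$area > 0 & rec$perimeter > 0 & rec$dry_mass > 0 &
                  rec$dmd > 0))
})

test_that("initial cells have full-length tracks and counts in range", {
  cfg <- acquisition_config(duration = 2)
  for (s in 1:5) {
    rec <- simulate_trajectories(cfg, builtin_archetypes()$control, seed = s)
    n0 <- length(unique(rec$cell_id[rec$cycle == 1]))
    expect_gte(n0, 15)
    expect_lte(n0, 25)
    first_cells <- unique(rec$cell_id[rec$cycle == 1])
    tab <- table(rec$cell_id[rec$cell_id %in% first_cells])
    expect_true(all(tab == cfg$n_cycles))  # control never dies
  }
})

test_that("count law: no division and no death gives n_cells * n_cycles rows", {
  cfg <- acquisition_config(duration = 3, initial_cells_min = 7,
                            initial_cells_max = 7)
  a <- noiseless(builtin_archetypes()$disruptor)   # events stripped
  rec <- simulate_trajectories(cfg, a, seed = 2)
  expect_equal(nrow(rec), 7 * cfg$n_cycles)
})

test_that("simulation is bit-reproducible from the seed", {
  cfg <- acquisition_config(duration = 2)
  a <- builtin_archetypes()$disruptor
  expect_identical(simulate_trajectories(cfg, a, seed = 9),
                   simulate_trajectories(cfg, a, seed = 9))
  expect_false(identical(simulate_trajectories(cfg, a, seed = 9),
                         simulate_trajectories(cfg, a, seed = 10)))
})

test_that("builtin archetypes encode the stated dynamics", {
  arcs <- builtin_archetypes()
  expect_setequal(names(arcs), c("control", "stabilizer", "disruptor"))
  cfg <- acquisition_config(initial_cells_min = 1, initial_cells_max = 1)
  rng <- calibration_ranges()
  for (a in arcs) {
    for (p in names(a$knots)) {
      k <- a$knots[[p]]
      expect_true(all(k[, "value"] >= rng[[p]][1] &
                      k[, "value"] <= rng[[p]][2]))
    }
  }
  # stabilizer: dry mass density strictly decreasing through cycles 1..200
  st <- simulate_trajectories(cfg, noiseless(arcs$stabilizer), seed = 1)
  expect_true(all(diff(st$dmd[st$cycle <= 200]) < 0))
  # disruptor: dmd rises, then a slight fall at the end
  di <- simulate_trajectories(cfg, noiseless(arcs$disruptor), seed = 1)
  expect_true(all(diff(di$dmd[di$cycle <= 320]) > 0))
  expect_true(all(diff(di$dmd[di$cycle >= 321]) < 0))
  # disruptor: area down by >= 20% of baseline at the cycle nearest 2 h
  c2h <- round(2 * 60 / cfg$interval)
  expect_lte(di$area[di$cycle == c2h], 0.8 * di$area[di$cycle == 1])
})

test_that("population means stay within calibration ranges", {
  cfg <- acquisition_config()
  rng <- calibration_ranges()
  for (a in builtin_archetypes()) {
    rec <- simulate_trajectories(cfg, a, seed = 31)
    s <- suppressWarnings(aggregate_records(rec)[[1]])
    for (p in colnames(s$mean)) {
      expect_gte(min(s$mean[, p]), rng[[p]][1])
      expect_lte(max(s$mean[, p]), rng[[p]][2])
    }
  }
})
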