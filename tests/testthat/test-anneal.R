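test_that("temperature schedule hits the printed endpoints", {
  sch <- sa_schedule()
  expect_equal(temperature_at(0, sch), 100)
  expect_true(all(temperature_at(3200:7199, sch) == 1000))
  expect_equal(temperature_at(15199, sch), 25)
  expect_lt(temperature_at(1600, sch), 1000)
  expect_gt(temperature_at(1600, sch), 100)
  expect_error(temperature_at(15200, sch), "range")
  expect_error(temperature_at(-1, sch), "range")
  # multi-cycle variant repeats the profile
  sch2 <- sa_schedule(cycles = 2)
  expect_equal(temperature_at(15200, sch2), 100)
})

test_that("Metropolis steps accept downhill always and uphill per temperature", {
  # quadratic well: proposals toward 0 always accepted
  efn <- function(th) sum(th^2)
  set.seed(1)
  th <- c(x = 100)
  out <- mc_step(th, efn, temperature = 1000, moveset = move_set(sigma = 5,
                                                                p_uniform = 0))
  expect_true(out$accepted)  # overwhelmingly downhill from 100
  # at T -> 0+ uphill moves are rejected
  up <- 0
  set.seed(2)
  th <- c(x = 0)
  for (i in 1:50) {
    res <- mc_step(th, efn, temperature = 1e-9,
                   moveset = move_set(sigma = 30, p_uniform = 0))
    if (res$accepted && res$energy > 0) up <- up + 1
  }
  expect_equal(up, 0)
  # fixed seed, fixed input -> identical outcome
  set.seed(7); a <- mc_step(c(x = 10), efn, 500)
  set.seed(7); b <- mc_step(c(x = 10), efn, 500)
  expect_identical(a, b)
})

test_that("refinement is deterministic, traced, and degenerate-schedule safe", {
  fix <- fixture_bundle()
  sch <- sa_schedule(heat_steps = 60, hold_steps = 60, cool_steps = 80)
  r1 <- refine_model(fix$start, fix$restraints, tables = fix$tables,
                     schedule = sch, seed = 3)
  r2 <- refine_model(fix$start, fix$restraints, tables = fix$tables,
                     schedule = sch, seed = 3)
  expect_identical(model_xyz(r1$final_model), model_xyz(r2$final_model))
  expect_identical(r1$energy_trace, r2$energy_trace)
  expect_equal(nrow(r1$energy_trace), 200)
  expect_lte(r1$best_energy, r1$final_energy$E_tot)
  # energy trace carries the exact breakdown sum
  tr <- r1$energy_trace
  expect_equal(tr$E_tot, tr$E_stereo + tr$E_solv + tr$E_exp_noe +
                 tr$E_exp_dihe + tr$E_stap, tolerance = 1e-9)

  # near-degenerate schedule with tiny moves leaves the model unchanged
  tiny <- sa_schedule(heat_steps = 1, hold_steps = 1, cool_steps = 1)
  r0 <- refine_model(fix$start, fix$restraints,
                     moveset = move_set(sigma = 1e-9, p_uniform = 0),
                     schedule = tiny, seed = 1)
  expect_lt(max(abs(model_xyz(r0$final_model) - model_xyz(fix$start))),
            1e-5)
})

test_that("ensemble refinement is reproducible and picks the representative", {
  fix <- fixture_bundle()
  sch <- sa_schedule(heat_steps = 40, hold_steps = 40, cool_steps = 60)
  ens <- ensemble(list(fix$start, fix$start, fix$start), "toy")
  run <- refine_ensemble(ens, fix$restraints, tables = fix$tables,
                         schedule = sch, base_seed = 5)
  expect_length(run$results, 3)
  # per-member seeds derive from the base seed
  expect_equal(vapply(run$results, `[[`, 0, "seed"), c(5, 6, 7))
  solo <- refine_model(fix$start, fix$restraints, tables = fix$tables,
                       schedule = sch, seed = 6)
  expect_identical(model_xyz(run$results[[2]]$best_model),
                   model_xyz(solo$best_model))
  # representative: lexicographic (violations at 0.0 A, then E_tot)
  viol <- vapply(run$results, function(r)
    violation_stats(r$best_model, fix$restraints)["all", "n_gt_0"], 0)
  expect_true(all(viol[run$representative] <= viol))
})

test_that("annealing reduces restraint violations on the fixture", {
  fix <- fixture_bundle()
  res <- refine_model(fix$start, fix$restraints, tables = fix$tables,
                      schedule = sa_schedule(heat_steps = 400,
                                             hold_steps = 600,
                                             cool_steps = 2000),
                      seed = 11)
  e0 <- total_energy(fix$start, fix$restraints, fix$tables)
  e1 <- total_energy(res$best_model, fix$restraints, fix$tables)
  expect_lt(e1$E_exp_noe, e0$E_exp_noe)
  expect_lt(e1$E_tot, e0$E_tot)
})
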