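test_that("initial state puts the inoculum in MHCI- and naive cells at c1/kd1", {
  p <- calib
  y0 <- initial_state(p)
  expect_equal(y0[["t_n"]], p[["c1"]] / p[["kd1"]])
  expect_equal(y0[["t_n"]], 0.0714, tolerance = 1e-3)
  expect_equal(y0[["c_neg"]], 2e6)
  expect_true(all(y0[setdiff(names(y0), c("t_n", "c_neg"))] == 0))
  # tumor-free start
  y0f <- initial_state(p, tumor_inoculum = 0)
  expect_equal(sum(y0f != 0), 1L)
  expect_error(initial_state(p, tumor_inoculum = -1), ">= 0")
})

test_that("impulses add the dose to the antigen state only", {
  y <- state_vector(t_n = 0.07, lv = 5, t_e2 = 3)
  y2 <- apply_impulse(y, 3)
  expect_equal(y2[["lv"]], 8)
  expect_identical(as.numeric(y2[-3]), as.numeric(y[-3]))
  expect_equal(apply_impulse(state_vector(), 1.1e6)[["lv"]], 1.1e6)
  expect_identical(as.numeric(apply_impulse(y, 0)), as.numeric(y))
  expect_error(apply_impulse(y, -1), "non-negative")
})

test_that("schedules demand increasing days and non-negative doses", {
  s <- vaccination_schedule(c(5, 10), 1e6)
  expect_equal(nrow(s), 2L)
  expect_error(vaccination_schedule(c(5, 5), 1e6), "strictly increasing")
  expect_error(vaccination_schedule(5, -1), "non-negative")
})

test_that("the tumor-free equilibrium is preserved by the integrator", {
  p <- calib
  y0 <- tumor_free_equilibrium(p)
  traj <- simulate_trajectory(p, y0 = y0, t1 = 50, dt = 0.05)
  drift <- abs(traj$t_n - y0[["t_n"]]) / y0[["t_n"]]
  expect_lt(max(drift), 1e-10)
  expect_true(all(traj[, c("t_e1", "lv", "t_e2", "c_pos", "c_neg",
                           "t_e3", "ifng", "tnfa")] == 0))
})

test_that("antigen decays exponentially with the calibrated half-life", {
  p <- calib
  L0 <- 1.1e6
  y0 <- state_vector(lv = L0)
  traj <- simulate_trajectory(p, y0 = y0, t1 = 10, dt = 0.01)
  expect_equal(traj$lv, L0 * exp(-p[["kd2"]] * traj$time), tolerance = 1e-10)
  # half-life ln(2)/kd2 ~ 1.904 days
  t_half <- log(2) / p[["kd2"]]
  expect_equal(t_half, 1.904, tolerance = 1e-3)
  i <- which.min(abs(traj$time - t_half))
  expect_equal(traj$lv[i] / L0, 0.5, tolerance = 2e-3)  # nearest grid node
})

test_that("the integrator converges at fourth order on the antigen subsystem", {
  p <- calib
  L0 <- 1e6
  err_at <- function(dt) {
    traj <- simulate_trajectory(p, y0 = state_vector(lv = L0),
                                t1 = 2, dt = dt)
    abs(traj$lv[nrow(traj)] - L0 * exp(-p[["kd2"]] * 2))
  }
  e1 <- err_at(0.2)
  e2 <- err_at(0.1)
  e3 <- err_at(0.05)
  expect_gt(e1 / e2, 13)
  expect_lt(e1 / e2, 19)
  expect_gt(e2 / e3, 13)
  expect_lt(e2 / e3, 19)
})

test_that("impulse bookkeeping records exactly one pre/post pair per event", {
  p <- calib
  sched <- vaccination_schedule(c(5, 12), c(1.1e6, 2e5))
  traj <- simulate_trajectory(p, schedule = sched, t1 = 20, dt = 0.01)
  for (k in seq_len(nrow(sched))) {
    pre <- which(traj$time == sched$day[k] & traj$event == -1L)
    post <- which(traj$time == sched$day[k] & traj$event == 1L)
    expect_length(pre, 1L)
    expect_length(post, 1L)
    expect_equal(post, pre + 1L)
    jump <- as.numeric(traj[post, tcellvax:::.STATE_NAMES]) -
      as.numeric(traj[pre, tcellvax:::.STATE_NAMES])
    expect_equal(jump[3], sched$dose[k])
    expect_true(all(jump[-3] == 0))
  }
  # grid lands exactly on both events and the endpoints
  expect_true(all(c(0, 5, 12, 20) %in% traj$time))
})

test_that("simulation can be split and restarted without changing the path", {
  p <- calib
  sched <- single_vax()
  full <- simulate_trajectory(p, schedule = sched, t1 = 49, dt = 0.02)
  part1 <- simulate_trajectory(p, schedule = sched, t1 = 20, dt = 0.02)
  part2 <- simulate_trajectory(p, y0 = final_state(part1),
                               schedule = vaccination_schedule(),
                               t0 = 20, t1 = 49, dt = 0.02)
  i <- which(full$time == 35)[1]
  j <- which(part2$time == 35)[1]
  a <- as.numeric(full[i, tcellvax:::.STATE_NAMES])
  b <- as.numeric(part2[j, tcellvax:::.STATE_NAMES])
  expect_equal(b, a, tolerance = 1e-12)
})

test_that("too-large steps and out-of-window events are surfaced", {
  p <- calib
  expect_error(
    simulate_trajectory(p, schedule = vaccination_schedule(c(5, 5.05), 1e5),
                        t1 = 20, dt = 0.1),
    "smallest inter-event gap")
  expect_warning(
    simulate_trajectory(p, schedule = vaccination_schedule(60, 1e5),
                        t1 = 20, dt = 0.1),
    "outside")
})

test_that("fixed-step and adaptive reference paths agree on the calibrated run", {
  p <- calib
  rk <- simulate_trajectory(p, schedule = single_vax(), t1 = 49, dt = 0.01)
  ref <- simulate_reference(p, schedule = single_vax(), t1 = 49,
                            rtol = 1e-10, atol = 1e-10, n_out = 50)
  # compare at the reference grid times; per-state relative to its scale
  for (s in tcellvax:::.STATE_NAMES) {
    scale <- max(abs(ref[[s]]), 1e-300)
    idx <- match(round(ref$time, 8), round(rk$time, 8))
    keep <- !is.na(idx) & ref$event == 0
    err <- abs(rk[[s]][idx[keep]] - ref[[s]][keep]) / scale
    expect_lt(max(err), 1e-4)
  }
})

test_that("the extinction floor absorbs the tumor and prevents regrowth", {
  p <- model_parameters(kp3 = 5.73)
  traj <- simulate_trajectory(p, schedule = vaccination_schedule(5, 1.100481e6),
                              t1 = 200, dt = 0.01, extinction_threshold = 1)
  tot <- tumor_total(traj)
  first_below <- min(which(tot < 1))
  expect_lt(traj$time[first_below], 105)
  expect_true(all(tot[first_below:length(tot)] == 0))
})
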