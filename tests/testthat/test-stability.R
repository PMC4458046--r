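test_that("equilibria match their closed forms at the calibrated values", {
  p <- calib
  x0 <- tumor_free_equilibrium(p)
  expect_equal(x0[["t_n"]], p[["c1"]] / p[["kd1"]])
  expect_equal(x0[["t_n"]], 0.0714, tolerance = 1e-3)
  # doubling c1 doubles the naive level
  p2 <- model_parameters(c1 = 2 * p[["c1"]])
  expect_equal(tumor_free_equilibrium(p2)[["t_n"]], 2 * x0[["t_n"]])

  x1 <- high_tumor_equilibrium(p)
  expect_equal(x1[["c_neg"]], 1.497e9, tolerance = 1e-3)
  expect_equal(p[["s_t"]] * x1[["c_neg"]], 898.2, tolerance = 1e-3)
  # unit excess identity: kp2 = kd4 + r2 gives exactly one cell
  p3 <- model_parameters(kp2 = p[["kd4"]] + p[["r2"]])
  expect_equal(high_tumor_equilibrium(p3)[["c_neg"]], 1)
  # non-physical case errors
  p4 <- model_parameters(kp2 = p[["kd4"]] / 2)
  expect_error(high_tumor_equilibrium(p4), "non-physical")
})

test_that("the analytic Jacobian matches central finite differences", {
  set.seed(23)
  worst <- 0
  for (i in 1:100) {
    pr <- random_parameters()
    y <- random_state()
    Ja <- model_jacobian(y, pr)
    Jf <- fd_jacobian(y, pr)
    scale <- max(abs(Ja))
    worst <- max(worst, max(abs(Ja - Jf)) / scale)
  }
  expect_lt(worst, 1e-5)
})

test_that("the Jacobian is finite at the origin and matches printed entries at X0", {
  p <- calib
  expect_true(all(is.finite(model_jacobian(state_vector(), p))))
  J0 <- model_jacobian(tumor_free_equilibrium(p), p)
  expect_equal(J0[7, 7], -p[["kd5"]])
  expect_equal(J0[6, 6], p[["kp2"]] - p[["kd4"]])
  expect_equal(J0[3, 3], -p[["kd2"]])
  expect_equal(J0[4, 4], -p[["kd3"]] - p[["a21"]] - p[["a23"]])
  expect_equal(J0[5, 5], -p[["kp2"]] - p[["kd4"]])
  expect_equal(J0[7, 4], p[["a23"]] * p[["vol_b"]] / p[["epsilon"]])
  expect_equal(J0[1, 3], -p[["c1"]] * p[["c2"]] / (p[["gamma"]] * p[["kd1"]]))
})

test_that("closed-form tumor-free spectrum equals the numeric spectrum", {
  set.seed(31)
  for (i in 1:50) {
    pr <- random_parameters()
    ev_closed <- eigenvalues_tumor_free(pr)
    ev_num <- eigen(model_jacobian(tumor_free_equilibrium(pr), pr),
                    only.values = TRUE)$values
    # multiset match after sorting by (Re, Im)
    ord <- function(z) z[order(Re(z), Im(z))]
    a <- ord(as.complex(ev_closed)); b <- ord(as.complex(ev_num))
    scale <- max(Mod(a))
    expect_lt(max(Mod(a - b)) / scale, 1e-6)
    # the trafficking pair always decays
    expect_true(all(Re(ev_closed[8:9]) < 0))
  }
})

test_that("the trafficking quadratic factors exactly when reflux is absent", {
  p <- unclass(calib)
  p["a21"] <- 1e-300
  p <- do.call(model_parameters, as.list(p))
  ev <- eigenvalues_tumor_free(p)
  expect_true(any(abs(ev - (-p[["a12"]])) < 1e-10))
  expect_true(any(abs(ev - (-(p[["kd3"]] + p[["a23"]]))) < 1e-10))
})

test_that("Routh-Hurwitz coefficients are positive and verify against cubic roots", {
  p <- calib
  rh <- routh_hurwitz_high_tumor(p)
  expect_true(rh$a0 > 0 && rh$a1 > 0 && rh$a2 > 0)
  expect_gt(rh$hurwitz, 0)
  expect_true(all(Re(rh$roots) < 0))
  expect_true(rh$stable_cubic)
  # residual of the cubic at its own roots
  res <- rh$roots^3 + rh$a2 * rh$roots^2 + rh$a1 * rh$roots + rh$a0
  expect_lt(max(Mod(res)) / max(1, rh$a0), 1e-8)

  # hand-computed unit case: all flows and deaths equal one
  ones <- as.list(stats::setNames(rep(1, 6),
                                  c("a12", "a21", "a23", "a32", "kd3", "kd5")))
  p1 <- do.call(model_parameters, ones)
  rh1 <- routh_hurwitz_high_tumor(p1)
  expect_equal(rh1$a2, 6)
  expect_equal(rh1$a1, 9)
  expect_equal(rh1$a0, 3)
  expect_true(rh1$stable_cubic)

  # positivity for random positive parameter sets
  set.seed(5)
  for (i in 1:25) {
    rhr <- routh_hurwitz_high_tumor(random_parameters())
    expect_true(rhr$a0 > 0 && rhr$a1 > 0 && rhr$a2 > 0 && rhr$hurwitz > 0)
  }
})

test_that("classification: calibrated values give unstable X0 and stable X1", {
  cl <- classify_equilibria(calib)
  expect_equal(cl$tumor_free$criterion, "unstable")
  expect_equal(cl$tumor_free$numeric_verdict, "unstable")
  expect_true(any(abs(Re(cl$tumor_free$eigenvalues_numeric) -
                        (calib[["kp2"]] - calib[["kd4"]])) < 1e-8))
  expect_equal(cl$high_tumor$criterion, "stable")
  expect_equal(cl$high_tumor$numeric_verdict, "stable")
  expect_true(all(Re(cl$high_tumor$eigenvalues_numeric) < 0))
  expect_gt(cl$high_tumor$criteria$hurwitz, 0)
})

test_that("classification swaps when tumor death outpaces proliferation", {
  p <- model_parameters(kp2 = 1e-6, kd4 = 0.5)
  cl <- classify_equilibria(p)
  expect_equal(cl$tumor_free$criterion, "stable")
  expect_equal(cl$tumor_free$numeric_verdict, "stable")
  expect_false(cl$high_tumor$physical)
  expect_equal(cl$high_tumor$criterion, "unstable")
})

test_that("the marginal growth case is reported, never classified", {
  p <- model_parameters(kp2 = 0.3, kd4 = 0.3)
  cl <- classify_equilibria(p)
  expect_equal(cl$tumor_free$criterion, "marginal")
  expect_equal(cl$high_tumor$criterion, "marginal")
})

test_that("criterion verdict equals the numeric verdict on random parameter sets", {
  set.seed(41)
  n_checked <- 0
  for (i in 1:50) {
    pr <- random_parameters()
    cl <- classify_equilibria(pr)
    expect_equal(cl$tumor_free$criterion, cl$tumor_free$numeric_verdict)
    if (cl$high_tumor$physical) {
      expect_equal(cl$high_tumor$criterion, cl$high_tumor$numeric_verdict)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("trajectories return to the high-tumor equilibrium after perturbation", {
  p <- calib
  x1 <- high_tumor_equilibrium(p)
  y0 <- x1
  y0[["c_neg"]] <- 1.01 * x1[["c_neg"]]
  traj <- simulate_trajectory(p, y0 = y0, t1 = 100, dt = 0.05)
  d0 <- abs(traj$c_neg[1] - x1[["c_neg"]])
  d1 <- abs(traj$c_neg[nrow(traj)] - x1[["c_neg"]])
  expect_lt(d1, d0 / 100)
})

test_that("a small untreated tumor grows logistically to carrying capacity", {
  p <- calib
  traj <- simulate_trajectory(p, y0 = initial_state(p, tumor_inoculum = 1e3),
                              t1 = 200, dt = 0.05)
  K <- carrying_capacity(p)
  expect_true(all(diff(traj$c_neg) >= -1e-6 * K))
  expect_equal(traj$c_neg[nrow(traj)] / K, 1, tolerance = 0.01)
})

test_that("tidy and glance expose the analysis as tibbles", {
  cl <- classify_equilibria(calib)
  td <- tidy(cl)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4 * 9)
  gl <- glance(cl)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$carrying_capacity_mm3, 898.2, tolerance = 1e-3)
  expect_equal(gl$high_tumor_criterion, "stable")
})
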