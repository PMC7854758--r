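p <- bone_parameters()

test_that("daily cell stepping matches an adaptive integration of the same field", {
  ss <- solve_steady_state(p, 0.458)
  cell <- ss * c(1.4, 0.7, 1.8)   # push off the fixed point
  C_d <- 2.5; c_b <- 0.4; r_eff <- 0.09
  ch <- p$chemical
  piP <- pth_occupancy(p)
  consts <- list(D_R = ch$D_R, D_B = ch$f_0 * ch$d_B, k_B = ch$k_B,
                 D_C = ch$D_C, D_A = ch$D_A, f0Cs = ch$f_0 * ch$C_s,
                 Cs = ch$C_s, k12 = ch$k_1 / ch$k_2,
                 opg_coef = ch$K_O_P / (ch$k_O * piP),
                 num_coef = r_eff * ch$K_L_P * piP,
                 den0 = 1 + r_eff * ch$K + C_d / osteopkpd:::K_D_nM(p),
                 bp_inh = 1 - c_b / (p$ibandronate$IC_50 + c_b))
  fast <- osteopkpd:::integrate_cells_day(cell, consts, 10)
  ref_rhs <- function(t, y, parms) {
    yy <- unname(y)
    d <- cell_rhs(c(B_r = yy[1], B_a = yy[2], C = yy[3]), p, C_d, c_b,
                  r_eff)$deriv
    list(c(d, yy[2], yy[3]))
  }
  ref <- deSolve::ode(c(cell, 0, 0), c(0, 1), ref_rhs, NULL,
                      rtol = 1e-12, atol = 1e-14)
  expect_equal(unname(fast), unname(ref[2, -1]), tolerance = 1e-8)
})

test_that("control runs are homeostatic and deterministic", {
  sc <- bone_scenario(1.0, "equilibrium", duration = 1200)
  a <- run_point_simulation(sc, p)
  b <- run_point_simulation(sc, p)
  expect_identical(a$series, b$series)   # bitwise repeatability
  drift <- max(abs(a$series$v_b - a$series$v_b[1])) / a$series$v_b[1]
  expect_lt(drift, 1e-6)
  # occupancies stay within physical bounds along the trajectory
  expect_true(all(a$series$pi_RANKL >= 0 & a$series$pi_RANKL <= 1))
  expect_true(all(a$series$pi_TGFb >= 0 & a$series$pi_TGFb <= 1))
})

test_that("disuse resorbs bone and overload protects it", {
  dis <- run_point_simulation(bone_scenario(1.0, "disuse",
                                            duration = 1000), p)
  expect_true(all(diff(dis$series$v_b) <= 1e-12))
  expect_lt(dis$series$v_b[1001], 0.9 * dis$series$v_b[1])
  over <- run_point_simulation(bone_scenario(1.0, "overload",
                                             overload_factor = 5,
                                             duration = 1000), p)
  expect_gt(over$series$v_b[1001], over$series$v_b[1])
})

test_that("volume bookkeeping is exact and the drug series has no lag", {
  sched <- dose_schedule("denosumab", 0.3)
  sc <- bone_scenario(1.0, "equilibrium", schedule = sched, duration = 400)
  sim <- run_point_simulation(sc, p)
  s <- sim$series
  vb_rebuilt <- sim$v_b0 + cumsum(s$dv_form - s$dv_res)
  expect_lt(max(abs(vb_rebuilt - s$v_b)), 1e-12)
  pk <- simulate_pk(sched, p, duration = 400)
  expect_identical(s$C_d_nM, pk$C_d_nM)
  expect_identical(s$NTX_nM, pk$NTX_nM)
  # mean ash recomputed from the recorded history matches the state
  ab <- mean_ash_fraction(s[-1, c("dv_form", "dv_res")], sim$v_b0, p)
  expect_equal(ab, s$alpha_bar, tolerance = 1e-12)
})

test_that("halving the cell sub-step leaves the trajectory unchanged", {
  sc <- bone_scenario(1.0, "equilibrium",
                      schedule = dose_schedule("denosumab", 1.0),
                      duration = 1500)
  coarse <- run_point_simulation(sc, p, n_substeps = 10)
  fine <- run_point_simulation(sc, p, n_substeps = 20)
  rel <- abs(fine$series$v_b[1501] - coarse$series$v_b[1501]) /
    coarse$series$v_b[1501]
  expect_lt(rel, 0.002)
  sc2 <- bone_scenario(0.5, "constant_stress", stress_MPa = 1.0,
                       schedule = dose_schedule("ibandronate", 0.5),
                       duration = 1500)
  c2 <- run_point_simulation(sc2, p, n_substeps = 10)
  f2 <- run_point_simulation(sc2, p, n_substeps = 20)
  expect_lt(abs(f2$series$v_b[1501] - c2$series$v_b[1501]) /
              c2$series$v_b[1501], 0.002)
})

test_that("antiresorptive treatment raises bone volume above control", {
  ctrl <- run_point_simulation(bone_scenario(1.0, "equilibrium",
                                             duration = 1000), p)
  den <- run_point_simulation(
    bone_scenario(1.0, "equilibrium",
                  schedule = dose_schedule("denosumab", 1.0),
                  duration = 1000), p)
  ib <- run_point_simulation(
    bone_scenario(1.0, "equilibrium",
                  schedule = dose_schedule("ibandronate", 2.0),
                  duration = 1000), p)
  expect_gt(percent_change(den, ctrl, "v_b", "max"), 5)
  expect_gt(percent_change(ib, ctrl, "v_b", "max"), 1)
  # osteoclasts are suppressed while drug is on board
  expect_lt(min(den$series$C), 0.1 * den$series$C[1])
})

test_that("percent change measures follow their definitions", {
  sc <- bone_scenario(1.0, "equilibrium", duration = 200)
  a <- run_point_simulation(sc, p)
  expect_equal(percent_change(a, a, "v_b", "max"), 0)
  expect_equal(percent_change(a, a, "v_b", "final"), 0)
  b <- a
  b$series$v_b <- a$series$v_b * 1.53
  expect_equal(percent_change(b, a, "v_b", "max"), 53, tolerance = 1e-9)
  expect_equal(percent_change(b, NULL, "v_b", "at", t = 0), 0)
  expect_error(percent_change(a, a, "nope"), "unknown variable")
  short <- run_point_simulation(bone_scenario(1.0, "equilibrium",
                                              duration = 100), p)
  expect_error(percent_change(a, short), "time grids")
})

test_that("the preset library spans the documented study designs", {
  pr <- scenario_presets()
  expect_true(all(c("dose_response_rho1_equilibrium_control",
                    "dose_response_rho1_equilibrium_denosumab_1",
                    "dose_response_rho0.5_disuse_ibandronate_2",
                    "dose_response_rho2.05_overload7_control") %in%
                    names(pr)))
  cs <- pr[["constant_stress_rho2.05_sigma54_denosumab_3"]]
  expect_equal(cs$stress_MPa, 54)
  expect_equal(cs$initial_density, 2.05)
  stresses <- vapply(c("constant_stress_rho0.5_sigma1_control",
                       "constant_stress_rho1_sigma7_control",
                       "constant_stress_rho2.05_sigma34_control"),
                     function(n) pr[[n]]$stress_MPa, 0)
  expect_equal(unname(stresses), c(1, 7, 34))
  ivs <- vapply(sprintf("interval_ibandronate_0.25_q%d",
                        c(60, 90, 120, 150, 180)),
                function(n) pr[[n]]$schedule$interval, 0)
  expect_equal(unname(ivs), c(60, 90, 120, 150, 180))
  facs <- vapply(sprintf("dose_response_rho1_%s_control",
                         c("disuse", "equilibrium", "overload5",
                           "overload7")),
                 function(n) {
                   sc <- pr[[n]]
                   if (sc$load_mode == "disuse") 0
                   else if (sc$load_mode == "equilibrium") 1
                   else sc$overload_factor
                 }, 0)
  expect_equal(unname(facs), c(0, 1, 5, 7))
  # biomarker presets are single-dose
  expect_equal(pr[["biomarker_denosumab_0.1"]]$schedule$n_doses, 1)
})

test_that("scenario validation rejects ill-posed runs", {
  expect_error(bone_scenario(0), "initial_density")
  expect_error(bone_scenario(1, "constant_stress"), "stress_MPa")
  expect_error(bone_scenario(1, duration = 0), "duration")
  expect_error(dose_schedule("denosumab", -1), "dose")
  expect_error(dose_schedule("denosumab", 1, interval = 0), "interval")
})
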