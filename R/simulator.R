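#' Define a point-simulation scenario
#'
#' A scenario fixes one material-point run: the bone type (as initial
#' apparent density), the mechanical environment, the dosing schedule and
#' the horizon. Initial cell populations always come from the drug-free
#' stationary state under the reference equilibrium stimulus.
#'
#' @param initial_density Initial apparent density, g/cm^3 (0.5
#'   osteoporotic, 1.0 trabecular, 2.05 cortical, or arbitrary).
#' @param load_mode One of \code{"equilibrium"} (reference stimulus),
#'   \code{"disuse"} (zero stimulus), \code{"overload"} (a multiple of
#'   the reference stimulus) or \code{"constant_stress"} (uniaxial stress
#'   control; the strain is recomputed daily from the current modulus).
#' @param overload_factor Stimulus multiple for \code{"overload"}.
#' @param stress_MPa Applied stress magnitude for
#'   \code{"constant_stress"}, MPa.
#' @param schedule A \code{\link{dose_schedule}} or \code{NULL} (control).
#' @param duration Horizon, days.
#' @param N_cycles_per_day Daily load cycles; default from the registry
#'   (10000; mandible-type runs use 500).
#' @param stress_mode \code{"compression"} (default; mastication-type
#'   loading) or \code{"tension"} for the fatigue laws.
#' @param seed Unused (the model is deterministic); kept for interface
#'   stability.
#' @return An object of class \code{bone_scenario}.
#' @export
bone_scenario <- function(initial_density = 1.0,
                          load_mode = c("equilibrium", "disuse",
                                        "overload", "constant_stress"),
                          overload_factor = 5, stress_MPa = NULL,
                          schedule = NULL, duration = 3000,
                          N_cycles_per_day = NULL,
                          stress_mode = c("compression", "tension"),
                          seed = NULL) {
  load_mode <- match.arg(load_mode)
  stress_mode <- match.arg(stress_mode)
  stopifnot(initial_density > 0, duration > 0)
  if (load_mode == "constant_stress" &&
      (is.null(stress_MPa) || stress_MPa <= 0))
    stop("constant_stress mode needs a positive stress_MPa")
  if (!is.null(schedule)) stopifnot(inherits(schedule, "dose_schedule"))
  structure(list(initial_density = initial_density, load_mode = load_mode,
                 overload_factor = overload_factor, stress_MPa = stress_MPa,
                 schedule = schedule, duration = as.integer(duration),
                 N_cycles_per_day = N_cycles_per_day,
                 stress_mode = stress_mode, seed = seed),
            class = "bone_scenario")
}

# Fast per-day integration of the cell populations (RK4, n_sub substeps)
# with the day's coupling coefficients frozen. State: B_r, B_a, C plus
# running integrals of B_a and C used for the daily volume balance.
# Mirrors cell_rhs(); the agreement is asserted in the test suite.
integrate_cells_day <- function(cell, consts, n_sub) {
  h <- 1 / n_sub
  y <- c(cell[["B_r"]], cell[["B_a"]], cell[["C"]], 0, 0)
  f <- function(y) {
    piT <- (y[3] + consts$f0Cs) / (y[3] + consts$Cs)
    O <- consts$opg_coef * y[1]
    piR <- consts$num_coef * y[2] / (consts$den0 + consts$k12 * O)
    if (piR > 1) piR <- 1
    c(consts$D_R * piT - consts$D_B / piT * y[1],
      consts$D_B / piT * y[1] - consts$k_B * y[2],
      consts$D_C * piR * consts$bp_inh - consts$D_A * piT * y[3],
      y[2], y[3])
  }
  for (i in seq_len(n_sub)) {
    k1 <- f(y)
    k2 <- f(y + h / 2 * k1)
    k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    neg <- which(y[1:3] < 0)
    if (length(neg)) y[neg] <- 0
  }
  y
}

#' Run a coupled point simulation
#'
#' Daily operator-split loop over the drug PK/PD, mechanics, cell
#' signaling and tissue sub-models: (1) the full PK trajectory is
#' integrated up front (it does not depend on the tissue) and read out
#' day by day; (2) each day the elastic modulus, equivalent strain,
#' stimulus and inhibitory signal are evaluated from the current tissue
#' state; (3) the cell populations advance one day under the
#' mechano-modulated RANK/RANK-L occupancy and the drug couplings;
#' (4) the bone volume fraction, mineralization bookkeeping, fatigue
#' damage and modulus are updated. Identical inputs give identical
#' outputs.
#'
#' @param scenario A \code{\link{bone_scenario}}.
#' @param params A \code{bone_params} object.
#' @param k_res_scale Magnitude of the turnover rates (see
#'   \code{\link{calibrate_turnover}}).
#' @param n_substeps Sub-daily RK4 steps for the cell populations.
#' @return An object of class \code{bone_sim}: a list with the daily
#'   \code{series} data frame (duration + 1 rows), the scenario, the
#'   turnover rates and the initial steady state.
#' @export
#' @examples
#' \donttest{
#' sc <- bone_scenario(1.0, "equilibrium",
#'                     schedule = dose_schedule("denosumab", 1.0),
#'                     duration = 365)
#' sim <- run_point_simulation(sc)
#' summary(sim)
#' }
run_point_simulation <- function(scenario, params = bone_parameters(),
                                 k_res_scale = default_k_res_scale(),
                                 n_substeps = 10) {
  stopifnot(inherits(scenario, "bone_scenario"))
  ch <- params$chemical
  me <- params$mechano
  n_days <- scenario$duration
  N_cyc <- if (is.null(scenario$N_cycles_per_day)) me$N_cycles else
    scenario$N_cycles_per_day

  v_b0 <- density_to_volume_fraction(scenario$initial_density, me$alpha_ini,
                                     params)
  if (v_b0 > me$v_b_max) v_b0 <- me$v_b_max
  ss <- solve_steady_state(params, v_b0)
  rates <- calibrate_turnover(ss[["C"]], ss[["B_a"]], k_res_scale)

  # drug exposure series (day 0 .. duration)
  drug <- if (!is.null(scenario$schedule) && scenario$schedule$dose > 0)
    scenario$schedule$drug else "none"
  C_d_series <- numeric(n_days + 1)
  c_b_series <- numeric(n_days + 1)
  ntx_series <- rep(NA_real_, n_days + 1)
  uctx_series <- rep(NA_real_, n_days + 1)
  pct_series <- rep(NA_real_, n_days + 1)
  if (drug != "none") {
    pk <- simulate_pk(scenario$schedule, params, duration = n_days)
    if (drug == "denosumab") {
      C_d_series <- pk$C_d_nM
      ntx_series <- pk$NTX_nM
      pct_series <- pk$NTX_pct_baseline
    } else {
      c_b_series <- pk$C_b_ug_per_l
      uctx_series <- pk$uCTX
      pct_series <- pk$uCTX_pct_baseline
    }
  }

  pi_P <- pth_occupancy(params)
  consts_base <- list(D_R = ch$D_R, D_B = ch$f_0 * ch$d_B, k_B = ch$k_B,
                      D_C = ch$D_C, D_A = ch$D_A,
                      f0Cs = ch$f_0 * ch$C_s, Cs = ch$C_s,
                      k12 = ch$k_1 / ch$k_2,
                      opg_coef = ch$K_O_P / (ch$k_O * pi_P))
  KD <- K_D_nM(params)
  ibp <- params$ibandronate

  # state
  cell <- ss
  v_b <- v_b0
  deficit <- v_b0 * (me$alpha_max - me$alpha_ini)
  alpha_bar <- me$alpha_max - deficit / v_b
  d <- me$d_0

  nr <- n_days + 1
  rec <- list(B_r = numeric(nr), B_a = numeric(nr), C = numeric(nr),
              pi_TGFb = numeric(nr), pi_RANKL = numeric(nr),
              OPG_pM = numeric(nr), v_b = numeric(nr),
              alpha_bar = numeric(nr), damage = numeric(nr),
              E_MPa = numeric(nr), dv_form = numeric(nr),
              dv_res = numeric(nr), stimulus = numeric(nr),
              signal = numeric(nr), strain_mu = numeric(nr))

  mech_env <- function(v_b, alpha_bar, d) {
    E <- elastic_modulus(v_b, alpha_bar, d, params)
    if (scenario$load_mode == "disuse") {
      eps <- 0; xi <- 0
    } else if (scenario$load_mode == "equilibrium") {
      xi <- me$xi_ref; eps <- xi / N_cyc^(1 / me$m)
    } else if (scenario$load_mode == "overload") {
      xi <- scenario$overload_factor * me$xi_ref
      eps <- xi / N_cyc^(1 / me$m)
    } else {
      eps <- scenario$stress_MPa / E
      xi <- mechanical_stimulus(N_cyc, eps, me$m)
    }
    list(E = E, eps = eps, xi = xi,
         S = remodeling_signal(xi, d, v_b, params))
  }

  record <- function(i, mech, occ) {
    rec$B_r[i] <<- cell[["B_r"]]; rec$B_a[i] <<- cell[["B_a"]]
    rec$C[i] <<- cell[["C"]]
    rec$pi_TGFb[i] <<- occ$pi_TGFb; rec$pi_RANKL[i] <<- occ$pi_RANKL
    rec$OPG_pM[i] <<- occ$O
    rec$v_b[i] <<- v_b; rec$alpha_bar[i] <<- alpha_bar
    rec$damage[i] <<- d
    rec$E_MPa[i] <<- mech$E
    rec$stimulus[i] <<- mech$xi; rec$signal[i] <<- mech$S
    rec$strain_mu[i] <<- mech$eps * 1e6
  }

  mech <- mech_env(v_b, alpha_bar, d)
  r_eff <- effective_k3_k4(mech$S, v_b / v_b0, specific_surface(v_b, params),
                           params)
  occ <- cell_rhs(cell, params, C_d_series[1], c_b_series[1], r_eff)
  record(1, mech, occ)

  for (t in seq_len(n_days)) {
    # (1) drug exposure for the day
    C_d <- C_d_series[t]     # value at day t - 1, the start of the step
    c_b <- c_b_series[t]
    # (2) mechanics from the current tissue state
    mech <- mech_env(v_b, alpha_bar, d)
    r_eff <- effective_k3_k4(mech$S, v_b / v_b0,
                             specific_surface(v_b, params), params)
    # (3) one day of cell dynamics
    consts <- consts_base
    consts$num_coef <- r_eff * ch$K_L_P * pi_P
    consts$den0 <- 1 + r_eff * ch$K + C_d / KD
    consts$bp_inh <- 1 - ibp$I_max_cell * c_b / (ibp$IC_50 + c_b)
    y <- integrate_cells_day(cell, consts, n_substeps)
    cell <- c(B_r = y[1], B_a = y[2], C = y[3])
    # (4) tissue update
    dv_form <- rates$k_form * y[4]
    dv_res <- rates$k_res * y[5]
    v_new <- v_b + dv_form - dv_res
    if (v_new > me$v_b_max) dv_form <- me$v_b_max - v_b + dv_res
    if (v_new < me$v_b_min) dv_res <- v_b - me$v_b_min + dv_form
    deficit <- mineral_deficit_step(deficit, v_b, dv_form, dv_res, params)
    eps_mu <- mech$eps * 1e6
    if (eps_mu > 0 && d < 1) {
      E_ratio <- stiffness_ratio(v_b, d, params)
      d_acc <- damage_accumulation(eps_mu, N_cyc, scenario$stress_mode,
                                   E_ratio, d, calcium_content(alpha_bar),
                                   params)
    } else d_acc <- d
    d_rep <- damage_repair_rate(dv_res, d, v_b)
    d <- min(max(d_acc - d_rep, 0), 1)
    v_b <- v_b + dv_form - dv_res
    alpha_bar <- me$alpha_max - deficit / v_b
    rec$dv_form[t + 1] <- dv_form
    rec$dv_res[t + 1] <- dv_res
    mech_rec <- mech_env(v_b, alpha_bar, d)
    occ <- cell_rhs(cell, params, C_d_series[t + 1], c_b_series[t + 1],
                    r_eff)
    record(t + 1, mech_rec, occ)
  }

  out <- data.frame(
    time = 0:n_days, B_r = rec$B_r, B_a = rec$B_a, C = rec$C,
    pi_TGFb = rec$pi_TGFb, pi_RANKL = rec$pi_RANKL, pi_PTH = pi_P,
    OPG_pM = rec$OPG_pM, C_d_nM = C_d_series, C_b_ug_per_l = c_b_series,
    NTX_nM = ntx_series, uCTX = uctx_series,
    biomarker_pct_baseline = pct_series,
    v_b = rec$v_b, alpha_bar = rec$alpha_bar, damage = rec$damage,
    microcracks = me$k_crack * rec$damage, E_MPa = rec$E_MPa,
    Ca_mg_g = calcium_content(rec$alpha_bar),
    dv_form = rec$dv_form, dv_res = rec$dv_res, stimulus = rec$stimulus,
    signal = rec$signal, strain_mu = rec$strain_mu
  )

  structure(list(series = out, scenario = scenario, rates = rates,
                 steady_state = ss, v_b0 = v_b0, params = params,
                 drug = drug),
            class = "bone_sim")
}

#' Percent change of a simulated variable
#'
#' \code{100 (x - x_ref) / x_ref}, either against a reference simulation
#' on the same time grid (\code{mode = "max"} takes the maximum relative
#' difference over time, \code{"final"} the last day, \code{"at"} a given
#' day), or — when \code{reference} is \code{NULL} — against the
#' variable's own initial value (whole-process change). The measure is
#' anti-symmetric under swapping series and reference only in the
#' small-change limit.
#'
#' @param result A \code{bone_sim}.
#' @param reference A \code{bone_sim} on the same time grid, or
#'   \code{NULL}.
#' @param variable Column of the daily series (default \code{"v_b"}).
#' @param mode \code{"max"}, \code{"final"} or \code{"at"}.
#' @param t Day for \code{mode = "at"}.
#' @return Percent change (scalar).
#' @export
percent_change <- function(result, reference = NULL, variable = "v_b",
                           mode = c("max", "final", "at"), t = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "bone_sim"))
  x <- result$series[[variable]]
  if (is.null(x)) stop("unknown variable: ", variable)
  if (is.null(reference)) {
    xref <- rep(x[1], length(x))
  } else {
    stopifnot(inherits(reference, "bone_sim"))
    if (!identical(reference$series$time, result$series$time))
      stop("result and reference are on different time grids")
    xref <- reference$series[[variable]]
  }
  rel <- 100 * (x - xref) / xref
  switch(mode,
         max = max(rel),
         final = rel[length(rel)],
         at = {
           if (is.null(t)) stop("mode 'at' needs t")
           i <- match(t, result$series$time)
           if (is.na(t) || is.na(i)) stop("t not on the time grid")
           rel[i]
         })
}

#' Scenario presets
#'
#' Named scenario library covering the standard study designs:
#' \describe{
#'   \item{biomarker_*}{Single-dose biomarker runs (serum NTX for
#'     denosumab doses 0.1/0.3/1/3 mg/kg over 90 days; urinary CTX for
#'     ibandronate doses 0.25/0.5/1/2 mg over 180 days).}
#'   \item{dose_response_*}{Grid of 3 bone densities (0.5/1.0/2.05
#'     g/cm^3) x 4 stimuli (disuse, equilibrium, 5x and 7x overload) x 9
#'     drug arms (control, 4 denosumab, 4 ibandronate doses), 3000
#'     days, 90-day dosing interval.}
#'   \item{constant_stress_*}{Stress-controlled runs: 1.0 MPa at 0.5
#'     g/cm^3, 7.0 MPa at 1.0 g/cm^3, 34 and 54 MPa at 2.05 g/cm^3,
#'     same drug arms.}
#'   \item{interval_*}{Dosing-interval study at 0.5 g/cm^3 under 1.0
#'     MPa: each drug dose at intervals of 60/90/120/150/180 days.}
#' }
#'
#' @param duration Horizon for the remodeling presets, days.
#' @return Named list of \code{\link{bone_scenario}} objects.
#' @export
scenario_presets <- function(duration = 3000) {
  den_doses <- c(0.1, 0.3, 1.0, 3.0)
  ib_doses <- c(0.25, 0.5, 1.0, 2.0)
  presets <- list()

  for (dd in den_doses) {
    presets[[sprintf("biomarker_denosumab_%g", dd)]] <-
      bone_scenario(1.0, "equilibrium",
                    schedule = dose_schedule("denosumab", dd, n_doses = 1),
                    duration = 90)
  }
  for (dd in ib_doses) {
    presets[[sprintf("biomarker_ibandronate_%g", dd)]] <-
      bone_scenario(1.0, "equilibrium",
                    schedule = dose_schedule("ibandronate", dd, n_doses = 1),
                    duration = 180)
  }

  arms <- c(list(control = NULL),
            stats::setNames(lapply(den_doses, function(dd)
              dose_schedule("denosumab", dd)),
              sprintf("denosumab_%g", den_doses)),
            stats::setNames(lapply(ib_doses, function(dd)
              dose_schedule("ibandronate", dd)),
              sprintf("ibandronate_%g", ib_doses)))
  stim <- list(disuse = c("disuse", NA), equilibrium = c("equilibrium", NA),
               overload5 = c("overload", 5), overload7 = c("overload", 7))
  for (rho in c(0.5, 1.0, 2.05)) {
    for (sn in names(stim)) {
      for (an in names(arms)) {
        nm <- sprintf("dose_response_rho%g_%s_%s", rho, sn, an)
        presets[[nm]] <- bone_scenario(
          rho, stim[[sn]][1],
          overload_factor = suppressWarnings(as.numeric(stim[[sn]][2])),
          schedule = arms[[an]], duration = duration)
      }
    }
  }
  stress_map <- list(c(0.5, 1.0), c(1.0, 7.0), c(2.05, 34), c(2.05, 54))
  for (rs in stress_map) {
    for (an in names(arms)) {
      nm <- sprintf("constant_stress_rho%g_sigma%g_%s", rs[1], rs[2], an)
      presets[[nm]] <- bone_scenario(rs[1], "constant_stress",
                                     stress_MPa = rs[2],
                                     schedule = arms[[an]],
                                     duration = duration)
    }
  }
  for (an in setdiff(names(arms), "control")) {
    for (iv in c(60, 90, 120, 150, 180)) {
      sched <- arms[[an]]
      sched$interval <- iv
      nm <- sprintf("interval_%s_q%d", an, iv)
      presets[[nm]] <- bone_scenario(0.5, "constant_stress",
                                     stress_MPa = 1.0, schedule = sched,
                                     duration = duration)
    }
  }
  presets
}
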