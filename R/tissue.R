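#' Apparent density to bone volume fraction
#'
#' Standard composition relation \eqn{v_b = \rho / (1.41 + 1.29
#' \bar\alpha)} (g/cm^3) linking apparent density, ash fraction and
#' volume fraction; osteoporotic / trabecular / cortical bone at
#' densities 0.5 / 1.0 / 2.05 g/cm^3 map to roughly 0.229 / 0.458 /
#' 0.939 at the initial ash fraction 0.6.
#'
#' @param rho Apparent density, g/cm^3.
#' @param alpha Ash fraction; defaults to the registry's initial value.
#' @param params A \code{bone_params} object.
#' @return Bone volume fraction.
#' @export
density_to_volume_fraction <- function(rho, alpha = NULL,
                                       params = bone_parameters()) {
  me <- params$mechano
  if (is.null(alpha)) alpha <- me$alpha_ini
  stopifnot(rho > 0)
  rho / (me$rho_organic + me$rho_mineral * alpha)
}

#' Calibrate the bone formation and resorption rate constants
#'
#' The ratio \code{k_form / k_res} is fixed to the initial
#' osteoclast-to-osteoblast population ratio \code{C0 / Ba0} so the
#' volume-fraction balance is stationary at the drug-free steady state;
#' the absolute magnitude (the one quantity the model leaves free) is set
#' by \code{k_res_scale}, in volume fraction per pM of osteoclasts per
#' day.
#'
#' @param C0 Steady-state osteoclast concentration, pM.
#' @param Ba0 Steady-state active osteoblast concentration, pM.
#' @param k_res_scale Resorption rate constant; the package default was
#'   calibrated once against the trabecular equilibrium dose-response
#'   (see the methods vignette) and is stored in
#'   \code{\link{default_k_res_scale}}.
#' @return List of class \code{turnover_rates}: \code{k_form},
#'   \code{k_res}.
#' @export
calibrate_turnover <- function(C0, Ba0, k_res_scale = default_k_res_scale()) {
  if (C0 <= 0 || Ba0 <= 0) stop("steady-state populations must be positive")
  stopifnot(k_res_scale > 0)
  structure(list(k_form = k_res_scale * C0 / Ba0, k_res = k_res_scale),
            class = "turnover_rates")
}

#' Default resorption rate magnitude
#'
#' Single package-level calibration constant (volume fraction per pM per
#' day). See the methods vignette for the calibration protocol.
#' @return A scalar.
#' @export
default_k_res_scale <- function() 0.2931664

#' Rate of change of the bone volume fraction
#'
#' \eqn{dv_b/dt = k_{form} B_a - k_{res} C}. During integration
#' \code{v_b} is clamped to the registry bounds
#' \code{[v_b_min, v_b_max]}.
#'
#' @param B_a Active osteoblasts, pM.
#' @param C Active osteoclasts, pM.
#' @param rates A \code{turnover_rates} object.
#' @return Rate in volume fraction per day.
#' @export
volume_fraction_rate <- function(B_a, C, rates) {
  stopifnot(inherits(rates, "turnover_rates"), B_a >= 0, C >= 0)
  rates$k_form * B_a - rates$k_res * C
}

#' Ash fraction of a bone packet as it mineralizes
#'
#' Exponential secondary mineralization
#' \eqn{\alpha(t) = \alpha_{max} + (\alpha_{start} - \alpha_{max})
#' e^{-\kappa t}} with \eqn{\kappa} the reciprocal of the secondary
#' mineralization period (6 years by default). Newly deposited bone
#' starts at \code{alpha_0} (0.45); pre-existing bone continues along the
#' same curve from \code{alpha_ini} (0.6).
#'
#' @param t_since_deposition Days since deposition (vectorized).
#' @param params A \code{bone_params} object.
#' @param alpha_start Starting ash fraction (default \code{alpha_0}).
#' @return Ash fraction, monotone increasing toward \code{alpha_max}.
#' @export
ash_kinetics <- function(t_since_deposition, params = bone_parameters(),
                         alpha_start = NULL) {
  me <- params$mechano
  if (is.null(alpha_start)) alpha_start <- me$alpha_0
  stopifnot(all(t_since_deposition >= 0))
  me$alpha_max + (alpha_start - me$alpha_max) *
    exp(-kappa_rate(params) * t_since_deposition)
}

# One daily step of the mineral bookkeeping, expressed through the
# "mineral deficit" D = sum over packets of volume * (alpha_max - alpha).
# Exact for exponential kinetics: aging decays D at rate kappa,
# resorption at the current mean removes a proportional share of D, and
# formation adds dv_form * (alpha_max - alpha_0). Returns the updated
# deficit; the mean ash fraction is alpha_max - D / v_b.
mineral_deficit_step <- function(deficit, v_prev, dv_form, dv_res, params,
                                 dt = 1) {
  me <- params$mechano
  deficit <- deficit * exp(-kappa_rate(params) * dt)
  if (dv_res > 0) {
    if (dv_res >= v_prev) stop("resorption exceeds available bone volume")
    deficit <- deficit * (1 - dv_res / v_prev)
  }
  deficit + dv_form * (me$alpha_max - me$alpha_0)
}

#' Mean ash fraction along a deposition/resorption history
#'
#' Given the daily volumes of newly formed and resorbed bone, evolves the
#' volume-averaged ash fraction: pre-existing bone mineralizes from
#' \code{alpha_ini}, each formation packet enters at \code{alpha_0} and
#' ages exponentially, and resorption removes bone at the mean ash
#' fraction current at the time of resorption. The update is an exact
#' incremental recursion on the aggregate mineral deficit (no per-packet
#' storage needed); each day applies aging, then resorption, then
#' formation.
#'
#' @param history Data frame with numeric columns \code{dv_form} and
#'   \code{dv_res} (volume fraction formed/resorbed on each day, both >=
#'   0).
#' @param v_b0 Initial bone volume fraction.
#' @param params A \code{bone_params} object.
#' @return Numeric vector of length \code{nrow(history) + 1}: the mean
#'   ash fraction at day 0 and after each day's update. Always within
#'   \code{[alpha_0, alpha_max]}.
#' @export
mean_ash_fraction <- function(history, v_b0, params = bone_parameters()) {
  stopifnot(is.data.frame(history),
            all(c("dv_form", "dv_res") %in% names(history)),
            all(history$dv_form >= 0), all(history$dv_res >= 0), v_b0 > 0)
  me <- params$mechano
  n <- nrow(history)
  out <- numeric(n + 1)
  deficit <- v_b0 * (me$alpha_max - me$alpha_ini)
  v_b <- v_b0
  out[1] <- me$alpha_max - deficit / v_b
  for (i in seq_len(n)) {
    deficit <- mineral_deficit_step(deficit, v_b, history$dv_form[i],
                                    history$dv_res[i], params)
    v_b <- v_b + history$dv_form[i] - history$dv_res[i]
    if (v_b <= 0) stop("history drives the bone volume fraction to zero")
    out[i + 1] <- me$alpha_max - deficit / v_b
  }
  out
}

#' Calcium content from the ash fraction
#'
#' Linear anchor \eqn{[Ca] = (259.2 / 0.69) \bar\alpha} in mg of calcium
#' per g of bone.
#' @param alpha_bar Mean ash fraction in [0, 1] (vectorized).
#' @return Calcium content, mg/g.
#' @export
calcium_content <- function(alpha_bar) {
  stopifnot(all(alpha_bar >= 0 & alpha_bar <= 1))
  259.2 / 0.69 * alpha_bar
}

#' Ultimate strain from calcium content
#'
#' Empirical mineralization-brittleness law
#' \eqn{\log_{10}\varepsilon_u = 25.425 - 11.341 \log_{10} [Ca]}:
#' more mineralized (higher-calcium) bone fails at smaller strain.
#' @param Ca Calcium content, mg/g (> 0, vectorized).
#' @return Ultimate strain, dimensionless.
#' @export
ultimate_strain <- function(Ca) {
  if (any(Ca <= 0)) stop("Ca must be strictly positive")
  10^(25.425 - 11.341 * log10(Ca))
}

# Tension fatigue coefficient K_t from the calcium content: the ultimate
# strain (converted to microstrain) against the fatigue limit coefficient
# beta. At full mineralization this reproduces the generic tension
# fatigue constant 1.445e53.
tension_K <- function(Ca, params) {
  1e7 * (ultimate_strain(Ca) * 1e6 / params$mechano$beta_fatigue)^14.1
}

# Severity of one loading block in the fatigue laws: the stiffness-ratio
# weighted power of the strain amplitude (microstrain).
fatigue_severity <- function(eps_mu, mode, E_ratio) {
  delta <- if (mode == "compression") 10.3 else 14.1
  E_ratio * eps_mu^delta
}

#' Fatigue life of bone tissue
#'
#' Cycles to failure \eqn{N_f = K_i / ((E/E^*) \bar\varepsilon^{\delta_i})}
#' at constant strain amplitude, with \eqn{K_c = 9.333 \times 10^{40}},
#' \eqn{\delta_c = 10.3} in compression, and a calcium-dependent
#' coefficient \eqn{K_t = 10^7 (\varepsilon_u/\beta)^{14.1}} with
#' \eqn{\delta_t = 14.1} in tension. Strain amplitudes are in
#' MICROSTRAIN.
#'
#' @param eps_mu Equivalent strain amplitude, microstrain (> 0).
#' @param mode \code{"compression"} or \code{"tension"}.
#' @param E_ratio Stiffness ratio \eqn{E/E^*} (1 for undamaged cortical
#'   bone).
#' @param Ca Calcium content, mg/g (tension only).
#' @param params A \code{bone_params} object.
#' @return Cycles to failure.
#' @export
#' @examples
#' fatigue_life(5000, "compression")   # ~ 7.4e2 cycles
fatigue_life <- function(eps_mu, mode = c("compression", "tension"),
                         E_ratio = 1, Ca = calcium_content(0.6),
                         params = bone_parameters()) {
  mode <- match.arg(mode)
  if (any(eps_mu <= 0)) stop("strain amplitude must be strictly positive")
  stopifnot(E_ratio > 0)
  K <- if (mode == "compression") 9.333e40 else tension_K(Ca, params)
  K / fatigue_severity(eps_mu, mode, E_ratio)
}

#' Fatigue damage accumulation over a block of cycles
#'
#' Advances the damage state through the nonlinear
#' damage-versus-cycle-fraction closed forms. Accumulation is made
#' path-consistent by equivalent-cycle bookkeeping: the prior damage is
#' inverted to an equivalent consumed fraction of the current strain
#' level's fatigue life, today's cycles are added, and the closed form is
#' re-evaluated; damage therefore reaches 1 exactly when the accumulated
#' cycle fraction reaches the fatigue life.
#'
#' @param eps_mu Strain amplitude, microstrain.
#' @param N Number of cycles in the block (>= 0).
#' @param mode \code{"compression"} or \code{"tension"}.
#' @param E_ratio Stiffness ratio \eqn{E/E^*}.
#' @param d_current Damage at the start of the block, in [0, 1].
#' @param Ca Calcium content, mg/g (tension coefficient).
#' @param params A \code{bone_params} object.
#' @return Updated damage in [0, 1] (1 = local failure).
#' @export
damage_accumulation <- function(eps_mu, N, mode = c("compression", "tension"),
                                E_ratio = 1, d_current = 0,
                                Ca = calcium_content(0.6),
                                params = bone_parameters()) {
  mode <- match.arg(mode)
  stopifnot(N >= 0, d_current >= 0, d_current <= 1, E_ratio > 0)
  if (N == 0 || eps_mu <= 0) return(d_current)
  if (d_current >= 1) return(1)
  X <- fatigue_severity(eps_mu, mode, E_ratio)

  if (mode == "compression") {
    gamma1 <- -5.238 * ((E_ratio * eps_mu - 6100) + 7) * 1e-3
    Nf <- 9.333e40 / X
    frac_used <- if (abs(gamma1) < 1e-9) d_current else
      -expm1(-gamma1 * d_current) / -expm1(-gamma1)   # (1-e^{-g d})/(1-e^{-g})
    frac <- frac_used + N / Nf
    if (frac >= 1) return(1)
    if (abs(gamma1) < 1e-9) return(frac)
    min(-log1p(frac * expm1(-gamma1)) / gamma1, 1)
  } else {
    gamma2 <- -0.018 * (E_ratio * eps_mu - 4100) + 12
    if (gamma2 <= 0)
      stop("tension damage law outside its validity range (gamma_2 <= 0)")
    C3 <- -20
    Kt <- tension_K(Ca, params)
    Nf <- Kt / X
    # inner argument runs from e^{C3} (d = 0) to 1 (d = 1)
    inner_cur <- exp(C3 * (1 - d_current)^gamma2)
    frac_used <- (inner_cur - exp(C3)) / (1 - exp(C3))
    frac <- frac_used + N / Nf
    if (frac >= 1) return(1)
    inner <- exp(C3) + frac * (1 - exp(C3))
    min(1 - (log(inner) / C3)^(1 / gamma2), 1)
  }
}

#' Damage repair rate through resorption
#'
#' Microcracks are removed with the bone that carries them:
#' \eqn{\dot d_{rep} = \dot v_R d / v_b} with \eqn{\dot v_R = k_{res} C}
#' the resorption rate.
#'
#' @param v_dot_R Resorption rate, volume fraction per day.
#' @param d Damage in [0, 1].
#' @param v_b Bone volume fraction (> 0).
#' @return Repair rate, 1/day.
#' @export
damage_repair_rate <- function(v_dot_R, d, v_b) {
  stopifnot(v_dot_R >= 0, d >= 0, d <= 1)
  if (v_b <= 0) stop("v_b must be strictly positive")
  v_dot_R * d / v_b
}

#' Elastic modulus from composition and damage
#'
#' Power-law composition model
#' \eqn{E = 84370\, v_b^{2.58} \bar\alpha^{2.74} (1 - d)} MPa.
#'
#' @param v_b Bone volume fraction (vectorized).
#' @param alpha_bar Mean ash fraction.
#' @param d Damage in [0, 1].
#' @param params A \code{bone_params} object.
#' @return Elastic modulus, MPa.
#' @export
elastic_modulus <- function(v_b, alpha_bar, d = 0,
                            params = bone_parameters()) {
  stopifnot(all(v_b >= 0), all(alpha_bar >= 0), all(d >= 0 & d <= 1))
  me <- params$mechano
  me$E_coeff * v_b^me$exp_vb * alpha_bar^me$exp_alpha * (1 - d)
}

#' Stiffness ratio entering the fatigue laws
#'
#' \eqn{E/E^*} with the reference modulus \eqn{E^*} taken as the
#' undamaged cortical-bone modulus at the current ash fraction, so the
#' ratio reduces to \eqn{(v_b / v_{b,cort})^{2.58} (1 - d)} and equals 1
#' for undamaged cortical bone.
#'
#' @param v_b Bone volume fraction.
#' @param d Damage in [0, 1].
#' @param params A \code{bone_params} object.
#' @return The dimensionless ratio \eqn{E/E^*}.
#' @export
stiffness_ratio <- function(v_b, d = 0, params = bone_parameters()) {
  (v_b / params$mechano$v_b_cortical)^params$mechano$exp_vb * (1 - d)
}
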