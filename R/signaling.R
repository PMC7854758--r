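#' PTH receptor occupancy
#'
#' Pseudo-steady occupancy of the PTH receptor under systemic PTH
#' synthesis and removal: \eqn{\pi_{PTH} = P / (P + P^s)} with
#' \eqn{P = S_P / k_P} and \eqn{P^s = k_6 / k_5}.
#'
#' @param params A \code{bone_params} object.
#' @return Occupancy fraction in [0, 1].
#' @export
pth_occupancy <- function(params = bone_parameters()) {
  ch <- params$chemical
  P <- ch$S_P / ch$k_P
  P_s <- ch$k_6 / ch$k_5
  P / (P + P_s)
}

#' Pseudo-steady OPG concentration
#'
#' OPG production by responding osteoblasts balanced against first-order
#' removal: \eqn{O = K_O^P B_r / (k_O \pi_{PTH})}.
#'
#' @param B_r Responding osteoblast concentration, pM.
#' @param pi_PTH PTH occupancy (> 0).
#' @param params A \code{bone_params} object.
#' @return OPG concentration, pM.
#' @export
opg_concentration <- function(B_r, pi_PTH, params = bone_parameters()) {
  if (pi_PTH <= 0) stop("pi_PTH must be strictly positive")
  params$chemical$K_O_P / (params$chemical$k_O * pi_PTH) * B_r
}

#' RANK-L occupancy of RANK, with optional denosumab competition
#'
#' Pseudo-steady fraction of RANK bound by RANK-L. OPG and (when present)
#' free denosumab compete for RANK-L, each entering the denominator
#' through its binding ratio; the drug term is \eqn{C_d / K_D} in matched
#' (nM) units. With \code{C_d = 0} this reduces to the drug-free
#' occupancy.
#'
#' @param B_a Active osteoblast concentration, pM.
#' @param O OPG concentration, pM.
#' @param C_d Free denosumab concentration, nM (default 0).
#' @param params A \code{bone_params} object.
#' @param k3_k4_ratio RANK/RANK-L binding ratio \eqn{k_3/k_4}
#'   (1/pM); defaults to the unmodulated registry value. Pass the
#'   mechano-modulated ratio from \code{\link{modulated_rates}} to couple
#'   mechanics.
#' @param pi_PTH PTH occupancy; defaults to \code{pth_occupancy(params)}.
#' @return Occupancy fraction in [0, 1].
#' @export
rankl_occupancy <- function(B_a, O, C_d = 0, params = bone_parameters(),
                            k3_k4_ratio = NULL, pi_PTH = NULL) {
  ch <- params$chemical
  if (is.null(k3_k4_ratio)) k3_k4_ratio <- ch$k_3 / ch$k_4
  if (is.null(pi_PTH)) pi_PTH <- pth_occupancy(params)
  stopifnot(B_a >= 0, O >= 0, C_d >= 0)
  num <- k3_k4_ratio * ch$K_L_P * pi_PTH * B_a
  den <- 1 + k3_k4_ratio * ch$K + (ch$k_1 / ch$k_2) * O + C_d / K_D_nM(params)
  min(num / den, 1)
}

#' TGF-beta receptor occupancy
#'
#' Osteoclast-driven TGF-beta signal of the Lemaire lineage:
#' \eqn{\pi_{TGF\beta} = (C + f_0 C_s) / (C + C_s)}, saturating at 1 and
#' bounded below by the basal fraction \eqn{f_0}.
#'
#' @param C Active osteoclast concentration, pM.
#' @param params A \code{bone_params} object.
#' @return Occupancy fraction in \code{[f_0, 1]}.
#' @export
tgfb_occupancy <- function(C, params = bone_parameters()) {
  stopifnot(all(C >= 0))
  ch <- params$chemical
  (C + ch$f_0 * ch$C_s) / (C + ch$C_s)
}

#' Cycle-weighted mechanical stimulus
#'
#' \eqn{\xi = (\sum_i N_i \bar\varepsilon_i^m)^{1/m}} over the daily load
#' blocks; an empty load set is disuse (\eqn{\xi = 0}).
#'
#' @param N Vector of daily cycle counts per load block.
#' @param eps Vector of equivalent strains (dimensionless) per block.
#' @param m Weighing exponent (default from the registry).
#' @return The stimulus \eqn{\xi} (dimensionless).
#' @export
#' @examples
#' mechanical_stimulus(10000, 2.5e-4)  # the reference equilibrium stimulus
mechanical_stimulus <- function(N, eps, m = bone_parameters()$mechano$m) {
  stopifnot(length(N) == length(eps), all(N >= 0), all(eps >= 0))
  if (length(N) == 0L) return(0)
  sum(N * eps^m)^(1 / m)
}

#' Equivalent strain from strain energy density
#'
#' \eqn{\bar\varepsilon = \sqrt{2u/E}}; for uniaxial stress
#' \eqn{\sigma}, \eqn{u = \sigma^2/(2E)} so
#' \eqn{\bar\varepsilon = \sigma/E}.
#'
#' @param u Strain energy density, MPa.
#' @param E Elastic modulus, MPa (> 0).
#' @return Dimensionless equivalent strain.
#' @export
equivalent_strain <- function(u, E) {
  stopifnot(all(u >= 0))
  if (any(E <= 0)) stop("E must be strictly positive")
  sqrt(2 * u / E)
}

#' Inhibitory remodeling signal
#'
#' \eqn{S = \xi/(\xi + c) (1-d)^{a v_b}}: the cell-to-cell mechanical
#' signal saturates with the stimulus and is attenuated by microdamage,
#' the more strongly the denser the bone.
#'
#' @param xi Mechanical stimulus (>= 0).
#' @param d Damage in [0, 1].
#' @param v_b Bone volume fraction in (0, 1].
#' @param params A \code{bone_params} object.
#' @return Signal in [0, 1].
#' @export
remodeling_signal <- function(xi, d, v_b, params = bone_parameters()) {
  stopifnot(xi >= 0, d >= 0, d <= 1, v_b > 0, v_b <= 1)
  me <- params$mechano
  xi / (xi + me$c) * (1 - d)^(me$a * v_b)
}

#' Mechano-modulated binding and unbinding rates
#'
#' Binding accelerates and unbinding slows, symmetrically, when the
#' inhibitory signal falls below saturation:
#' \eqn{k_f = k_{f0} e^{\gamma (1-S) \hat S_v}},
#' \eqn{k_r = k_{r0} e^{-\gamma (1-S) \hat S_v}}, with \eqn{\gamma}
#' the current-to-initial volume-fraction ratio and \eqn{\hat S_v} the
#' normalized specific surface. The product \eqn{k_f k_r} is invariant.
#'
#' @param k_f0,k_r0 Unmodulated binding/unbinding rates.
#' @param S Remodeling signal in [0, 1].
#' @param gamma_bond Ratio \eqn{v_b / v_{b0}}.
#' @param S_v_hat Normalized specific surface in [0, 1].
#' @return List with elements \code{k_f} and \code{k_r}.
#' @export
modulated_rates <- function(k_f0, k_r0, S, gamma_bond, S_v_hat) {
  stopifnot(S >= 0, S <= 1, S_v_hat >= 0, S_v_hat <= 1, gamma_bond >= 0)
  ex <- exp(gamma_bond * (1 - S) * S_v_hat)
  list(k_f = k_f0 * ex, k_r = k_r0 / ex)
}

#' Normalized specific bone surface
#'
#' Quintic specific-surface polynomial
#' \eqn{S_v = 32.3 v_b - 93.9 v_b^2 + 134 v_b^3 - 101 v_b^4 + 28.8 v_b^5}
#' (mm^2/mm^3), normalized by its 4.17 mm^2/mm^3 maximum; the surface
#' available for remodeling peaks in trabecular bone (v_b near 0.37) and
#' nearly vanishes for compact bone.
#'
#' @param v_b Bone volume fraction in [0, 1] (vectorized).
#' @param params A \code{bone_params} object.
#' @return Normalized specific surface in (0, 1].
#' @export
specific_surface <- function(v_b, params = bone_parameters()) {
  if (any(v_b < 0 | v_b > 1)) stop("v_b must lie in [0, 1]")
  S_v <- 32.3 * v_b - 93.9 * v_b^2 + 134 * v_b^3 - 101 * v_b^4 + 28.8 * v_b^5
  pmin(S_v / params$mechano$S_v_max, 1)
}

# Effective k3/k4 ratio under mechano-modulation applied to the RANK /
# RANK-L pair: both rates shift by exp(+/- g) so the ratio gains exp(2g).
effective_k3_k4 <- function(S, gamma_bond, S_v_hat, params,
                            modulate = TRUE) {
  r0 <- params$chemical$k_3 / params$chemical$k_4
  if (!modulate) return(r0)
  mod <- modulated_rates(params$chemical$k_3, params$chemical$k_4,
                         S, gamma_bond, S_v_hat)
  mod$k_f / mod$k_r
}

#' Time derivatives of the bone-cell populations
#'
#' Lemaire-type population balance for responding osteoblasts, active
#' osteoblasts and active osteoclasts, with the osteoclast production
#' term inhibited by the bone-bound bisphosphonate concentration
#' (\code{c_b}, ug/l) and RANK-L occupancy already carrying the free
#' denosumab competition.
#'
#' @param cell Named vector \code{c(B_r, B_a, C)}, pM.
#' @param params A \code{bone_params} object.
#' @param C_d Free denosumab concentration, nM.
#' @param c_b Bone-compartment bisphosphonate concentration, ug/l.
#' @param k3_k4_ratio Effective RANK/RANK-L binding ratio (1/pM);
#'   defaults to the unmodulated value.
#' @return List: \code{deriv} (named derivative vector, pM/day) and the
#'   occupancies \code{pi_TGFb}, \code{pi_RANKL}, \code{pi_PTH},
#'   \code{O} used to evaluate them.
#' @export
cell_rhs <- function(cell, params = bone_parameters(), C_d = 0, c_b = 0,
                     k3_k4_ratio = NULL) {
  ch <- params$chemical
  pi_T <- tgfb_occupancy(cell[["C"]], params)
  if (pi_T <= 0) stop("TGF-beta occupancy vanished; cell dynamics singular")
  pi_P <- pth_occupancy(params)
  O <- opg_concentration(cell[["B_r"]], pi_P, params)
  pi_R <- rankl_occupancy(cell[["B_a"]], O, C_d, params,
                          k3_k4_ratio = k3_k4_ratio, pi_PTH = pi_P)
  ib <- params$ibandronate
  bp_inh <- 1 - ib$I_max_cell * c_b / (ib$IC_50 + c_b)
  deriv <- c(
    B_r = ch$D_R * pi_T - (ch$f_0 * ch$d_B) / pi_T * cell[["B_r"]],
    B_a = (ch$f_0 * ch$d_B) / pi_T * cell[["B_r"]] - ch$k_B * cell[["B_a"]],
    C = ch$D_C * pi_R * bp_inh - ch$D_A * pi_T * cell[["C"]]
  )
  list(deriv = deriv, pi_TGFb = pi_T, pi_RANKL = pi_R, pi_PTH = pi_P, O = O)
}

#' Drug-free steady state of the cell populations
#'
#' Solves the stationary cell balance under a given stimulus (default the
#' reference equilibrium stimulus) and no drug. The system reduces
#' analytically to a single scalar equation in the osteoclast
#' concentration (the osteoblast pools and OPG follow in closed form from
#' the TGF-beta occupancy), solved by a damped Newton iteration started
#' from the Lemaire-scale fixed point, with a bracketing fallback.
#'
#' @param params A \code{bone_params} object.
#' @param v_b0 Initial bone volume fraction (sets the specific surface
#'   entering the mechano-modulation).
#' @param xi Stimulus; defaults to the reference equilibrium value.
#' @param d Damage level (default 0).
#' @param modulate Apply mechano-modulation to the RANK/RANK-L pair
#'   (default TRUE).
#' @param tol Relative residual tolerance.
#' @param C_init Initial osteoclast guess for the Newton iteration
#'   (Lemaire-scale default); the root found is checked to be
#'   guess-independent in the test suite.
#' @return Named vector \code{c(B_r, B_a, C)} in pM with attribute
#'   \code{"residual"} (max absolute derivative at the returned state).
#' @export
solve_steady_state <- function(params = bone_parameters(), v_b0 = 0.458,
                               xi = NULL, d = 0, modulate = TRUE,
                               tol = 1e-12, C_init = 9.127e-4) {
  ch <- params$chemical
  if (is.null(xi)) xi <- params$mechano$xi_ref
  S <- remodeling_signal(xi, d, v_b0, params)
  Sv <- specific_surface(v_b0, params)
  r_eff <- effective_k3_k4(S, 1, Sv, params, modulate)
  pi_P <- pth_occupancy(params)

  g <- function(C) {
    pi_T <- tgfb_occupancy(C, params)
    B_r <- ch$D_R * pi_T^2 / (ch$f_0 * ch$d_B)
    B_a <- ch$D_R * pi_T / ch$k_B
    O <- opg_concentration(B_r, pi_P, params)
    pi_R <- r_eff * ch$K_L_P * pi_P * B_a /
      (1 + r_eff * ch$K + ch$k_1 / ch$k_2 * O)
    ch$D_C * pi_R - ch$D_A * pi_T * C
  }
  # damped Newton (numeric derivative) from the Lemaire-scale guess
  C <- C_init
  for (it in 1:200) {
    f <- g(C)
    h <- max(1e-8 * C, 1e-12)
    df <- (g(C + h) - f) / h
    step <- f / df
    C_new <- C - step
    damp <- 1
    while ((!is.finite(C_new) || C_new <= 0) && damp > 1e-6) {
      damp <- damp / 2
      C_new <- C - damp * step
    }
    if (!is.finite(C_new) || C_new <= 0) break
    if (abs(C_new - C) <= tol * max(C, C_new)) { C <- C_new; break }
    C <- C_new
  }
  if (!is.finite(C) || C <= 0 || abs(g(C)) > 1e-9 * max(ch$D_C, 1)) {
    root <- stats::uniroot(g, c(1e-12, 10), tol = 1e-15)
    C <- root$root
  }
  pi_T <- tgfb_occupancy(C, params)
  state <- c(B_r = ch$D_R * pi_T^2 / (ch$f_0 * ch$d_B),
             B_a = ch$D_R * pi_T / ch$k_B,
             C = C)
  res <- cell_rhs(state, params, k3_k4_ratio = r_eff)$deriv
  if (max(abs(res)) > 1e-8 * max(state))
    stop("steady-state solve failed to converge; max residual ",
         format(max(abs(res))))
  attr(state, "residual") <- max(abs(res))
  state
}
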