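# Independent oracles used across the suite.

# Brute-force mineral bookkeeping: every daily formation event is kept as
# an explicit packet with its own deposition day; resorption removes a
# proportional share of every packet (removal at the current mean);
# packets age along the exponential mineralization curve individually.
# Deliberately O(days^2): the reference against the incremental recursion.
packet_ash_series <- function(dv_form, dv_res, v_b0,
                              p = bone_parameters()) {
  me <- p$mechano
  kr <- 1 / (me$kappa_years * 365)
  age <- 0                      # pre-existing bone
  vol <- v_b0
  a_start <- me$alpha_ini
  n <- length(dv_form)
  out <- numeric(n + 1)
  alpha_of <- function(age, a0) me$alpha_max + (a0 - me$alpha_max) *
    exp(-kr * age)
  out[1] <- sum(vol * alpha_of(age, a_start)) / sum(vol)
  for (i in seq_len(n)) {
    age <- age + 1
    v_tot <- sum(vol)
    if (dv_res[i] > 0) vol <- vol * (1 - dv_res[i] / v_tot)
    if (dv_form[i] > 0) {
      age <- c(age, 0)
      vol <- c(vol, dv_form[i])
      a_start <- c(a_start, me$alpha_0)
    }
    out[i + 1] <- sum(vol * alpha_of(age, a_start)) / sum(vol)
  }
  out
}

# Free-drug concentration oracle: solve the quasi-equilibrium ligand
# binding balance C_tot = C_d + R_ss * C_d / (K_D + C_d) by bracketing,
# independently of the closed-form quadratic root.
free_conc_oracle <- function(C_tot, R_ss, K_D) {
  if (C_tot == 0) return(0)
  stats::uniroot(function(cd) cd + R_ss * cd / (K_D + cd) - C_tot,
                 c(0, C_tot), tol = 1e-14)$root
}
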