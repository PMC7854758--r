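#' Default model parameters
#'
#' Returns the full parameter registry of the coupled remodeling / PK-PD
#' model as a nested list with four blocks:
#' \describe{
#'   \item{chemical}{Cell-dynamics and receptor-ligand constants. Time in
#'     days, concentrations in pM.}
#'   \item{mechano}{Mechanical stimulus, mineralization, fatigue and
#'     stiffness constants. Stresses/moduli in MPa, fatigue strains in
#'     microstrain.}
#'   \item{denosumab}{Two-compartment target-mediated PK plus serum-NTX
#'     turnover PD. Drug concentrations in nM (\code{K_D} is converted from
#'     molar internally through \code{K_D_nM}).}
#'   \item{ibandronate}{Four-compartment PK (amounts in mg, volumes in l)
#'     plus urinary-CTX turnover PD.}
#' }
#'
#' Notes on naming: the receptor-ligand modulation exponent uses the ratio
#' of current to initial bone volume fraction, stored behaviourally as
#' \code{gamma_bond} (computed at run time, not a constant); the fatigue
#' limit coefficient is \code{beta_fatigue} (a distinct quantity).
#' \code{r_L} (RANK-L turnover rate) is retained for completeness but is
#' absorbed by the pseudo-steady occupancy algebra and unused.
#'
#' @return An object of class \code{bone_params}: a nested named list.
#' @export
#' @examples
#' p <- bone_parameters()
#' p$chemical$D_A    # osteoclast apoptosis rate, 1/day
bone_parameters <- function() {
  p <- list(
    chemical = list(
      D_R   = 7e-4,    # differentiation rate of osteoblast progenitors, pM/day
      D_C   = 2.1e-3,  # differentiation rate of osteoclast precursors, pM/day
      D_A   = 0.7,     # osteoclast apoptosis rate via TGF-beta, 1/day
      d_B   = 0.7,     # differentiation rate of responsive osteoblasts, 1/day
                       # (the flux in the cell balance is f_0 * d_B)
      k_B   = 0.189,   # death rate of active osteoblasts, 1/day
      C_s   = 5e-3,    # osteoclast level giving half differentiation flux, pM
      f_0   = 0.05,    # basal TGF-beta occupancy fraction
      K     = 10,      # fixed RANK concentration, pM
      k_1   = 1e-2,    # OPG/RANK-L binding, 1/pM/day
      k_2   = 10,      # OPG/RANK-L unbinding, 1/day
      k_3   = 5.8e-4,  # RANK/RANK-L binding, 1/pM/day
      k_4   = 1.7e-2,  # RANK/RANK-L unbinding, 1/day
      k_5   = 0.02,    # PTH receptor binding, 1/pM/day
      k_6   = 3,       # PTH receptor unbinding, 1/day
      K_L_P = 3e6,     # max RANK-L per cell, pmol/pmol cells
      K_O_P = 2e5,     # minimal OPG production per cell, pmol/day/pmol cells
      k_O   = 0.35,    # OPG removal, 1/day
      k_P   = 86,      # PTH removal, 1/day
      r_L   = 1e3,     # RANK-L production/elimination, pM/day (unused)
      S_P   = 250      # systemic PTH synthesis, pM/day
    ),
    mechano = list(
      N_cycles    = 10000,   # daily load cycles (500 for mandible runs)
      m           = 4,       # stimulus weighing exponent
      xi_ref      = 0.0025,  # reference equilibrium stimulus
      c           = 0.0025,  # stimulus activation parameter
      a           = 20,      # damage activation parameter
      d_0         = 0,       # initial damage
      alpha_ini   = 0.6,     # ash fraction of pre-existing bone
      alpha_0     = 0.45,    # ash fraction of freshly deposited bone
      alpha_max   = 0.7,     # asymptotic ash fraction
      kappa_years = 6,       # secondary mineralization period, years
      beta_fatigue = 5,      # fatigue limit coefficient
      k_crack     = 0.00034, # microcrack density per unit damage
      S_v_max     = 4.17,    # maximum specific bone surface, mm^2/mm^3
      E_coeff     = 84370,   # stiffness-composition coefficient, MPa
      exp_vb      = 2.58,    # volume-fraction exponent in the modulus law
      exp_alpha   = 2.74,    # ash-fraction exponent in the modulus law
      v_b_min     = 0.01,    # lower integration clamp on volume fraction
      v_b_max     = 0.99,    # upper integration clamp on volume fraction
      rho_organic = 1.41,    # g/cm^3, density-composition intercept
      rho_mineral = 1.29,    # g/cm^3, density-composition ash slope
      v_b_cortical = 2.05 / (1.41 + 1.29 * 0.6)  # reference cortical v_b
    ),
    denosumab = list(
      k_a    = 0.167,     # subcutaneous absorption rate, 1/day
      k_int  = 2.67e-2,   # drug-ligand complex internalization, 1/day
      k_el   = 2.12e-2,   # central elimination rate, 1/day
      K_D    = 3.0e-12,   # equilibrium dissociation constant, M
      Vc_F   = 0.114,     # bioavailability-adjusted central volume, l/kg
      R_ss   = 1.07,      # steady-state free ligand, nM
      I_max  = 0.331,     # maximal fractional NTX inhibition
      IC_50  = 2.64,      # free-drug concentration at half inhibition, nM
      k_out  = 0.572,     # NTX removal rate, 1/day
      NTX_ss = c("0.1" = 9.8, "0.3" = 9.1, "1" = 10.2, "3" = 8.1),  # nM
      molar_mass = 147000 # g/mol, IgG2-scale antibody (configurable)
    ),
    ibandronate = list(
      V_pl  = 4.30,   # plasma volume, l
      V_p1  = 2.80,   # peripheral-1 volume, l
      V_p2  = 8.70,   # peripheral-2 volume, l
      V_b   = 609.00, # bone compartment volume, l
      Q_p1  = 69.43,  # plasma/peripheral-1 clearance, l/day
      Q_p2  = 18.57,  # plasma/peripheral-2 clearance, l/day
      Q_b   = 51.71,  # plasma/bone clearance, l/day
      CL    = 57.00,  # renal clearance, l/day
      KS    = 231.43, # uCTX formation rate, ug/mmolCR/day
      KD_uctx = 0.68, # uCTX degradation rate, 1/day
      R_tar = 194.29, # limiting uCTX formation rate, ug/mmolCR/day
      k_qq  = 0.0024, # ramp rate toward R_tar, 1/day
      IC_50 = 0.37,   # bone-compartment concentration at half response, ug/l
      n_hill = 1.92,  # Hill coefficient of the uCTX response
      I_max_cell = 1  # maximal inhibition of osteoclast differentiation
    )
  )
  class(p) <- "bone_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity of rates/volumes, the ash-fraction ordering
#' `alpha_0 <= alpha_ini <= alpha_max <= 1`, the damage and inhibition
#' bounds, and that unbinding rates are strictly positive so binding
#' ratios are finite.
#'
#' @param p A \code{bone_params} object.
#' @return \code{p}, invisibly; errors on the first violated invariant.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "bone_params"))
  ch <- p$chemical
  pos <- c("D_R", "D_C", "D_A", "d_B", "k_B", "C_s", "K", "k_1", "k_2",
           "k_3", "k_4", "k_5", "k_6", "K_L_P", "K_O_P", "k_O", "k_P",
           "r_L", "S_P")
  for (nm in pos) {
    if (!is.numeric(ch[[nm]]) || length(ch[[nm]]) != 1L || ch[[nm]] <= 0)
      stop("chemical.", nm, " must be a single strictly positive number")
  }
  if (ch$f_0 < 0 || ch$f_0 > 1)
    stop("chemical.f_0 must lie in [0, 1]")
  me <- p$mechano
  if (!(me$alpha_0 <= me$alpha_ini && me$alpha_ini <= me$alpha_max &&
        me$alpha_max <= 1 && me$alpha_0 >= 0))
    stop("ash fractions must satisfy 0 <= alpha_0 <= alpha_ini <= alpha_max <= 1")
  if (me$d_0 < 0 || me$d_0 >= 1)
    stop("mechano.d_0 must lie in [0, 1)")
  for (nm in c("N_cycles", "m", "xi_ref", "c", "a", "kappa_years",
               "beta_fatigue", "k_crack", "S_v_max", "E_coeff", "exp_vb",
               "exp_alpha")) {
    if (me[[nm]] <= 0) stop("mechano.", nm, " must be strictly positive")
  }
  de <- p$denosumab
  for (nm in c("k_a", "k_int", "k_el", "K_D", "Vc_F", "R_ss", "IC_50",
               "k_out", "molar_mass")) {
    if (de[[nm]] <= 0) stop("denosumab.", nm, " must be strictly positive")
  }
  if (de$I_max < 0 || de$I_max > 1)
    stop("denosumab.I_max must lie in [0, 1]")
  if (any(de$NTX_ss <= 0)) stop("denosumab.NTX_ss values must be positive")
  ib <- p$ibandronate
  for (nm in c("V_pl", "V_p1", "V_p2", "V_b", "Q_p1", "Q_p2", "Q_b", "CL",
               "KS", "KD_uctx", "R_tar", "k_qq", "IC_50", "n_hill")) {
    if (ib[[nm]] <= 0) stop("ibandronate.", nm, " must be strictly positive")
  }
  if (ib$I_max_cell < 0 || ib$I_max_cell > 1)
    stop("ibandronate.I_max_cell must lie in [0, 1]")
  invisible(p)
}

#' Override a single parameter by dotted key path
#'
#' @param p A \code{bone_params} object.
#' @param key_path Dotted path such as \code{"denosumab.K_D"} or
#'   \code{"chemical.k_2"}.
#' @param value Replacement value; the resulting set is re-validated.
#' @return A new \code{bone_params} object differing only at
#'   \code{key_path}.
#' @export
#' @examples
#' p <- set_parameter(bone_parameters(), "mechano.a", 20)
set_parameter <- function(p, key_path, value) {
  stopifnot(inherits(p, "bone_params"), is.character(key_path),
            length(key_path) == 1L)
  parts <- strsplit(key_path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("key path must have the form '<block>.<name>': ", key_path)
  if (!parts[1] %in% names(p))
    stop("unknown parameter block: ", parts[1])
  if (!parts[2] %in% names(p[[parts[1]]]))
    stop("unknown parameter: ", key_path)
  p[[parts[1]]][[parts[2]]] <- value
  validate_parameters(p)
  p
}

#' Apply a named list of dotted-path overrides
#'
#' @param p A \code{bone_params} object.
#' @param overrides Named list or vector, names are dotted key paths.
#' @return The updated, validated parameter set.
#' @export
set_parameters <- function(p, overrides) {
  if (length(overrides) == 0L) return(p)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("overrides must be a fully named list of dotted key paths")
  for (k in names(overrides)) p <- set_parameter(p, k, overrides[[k]])
  p
}

#' Denosumab dissociation constant in nM
#' @param p A \code{bone_params} object.
#' @return \code{K_D} expressed in nM.
#' @keywords internal
K_D_nM <- function(p) p$denosumab$K_D * 1e9

#' Mineralization rate constant in 1/day
#'
#' The secondary mineralization period (in years) is interpreted as the
#' time constant of the exponential ash-fraction kinetics.
#' @param p A \code{bone_params} object.
#' @keywords internal
kappa_rate <- function(p) 1 / (p$mechano$kappa_years * 365)

#' Serialize parameters to JSON
#'
#' Full-precision dump used for provenance logging; the companion
#' \code{read_parameters_json} reproduces the set bit-exactly.
#'
#' @param p A \code{bone_params} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_parameters_json <- function(p, path) {
  stopifnot(inherits(p, "bone_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Read parameters from JSON
#' @param path File written by \code{\link{write_parameters_json}}.
#' @return A validated \code{bone_params} object.
#' @export
read_parameters_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- bone_parameters()
  for (blk in names(p)) {
    for (nm in names(p[[blk]])) {
      v <- raw[[blk]][[nm]]
      if (is.null(v)) stop("missing parameter in JSON: ", blk, ".", nm)
      v <- as.numeric(unlist(v))       # JSON integers parse as integer
      if (nm == "NTX_ss") names(v) <- names(p[[blk]][[nm]])
      p[[blk]][[nm]] <- v
    }
  }
  validate_parameters(p)
  p
}

#' @export
print.bone_params <- function(x, ...) {
  cat("<bone_params>\n")
  for (blk in names(x)) {
    cat(sprintf("  $%s: %d parameters\n", blk, length(x[[blk]])))
  }
  invisible(x)
}
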