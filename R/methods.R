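#' @export
print.bone_scenario <- function(x, ...) {
  cat("<bone_scenario>\n")
  cat(sprintf("  initial density : %.3g g/cm^3\n", x$initial_density))
  load <- switch(x$load_mode,
                 disuse = "disuse (xi = 0)",
                 equilibrium = "equilibrium stimulus",
                 overload = sprintf("overload (%g x reference stimulus)",
                                    x$overload_factor),
                 constant_stress = sprintf("constant stress %g MPa (%s)",
                                           x$stress_MPa, x$stress_mode))
  cat("  loading         :", load, "\n")
  if (is.null(x$schedule) || x$schedule$dose <= 0) {
    cat("  treatment       : none (control)\n")
  } else {
    s <- x$schedule
    unit <- if (s$drug == "denosumab") "mg/kg" else "mg"
    cat(sprintf("  treatment       : %s %g %s every %g days\n",
                s$drug, s$dose, unit, s$interval))
  }
  cat(sprintf("  duration        : %d days\n", x$duration))
  invisible(x)
}

#' @export
print.bone_sim <- function(x, ...) {
  cat("<bone_sim> coupled remodeling / PK-PD point simulation\n")
  print(x$scenario)
  s <- x$series
  n <- nrow(s)
  cat(sprintf("  v_b   : %.4f -> %.4f (%+.1f%%)\n", s$v_b[1], s$v_b[n],
              100 * (s$v_b[n] - s$v_b[1]) / s$v_b[1]))
  cat(sprintf("  alpha : %.4f -> %.4f\n", s$alpha_bar[1], s$alpha_bar[n]))
  cat(sprintf("  damage: %.4g -> %.4g\n", s$damage[1], s$damage[n]))
  invisible(x)
}

#' @export
summary.bone_sim <- function(object, ...) {
  s <- object$series
  n <- nrow(s)
  out <- list(
    scenario = object$scenario,
    days = n - 1L,
    v_b_initial = s$v_b[1], v_b_final = s$v_b[n], v_b_max = max(s$v_b),
    v_b_change_pct = 100 * (s$v_b[n] - s$v_b[1]) / s$v_b[1],
    alpha_final = s$alpha_bar[n],
    damage_max = max(s$damage),
    E_final_MPa = s$E_MPa[n],
    biomarker_trough_pct = if (all(is.na(s$biomarker_pct_baseline))) NA_real_
      else min(s$biomarker_pct_baseline, na.rm = TRUE)
  )
  class(out) <- "summary.bone_sim"
  out
}

#' @export
print.summary.bone_sim <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("  %d days simulated\n", x$days))
  cat(sprintf("  bone volume fraction: %.4f -> %.4f (max %.4f, %+.1f%%)\n",
              x$v_b_initial, x$v_b_final, x$v_b_max, x$v_b_change_pct))
  cat(sprintf("  final ash fraction  : %.4f\n", x$alpha_final))
  cat(sprintf("  peak damage         : %.4g\n", x$damage_max))
  cat(sprintf("  final modulus       : %.0f MPa\n", x$E_final_MPa))
  if (!is.na(x$biomarker_trough_pct))
    cat(sprintf("  biomarker trough    : %.1f%% of baseline\n",
                x$biomarker_trough_pct))
  invisible(x)
}

#' @export
as.data.frame.bone_sim <- function(x, ...) x$series

#' Plot the standard simulation panels
#'
#' Time courses of the bone volume fraction, mean ash fraction, damage,
#' elastic modulus and (when a drug is dosed) the turnover biomarker as
#' percent of baseline.
#'
#' @param x A \code{bone_sim}.
#' @param which Subset of panels, any of \code{"v_b"}, \code{"alpha_bar"},
#'   \code{"damage"}, \code{"E_MPa"}, \code{"biomarker"}.
#' @param ... Passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @export
plot.bone_sim <- function(x, which = c("v_b", "alpha_bar", "damage",
                                       "E_MPa", "biomarker"), ...) {
  s <- x$series
  which <- match.arg(which, several.ok = TRUE)
  if (all(is.na(s$biomarker_pct_baseline)))
    which <- setdiff(which, "biomarker")
  labs <- c(v_b = "bone volume fraction",
            alpha_bar = "mean ash fraction", damage = "damage",
            E_MPa = "elastic modulus (MPa)",
            biomarker = "biomarker (% baseline)")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)),
                       mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  for (w in which) {
    y <- if (w == "biomarker") s$biomarker_pct_baseline else s[[w]]
    graphics::plot(s$time, y, type = "l", xlab = "time (days)",
                   ylab = labs[[w]], ...)
  }
  invisible(x)
}
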