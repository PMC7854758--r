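#' Load a run configuration
#'
#' Reads a YAML (or JSON) run configuration with up to three blocks:
#' \code{scenario} (either \code{preset: <name>} or inline
#' \code{\link{bone_scenario}} fields plus \code{drug}/\code{dose}/
#' \code{interval}/\code{first_dose_time}/\code{n_doses}),
#' \code{parameters} (dotted-path overrides) and \code{output}
#' (\code{csv}, \code{json} paths). Unknown keys raise an error naming
#' every offender; an empty file yields the control scenario with
#' default parameters.
#'
#' @param path Configuration file path.
#' @return List with validated elements \code{scenario}
#'   (\code{bone_scenario}), \code{params} (\code{bone_params}) and
#'   \code{output} (list, possibly empty).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), c("scenario", "parameters", "output"))
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))

  params <- bone_parameters()
  if (!is.null(cfg$parameters)) params <- set_parameters(params, cfg$parameters)

  sc_cfg <- if (is.null(cfg$scenario)) list() else cfg$scenario
  sc_keys <- c("preset", "initial_density", "load_mode", "overload_factor",
               "stress_MPa", "duration", "N_cycles_per_day", "stress_mode",
               "drug", "dose", "interval", "first_dose_time", "n_doses")
  bad <- setdiff(names(sc_cfg), sc_keys)
  if (length(bad))
    stop("unknown scenario keys: ", paste(bad, collapse = ", "))

  if (!is.null(sc_cfg$preset)) {
    presets <- scenario_presets()
    if (!sc_cfg$preset %in% names(presets))
      stop("unknown preset: ", sc_cfg$preset)
    scenario <- presets[[sc_cfg$preset]]
  } else {
    schedule <- NULL
    if (!is.null(sc_cfg$drug) && !is.null(sc_cfg$dose) && sc_cfg$dose > 0) {
      schedule <- dose_schedule(
        sc_cfg$drug, sc_cfg$dose,
        interval = sc_cfg$interval,
        first_dose_time = if (is.null(sc_cfg$first_dose_time)) 0 else
          sc_cfg$first_dose_time,
        n_doses = if (is.null(sc_cfg$n_doses)) Inf else sc_cfg$n_doses)
    }
    args <- sc_cfg[intersect(names(sc_cfg),
                             c("initial_density", "load_mode",
                               "overload_factor", "stress_MPa", "duration",
                               "N_cycles_per_day", "stress_mode"))]
    args$schedule <- schedule
    scenario <- do.call(bone_scenario, args)
  }
  list(scenario = scenario, params = params,
       output = if (is.null(cfg$output)) list() else cfg$output)
}

# Full-precision CSV formatting: every double is written with 17
# significant digits so read -> write -> read round-trips exactly.
format_full_precision <- function(df) {
  as.data.frame(lapply(df, function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- NA
      out
    } else col
  }), optional = TRUE)
}

#' Write a simulation result to CSV plus JSON sidecar
#'
#' The daily series goes to \code{path} as plain CSV (full double
#' precision, stable column order); scenario, turnover rates, initial
#' steady state and the complete parameter set go to
#' \code{<path>.json}, together with an MD5 checksum of the CSV for
#' tamper detection on re-read.
#'
#' @param result A \code{bone_sim}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "bone_sim"))
  utils::write.csv(format_full_precision(result$series), path,
                   row.names = FALSE, quote = FALSE, na = "")
  sc <- result$scenario
  meta <- list(
    format_version = 1L,
    scenario = sc[!vapply(sc, is.null, logical(1))],
    rates = unclass(result$rates),
    steady_state = as.list(result$steady_state),
    v_b0 = result$v_b0,
    drug = result$drug,
    parameters = unclass(result$params),
    csv_md5 = unname(tools::md5sum(path))
  )
  if (!is.null(meta$scenario$schedule))
    meta$scenario$schedule <- unclass(meta$scenario$schedule)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Read a simulation result written by \code{write_result}
#'
#' Restores the daily series and metadata; warns if the CSV checksum no
#' longer matches the sidecar (file edited or corrupted).
#'
#' @param path CSV path (the sidecar is \code{<path>.json}).
#' @return A \code{bone_sim} object.
#' @export
read_result <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path))
    stop("result files not found: ", path, " / ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(unname(tools::md5sum(path)), meta$csv_md5))
    warning("CSV checksum does not match its sidecar; ",
            "the series may have been modified")
  series <- utils::read.csv(path)
  for (nm in setdiff(names(series), "time"))
    series[[nm]] <- as.numeric(series[[nm]])
  sc <- meta$scenario
  schedule <- NULL
  if (!is.null(sc$schedule))
    schedule <- do.call(dose_schedule, sc$schedule)
  scenario <- bone_scenario(
    initial_density = sc$initial_density, load_mode = sc$load_mode,
    overload_factor = if (is.null(sc$overload_factor) ||
                          is.na(sc$overload_factor)) 5 else sc$overload_factor,
    stress_MPa = sc$stress_MPa, schedule = schedule,
    duration = sc$duration, N_cycles_per_day = sc$N_cycles_per_day,
    stress_mode = sc$stress_mode)
  params <- bone_parameters()
  for (blk in names(params)) {
    for (nm in names(params[[blk]])) {
      v <- meta$parameters[[blk]][[nm]]
      if (!is.null(v)) {
        v <- as.numeric(unlist(v))
        if (nm == "NTX_ss") names(v) <- names(params[[blk]][[nm]])
        params[[blk]][[nm]] <- v
      }
    }
  }
  structure(list(series = series, scenario = scenario,
                 rates = structure(as.list(meta$rates),
                                   class = "turnover_rates"),
                 steady_state = unlist(meta$steady_state),
                 v_b0 = meta$v_b0, params = validate_parameters(params),
                 drug = meta$drug),
            class = "bone_sim")
}
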