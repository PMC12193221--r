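## Deterministic bench-planning calculators for the 20 uL PCR-HRM reaction:
## template-quantity rule (>= 10 ng total template DNA, whole-uL pipetting),
## master-mix scaling, and the thermocycler program.

#' Template and water volumes for the >= 10 ng rule
#'
#' The reaction needs at least `required_ng` of template DNA.  At least
#' `baseline_ul` (default 2 uL) of template is always added; dilute samples
#' get more, rounded up to whole microlitres, with water making the template
#' plus water slot up to `headroom_ul` (default 7 uL, i.e. the 5 uL water +
#' 2 uL template of the standard 20 uL mix).  Samples too dilute to reach
#' the requirement within the headroom are rejected with a suggestion to
#' re-extract.
#'
#' @param conc Template DNA concentration, ng/uL (> 0).
#' @param required_ng Minimum template mass per reaction, ng.
#' @param baseline_ul Baseline template volume, uL.
#' @param headroom_ul Combined template + water budget, uL.
#' @return List with `template_ul` and `water_ul` (integers).
#' @examples
#' template_volume(3.83)  # 3 uL template + 4 uL water
#' template_volume(138)   # 2 uL template + 5 uL water
#' @export
template_volume <- function(conc, required_ng = 10, baseline_ul = 2,
                            headroom_ul = 7) {
  if (!is.numeric(conc) || length(conc) != 1L || !is.finite(conc) ||
      conc <= 0) {
    stop("value error: conc must be a positive number (ng/uL)", call. = FALSE)
  }
  template <- max(as.integer(baseline_ul), as.integer(ceiling(required_ng / conc)))
  if (template > headroom_ul) {
    stop("infeasible: ", template, " uL of template needed but only ",
         headroom_ul, " uL of headroom; re-extract or concentrate the sample",
         call. = FALSE)
  }
  list(template_ul = template, water_ul = as.integer(headroom_ul - template))
}

#' Reaction-mix table for a batch of PCR-HRM samples
#'
#' Per-reaction volumes (uL): 2x Taq master mix 10, each primer 1,
#' saturation dye 1, then water and template filling the remaining 7 uL so
#' every reaction totals exactly 20 uL.  Batch volumes for everything except
#' the template (which is pipetted per tube) are scaled by
#' `n_samples * (1 + overage_frac)` to cover pipetting losses.
#'
#' @param n_samples Number of reactions (>= 1).
#' @param overage_frac Fractional overage on batch volumes.
#' @param template_ul Template volume per reaction (from
#'   [template_volume()]); must not exceed 7 uL.
#' @return Object of class `MixSpec`: data.frame `component`,
#'   `per_reaction_ul`, `batch_ul`, with attribute `total_ul` = 20.
#' @examples
#' mix_table(n_samples = 8, template_ul = 3)
#' @export
mix_table <- function(n_samples = 1L, overage_frac = 0.1, template_ul = 2L) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (template_ul > 7) {
    stop("infeasible: template volume exceeds the 7 uL headroom",
         call. = FALSE)
  }
  if (template_ul < 0) stop("template_ul must be >= 0", call. = FALSE)
  per <- c(master_mix = 10, primer1 = 1, primer2 = 1, dye = 1,
           water = 7 - template_ul, template = template_ul)
  batch <- per * n_samples * (1 + overage_frac)
  batch[["template"]] <- template_ul * n_samples  # pipetted per tube, no overage
  df <- data.frame(component = names(per), per_reaction_ul = unname(per),
                   batch_ul = unname(batch))
  structure(df, total_ul = sum(per), class = c("MixSpec", "data.frame"))
}

#' Thermocycler and melt-ramp program
#'
#' Fixed program structure: initial denaturation 95 degC 10 min; 35 cycles
#' of 95 degC 30 s, annealing at the primer pair's annealing temperature for
#' 30 s, extension 72 degC 45 s; final extension 72 degC 10 min; then the
#' HRM stage of 95 degC 1 min, 40 degC 1 min and a 65 to 90 degC ramp at
#' 0.1 degC/s.
#'
#' @param annealing_tm Annealing temperature in degrees Celsius, within
#'   40-72 (the COXI pair anneals at 48, the COXII pair at 53).
#' @return Object of class `ThermoProgram` (nested list), serializable with
#'   [program_json()].
#' @examples
#' thermocycler_program(53)
#' @export
thermocycler_program <- function(annealing_tm) {
  if (!is.numeric(annealing_tm) || annealing_tm < 40 || annealing_tm > 72) {
    stop("value error: annealing_tm must be within 40-72 degC", call. = FALSE)
  }
  structure(
    list(
      initial_denaturation = list(temp_c = 95, time_s = 600),
      cycles = list(
        count = 35L,
        denaturation = list(temp_c = 95, time_s = 30),
        annealing = list(temp_c = annealing_tm, time_s = 30),
        extension = list(temp_c = 72, time_s = 45)
      ),
      final_extension = list(temp_c = 72, time_s = 600),
      hrm = list(
        denaturation = list(temp_c = 95, time_s = 60),
        hold = list(temp_c = 40, time_s = 60),
        ramp = list(from_c = 65, to_c = 90, rate_c_per_s = 0.1)
      )
    ),
    class = "ThermoProgram"
  )
}

#' @export
print.ThermoProgram <- function(x, ...) {
  cat(sprintf(
    "<ThermoProgram> 95/10min; %dx [95/30s, %g/30s, 72/45s]; 72/10min; HRM ramp %g-%g degC @ %g degC/s\n",
    x$cycles$count, x$cycles$annealing$temp_c,
    x$hrm$ramp$from_c, x$hrm$ramp$to_c, x$hrm$ramp$rate_c_per_s))
  invisible(x)
}

#' Serialize a thermocycler program to JSON
#'
#' @param program A [thermocycler_program()].
#' @param path Optional output path; when omitted the JSON string is
#'   returned.
#' @return JSON string, or `path` invisibly when writing to file.
#' @export
program_json <- function(program, path = NULL) {
  if (is.null(path)) {
    jsonlite::toJSON(unclass(program), auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(unclass(program), path, auto_unbox = TRUE,
                         digits = NA)
    invisible(path)
  }
}
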