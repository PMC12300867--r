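#' Define an intake scenario
#'
#' A scenario is either the baseline (mean 2019 intake maintained over the
#' whole horizon) or a named target daily intake that every stratum is lifted
#' to immediately and maintains for the whole horizon. Individuals already at
#' or above the target keep their current intake; nobody is forced to reduce.
#'
#' @param name Scenario label; `"baseline"` is reserved for the no-change
#'   scenario.
#' @param target_intake Target intake in g/day, or `NULL` for baseline.
#' @return A `scenario` object.
#' @export
#' @examples
#' scenario("scenario1", 160)  # two servings of yogurt per day
#' scenario("scenario2", 80)   # one serving
#' baseline_scenario()
scenario <- function(name, target_intake = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (identical(name, "baseline") && is.null(target_intake)) {
    return(structure(list(name = "baseline", target_intake = NULL),
                     class = "scenario"))
  }
  if (is.null(target_intake)) {
    stop("scenario: target_intake is required unless name == 'baseline'")
  }
  stopifnot(is.numeric(target_intake), length(target_intake) == 1)
  if (target_intake < 0) stop("scenario: target_intake must be >= 0")
  structure(list(name = name, target_intake = target_intake),
            class = "scenario")
}

#' @rdname scenario
#' @export
baseline_scenario <- function() scenario("baseline")

is_baseline <- function(sc) is.null(sc$target_intake)

#' Intake change implied by a scenario
#'
#' The increase in daily intake a stratum experiences under a scenario:
#' zero for the baseline, otherwise `target - mean`, floored at zero so
#' strata already above the target are unchanged.
#'
#' @param stratum One row of a parameter set's `strata` table (or the whole
#'   table; the function is vectorised over rows).
#' @param sc A [scenario()].
#' @return Intake increase(s) in g/day, one per stratum row.
#' @export
#' @examples
#' ps <- japan_2019()
#' intake_delta(ps$strata[1, ], scenario("scenario1", 160))  # 160 - 24.5
intake_delta <- function(stratum, sc) {
  stopifnot(inherits(sc, "scenario"))
  if (is_baseline(sc)) return(rep(0, nrow(stratum)))
  pmax(0, sc$target_intake - stratum$mean_intake_g)
}

#' Relative risk for an intake change
#'
#' Log-linear (power-law) extrapolation of the dose-response relative risk:
#' an increase of `delta` g/day multiplies the annual risk of developing T2D
#' by `rr^(delta / increment)`. This is the standard reading of a
#' "per 50 g/day" dose-response risk: multiplicative in the dose, so
#' `rr(a + b) = rr(a) * rr(b)` exactly.
#'
#' @param delta Intake increase in g/day; must be non-negative (the model
#'   covers intake increases only).
#' @param dr A [dose_response()].
#' @param bound Which dose-response value to extrapolate: the point estimate
#'   (default) or a CI bound.
#' @return Risk multiplier(s) in (0, 1] for protective `rr < 1`.
#' @export
#' @examples
#' dr <- dose_response(0.93, 50, 0.89, 0.97)
#' rr_for_intake_change(50, dr)    # 0.93
#' rr_for_intake_change(100, dr)   # 0.93^2
rr_for_intake_change <- function(delta, dr,
                                 bound = c("point", "ci_low", "ci_high")) {
  stopifnot(inherits(dr, "dose_response"), is.numeric(delta))
  if (any(delta < 0)) {
    stop("rr_for_intake_change: negative intake change is outside the ",
         "modelled domain (intake increases only)")
  }
  bound <- match.arg(bound)
  rr <- switch(bound, point = dr$rr, ci_low = dr$ci_low, ci_high = dr$ci_high)
  rr ^ (delta / dr$increment)
}

#' Per-stratum relative-risk multipliers for a scenario
#'
#' Computes the multiplier applied to each stratum's T2D incidence
#' probability under a scenario. With `reference = "baseline"` the multiplier
#' is relative to the baseline arm: `rr^(delta/increment)` with `delta` from
#' [intake_delta()], so the baseline scenario maps to exactly 1 everywhere.
#' With `reference = "zero"` the multiplier is relative to a zero-intake
#' cohort: `rr^(intake/increment)` with the scenario's achieved intake
#' (`max(target, mean)`; the mean itself for baseline). The engine uses the
#' zero-intake reference (see [run_scenario()]): the published incidence
#' rates are treated as pre-intake rates and attenuated by the current intake
#' in every arm, which is the calibration that reproduces the published
#' projections; the reference cancels in all baseline-versus-scenario
#' comparisons.
#'
#' @param ps A [parameter_set()].
#' @param sc A [scenario()].
#' @param reference `"baseline"` (default) or `"zero"`, see above.
#' @param bound Dose-response value to use, as in [rr_for_intake_change()].
#' @return `data.frame` with columns `sex`, `age_band`, `rr_multiplier`.
#' @export
#' @examples
#' ps <- japan_2019()
#' scenario_rr_table(ps, baseline_scenario())$rr_multiplier  # all 1
scenario_rr_table <- function(ps, sc, reference = c("baseline", "zero"),
                              bound = c("point", "ci_low", "ci_high")) {
  stopifnot(inherits(ps, "parameter_set"), inherits(sc, "scenario"))
  reference <- match.arg(reference)
  bound <- match.arg(bound)
  s <- ps$strata
  exposure <- switch(
    reference,
    baseline = intake_delta(s, sc),
    zero = if (is_baseline(sc)) s$mean_intake_g
           else pmax(s$mean_intake_g, sc$target_intake)
  )
  data.frame(
    sex = s$sex, age_band = s$age_band,
    rr_multiplier = rr_for_intake_change(exposure, ps$dose_response, bound)
  )
}
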