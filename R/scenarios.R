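## Reference initial concentrations (mol per mol H2O) for the volatile
## reactants in carbonaceous planetesimal source material. Formaldehyde is
## the cometary value with a 1e-3 depletion factor folded in upstream (the
## nebular estimate for the warmer, partially devolatilized region where
## these parent bodies assembled); glycolaldehyde follows water ice and
## spans a two-decade range of cometary measurements.
.ch2o_predicted <- 6.6e-4
.gly_range <- c(lower = 5e-6, upper = 4e-4)
.ch2o_depletion_factor <- 1e-3

#' Construct a composition scenario
#'
#' A composition scenario bundles the initial molar concentrations of the
#' formose reactants (per mole of water, which is fixed at 1), the mineral
#' catalyst assumed present, and provenance metadata.
#'
#' @param ch2o Initial formaldehyde concentration, mol per mol H2O.
#' @param gly Initial glycolaldehyde concentration, mol per mol H2O.
#' @param catalyst One of \code{names(catalyst_yields())}.
#' @param label Free-text label.
#' @param provenance One of \code{"table1_lower"}, \code{"table1_upper"},
#'   \code{"sampled"}, \code{"custom"}. Reference provenances are validated
#'   against the canonical concentration ranges.
#' @return Object of class \code{composition_scenario}.
#' @export
composition_scenario <- function(ch2o, gly, catalyst = "Ca(OH)2",
                                 label = "", provenance = "custom") {
  provenance <- match.arg(provenance,
                          c("table1_lower", "table1_upper", "sampled", "custom"))
  if (!catalyst %in% names(catalyst_yields()))
    stop("unknown catalyst '", catalyst, "'; valid: ",
         paste(names(catalyst_yields()), collapse = ", "))
  if (!is.finite(ch2o) || !is.finite(gly) || ch2o < 0 || gly < 0)
    stop("concentrations must be finite and non-negative")
  if (provenance %in% c("table1_lower", "table1_upper") &&
      abs(ch2o - .ch2o_predicted) > 1e-12)
    stop("reference scenarios fix formaldehyde at ", .ch2o_predicted)
  if (provenance != "custom" &&
      (gly < .gly_range[["lower"]] - 1e-18 || gly > .gly_range[["upper"]] + 1e-18))
    stop("glycolaldehyde outside the reference range [5e-6, 4e-4]")
  structure(list(concentrations = c(water = 1, formaldehyde = ch2o,
                                    glycolaldehyde = gly),
                 catalyst = catalyst, label = label, provenance = provenance,
                 ch2o_depletion_factor = .ch2o_depletion_factor),
            class = "composition_scenario")
}

#' @export
print.composition_scenario <- function(x, ...) {
  cat("<composition_scenario> ", x$provenance,
      if (nzchar(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  cat("  CH2O = ", signif(x$concentrations[["formaldehyde"]], 4),
      ", C2H4O2 = ", signif(x$concentrations[["glycolaldehyde"]], 4),
      " mol/mol(H2O), catalyst ", x$catalyst, "\n", sep = "")
  invisible(x)
}

## amounts vector for chemistry entry points
scenario_concentrations <- function(scenario) {
  stopifnot(inherits(scenario, "composition_scenario"))
  scenario$concentrations
}

#' Reference composition scenarios (lower / upper glycolaldehyde bound)
#'
#' Builds the two canonical scenarios of the study: formaldehyde fixed at
#' 6.6e-4 mol/mol(H2O), glycolaldehyde at the lower (5e-6) or upper (4e-4)
#' bound of the cometary range.
#'
#' @param bound \code{"lower"} or \code{"upper"}.
#' @param catalyst Catalyst identifier, see \code{\link{catalyst_yields}}.
#' @return A \code{composition_scenario}.
#' @examples
#' table1_scenario("lower")
#' @export
table1_scenario <- function(bound = c("lower", "upper"), catalyst = "Ca(OH)2") {
  bound <- match.arg(bound)
  composition_scenario(.ch2o_predicted, .gly_range[[bound]],
                       catalyst = catalyst,
                       label = paste0(bound, "-bound glycolaldehyde"),
                       provenance = paste0("table1_", bound))
}

#' Sample composition scenarios over the glycolaldehyde range
#'
#' Draws glycolaldehyde concentrations log-uniformly over the reference
#' range [5e-6, 4e-4] mol/mol(H2O) (the range spans roughly two decades and
#' its endpoints are order-of-magnitude bounds, so a log-uniform measure is
#' the natural uninformative choice); formaldehyde is fixed. Reproducible
#' for a given seed.
#'
#' @param n Number of scenarios (>= 1).
#' @param seed Integer seed.
#' @param catalyst Catalyst identifier applied to every scenario.
#' @return List of \code{composition_scenario} objects.
#' @export
sample_scenarios <- function(n, seed, catalyst = "Ca(OH)2") {
  if (!is.finite(n) || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lg <- stats::runif(n, log(.gly_range[["lower"]]), log(.gly_range[["upper"]]))
  lapply(seq_len(n), function(i)
    composition_scenario(.ch2o_predicted, exp(lg[i]), catalyst = catalyst,
                         label = sprintf("sampled %d/%d", i, n),
                         provenance = "sampled"))
}

#' Toy temperature histories for chemistry tests
#'
#' Deterministic temperature-versus-time series that exercise the chemistry
#' and window analytics without running the thermal solver.
#'
#' @param shape \code{"constant"}, \code{"boxcar"} or \code{"ramp"}.
#' @param t_end End time in yr (history starts at 0).
#' @param n Number of equally spaced samples.
#' @param level Temperature (K) of the constant history.
#' @param cold,warm Temperatures (K) outside/inside the boxcar.
#' @param t_on,t_off Boxcar warm interval (yr); \code{t_off} must exceed
#'   \code{t_on}.
#' @param T_start,T_stop End temperatures (K) of the linear ramp.
#' @return Data frame with columns \code{time_yr}, \code{temperature_K}.
#' @examples
#' toy_thermal_history("boxcar", t_end = 3e6, t_on = 1e6, t_off = 2e6)
#' @export
toy_thermal_history <- function(shape = c("constant", "boxcar", "ramp"),
                                t_end = 1e6, n = 201, level = 150,
                                cold = 150, warm = 300,
                                t_on = t_end / 3, t_off = 2 * t_end / 3,
                                T_start = 150, T_stop = 350) {
  shape <- match.arg(shape)
  if (t_end <= 0 || n < 2) stop("need t_end > 0 and n >= 2")
  tt <- seq(0, t_end, length.out = n)
  temp <- switch(shape,
    constant = rep(level, n),
    boxcar = {
      if (t_off <= t_on) stop("boxcar requires t_off > t_on")
      ifelse(tt >= t_on & tt < t_off, warm, cold)
    },
    ramp = T_start + (T_stop - T_start) * tt / t_end
  )
  data.frame(time_yr = tt, temperature_K = temp)
}
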