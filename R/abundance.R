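## molar masses used in the ppb conversion, g/mol
.M_ribose <- 150.13
.M_h2o <- 18.015

#' Convert total-pentose abundance to ribose abundance
#'
#' The equilibrium model predicts the total pentose (5C) abundance; the
#' fraction of it that is ribose is taken from laboratory formose runs with
#' the given mineral catalyst (see \code{\link{catalyst_yields}}).
#'
#' @param pentose_molar Total-pentose abundance, mol per mol H2O (>= 0;
#'   vectorized).
#' @param catalyst Catalyst identifier.
#' @return Ribose abundance, mol per mol H2O.
#' @examples
#' apply_yield(2.5e-6, "Ca(OH)2")
#' @export
apply_yield <- function(pentose_molar, catalyst) {
  yields <- catalyst_yields()
  if (length(catalyst) != 1L || !catalyst %in% names(yields))
    stop("unknown catalyst '", catalyst, "'; valid options: ",
         paste(names(yields), collapse = ", "))
  if (any(!is.finite(pentose_molar)) || any(pentose_molar < 0))
    stop("'pentose_molar' must be finite and non-negative")
  unname(yields[[catalyst]]) * pentose_molar
}

#' Convert a water-normalized molar abundance to bulk-mass ppb
#'
#' Water-normalized molar abundances (mol per mol H2O) are converted to
#' parts per billion by mass of the bulk planetesimal (rock plus ice):
#' \deqn{ppb = n \cdot (M_{ribose}/M_{H_2O}) \cdot f_{ice} \cdot 10^9,}
#' where \eqn{f_{ice}} is the ice mass fraction of the bulk. This is the
#' baseline on which meteoritic concentrations are reported.
#'
#' @param ribose_molar Ribose abundance, mol per mol H2O (vectorized).
#' @param config Optional \code{planetesimal_config} supplying porosity and
#'   densities.
#' @param porosity,rho_ice,rho_rock Used when no config is given.
#' @return Concentration in ppb by mass of bulk planetesimal.
#' @examples
#' molar_to_mass_ppb(1.025e-7)   # about 61 ppb
#' @export
molar_to_mass_ppb <- function(ribose_molar, config = NULL, porosity = 0.2,
                              rho_ice = 0.917, rho_rock = 3) {
  f_ice <- ice_mass_fraction(config, porosity, rho_ice, rho_rock)
  ribose_molar * (.M_ribose / .M_h2o) * f_ice * 1e9
}

## shared finishing step: pentose -> ribose -> ppb, packaged as a profile
.finish_profile <- function(df, axis, scenario, config) {
  df$ribose_molar <- apply_yield(df$pentose_molar, scenario$catalyst)
  df$ribose_ppb <- molar_to_mass_ppb(df$ribose_molar, config)
  structure(df, class = c("abundance_profile", "data.frame"),
            axis = axis, catalyst = scenario$catalyst,
            scenario = scenario$provenance)
}

#' Radial abundance profile at peak temperature
#'
#' For each radius, equilibrates the composition scenario at the maximum
#' temperature reached there over the whole thermal history, provided that
#' maximum reaches the melting point of water; colder radii retain zero
#' product. Peak production is thereby attributed to the peak temperature
#' at each depth.
#'
#' @param field A \code{thermal_field}.
#' @param scenario A \code{composition_scenario}.
#' @param table A \code{gibbs_table} (defaults to the packaged table).
#' @param threshold Liquid-water threshold, K.
#' @return An \code{abundance_profile} data frame over radius with columns
#'   \code{radius_km}, \code{t_max_K}, \code{pentose_molar},
#'   \code{ribose_molar}, \code{ribose_ppb}.
#' @export
radial_profile <- function(field, scenario, table = gibbs_table(),
                           threshold = 273.15) {
  stopifnot(inherits(field, "thermal_field"),
            inherits(scenario, "composition_scenario"))
  prof <- max_temperature_profile(field)
  conc <- scenario_concentrations(scenario)
  pent <- numeric(nrow(prof))
  for (i in seq_len(nrow(prof))) {
    if (prof$t_max_K[i] >= threshold) {
      st <- mixture_state(conc[["formaldehyde"]], conc[["glycolaldehyde"]],
                          temperature = prof$t_max_K[i])
      pent[i] <- minimize_gibbs(st, table)$amounts[["ribose"]]
    }
  }
  df <- data.frame(radius_km = prof$radius_km, t_max_K = prof$t_max_K,
                   pentose_molar = pent)
  .finish_profile(df, "radius", scenario, field$config)
}

#' Temporal abundance profile at a given depth
#'
#' Runs the time-iterated equilibrium along the temperature history at
#' radius \code{r_km} and converts the resulting pentose trajectory to
#' ribose and bulk-mass ppb.
#'
#' @inheritParams radial_profile
#' @param r_km Radius in km (0 for the center).
#' @return An \code{abundance_profile} data frame over time with columns
#'   \code{time_yr}, \code{temperature_K}, \code{pentose_molar},
#'   \code{ribose_molar}, \code{ribose_ppb}.
#' @export
temporal_profile <- function(field, r_km, scenario, table = gibbs_table(),
                             threshold = 273.15) {
  stopifnot(inherits(field, "thermal_field"),
            inherits(scenario, "composition_scenario"))
  temp <- temperature_at(field, r_km)
  traj <- time_iterated_equilibrium(field$times_yr, temp, scenario, table,
                                    threshold = threshold)
  df <- traj[, c("time_yr", "temperature_K", "pentose_molar")]
  .finish_profile(df, "time", scenario, field$config)
}

#' Onset time of synthesis in a temporal profile
#'
#' First time at which the product abundance is nonzero.
#'
#' @param profile A temporal \code{abundance_profile}.
#' @return Time in yr, or \code{NA} if no synthesis occurred.
#' @export
onset_time <- function(profile) {
  stopifnot(inherits(profile, "abundance_profile"),
            attr(profile, "axis") == "time")
  i <- which(profile$ribose_molar > 0)
  if (length(i) == 0) return(NA_real_)
  profile$time_yr[i[1]]
}

#' Compare a profile plateau with the meteoritic range
#'
#' The headline scalar of a profile is its plateau concentration (the flat
#' nonzero level; reactant-limited chemistry makes the synthesized region
#' flat). The deviation factor is 1 when the plateau lies inside the
#' measured range, otherwise the multiplicative factor to the nearest
#' endpoint.
#'
#' @param profile An \code{abundance_profile} with at least one nonzero
#'   value.
#' @param range Measured range, ppb (default \code{\link{meteoritic_range}}).
#' @return List with \code{plateau_ppb} and \code{factor}.
#' @export
compare_to_meteorites <- function(profile, range = meteoritic_range()) {
  stopifnot(inherits(profile, "abundance_profile"))
  nz <- profile$ribose_ppb[profile$ribose_ppb > 0]
  if (length(nz) == 0)
    stop("no synthesis: profile contains no nonzero abundance")
  plateau <- max(nz)
  fac <- if (plateau < range[["low"]]) range[["low"]] / plateau
    else if (plateau > range[["high"]]) plateau / range[["high"]]
    else 1
  list(plateau_ppb = plateau, factor = fac)
}
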