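#' Construct a mixture state
#'
#' A mixture state holds the molar amounts of the four species of the
#' simplified formose system, normalized per mole of initially present
#' water (water itself starts at amount 1), together with temperature and
#' pressure.
#'
#' @param formaldehyde,glycolaldehyde,ribose Molar amounts, mol per mol of
#'   initial H2O. All must be non-negative.
#' @param water Amount of water, fixed at 1 by the normalization convention.
#' @param temperature Temperature in kelvin.
#' @param pressure Pressure in bar (all thermochemistry is at 100 bar).
#' @return Object of class \code{mixture_state}.
#' @export
mixture_state <- function(formaldehyde, glycolaldehyde, ribose = 0,
                          water = 1, temperature = 298.15, pressure = 100) {
  amounts <- c(water = water, formaldehyde = formaldehyde,
               glycolaldehyde = glycolaldehyde, ribose = ribose)
  if (any(!is.finite(amounts)) || any(amounts < 0))
    stop("all species amounts must be finite and non-negative")
  structure(list(amounts = amounts, temperature = temperature,
                 pressure = pressure),
            class = "mixture_state")
}

#' @export
print.mixture_state <- function(x, ...) {
  cat("<mixture_state> T =", x$temperature, "K, P =", x$pressure, "bar\n")
  print(signif(x$amounts, 6))
  invisible(x)
}

#' Complete-conversion pentose amount from the limiting reagent
#'
#' The simplified formose pathway consumes one formaldehyde and two
#' glycolaldehyde per pentose. When the reaction is strongly favoured the
#' equilibrium composition is set entirely by the scarcer reactant, so the
#' pentose amount has the closed form min(n_CH2O, n_gly / 2). This closed
#' form is both the fast path of the pipeline and the independent oracle
#' against which the Gibbs minimizer is tested.
#'
#' @param n_ch2o Formaldehyde amount, mol per mol H2O (>= 0).
#' @param n_gly Glycolaldehyde amount, mol per mol H2O (>= 0).
#' @return List with \code{pentose}, \code{leftover_ch2o},
#'   \code{leftover_gly} and \code{limiting} ("formaldehyde",
#'   "glycolaldehyde", or "none" when either input is zero).
#' @examples
#' limiting_reagent_conversion(6.6e-4, 5e-6)   # glycolaldehyde limiting
#' @export
limiting_reagent_conversion <- function(n_ch2o, n_gly) {
  if (!is.finite(n_ch2o) || !is.finite(n_gly) || n_ch2o < 0 || n_gly < 0)
    stop("reactant amounts must be finite and non-negative")
  pentose <- min(n_ch2o, n_gly / 2)
  limiting <- if (pentose == 0) "none"
    else if (n_ch2o <= n_gly / 2) "formaldehyde" else "glycolaldehyde"
  list(pentose = pentose,
       leftover_ch2o = n_ch2o - pentose,
       leftover_gly = n_gly - 2 * pentose,
       limiting = limiting)
}

## Chemical potentials (J/mol) of the four mixture species at T, with the
## glycolaldehyde standard-state energy supplied by the weighted proxy
## estimate (optionally perturbed).
.standard_potentials <- function(table, T, gly_offset = 0) {
  c(water = gibbs_of(table, "water", T),
    formaldehyde = gibbs_of(table, "formaldehyde", T),
    glycolaldehyde = glycolaldehyde_weighted(table, T) + gly_offset,
    ribose = gibbs_of(table, "ribose", T))
}

#' Equilibrate a mixture by Gibbs energy minimization
#'
#' Minimizes the total Gibbs energy G = sum_i n_i (dGf_i + RT ln x_i)
#' (ideal dilute solution, activity = mole fraction) along the
#' stoichiometric coordinate of the simplified formose pathway
#' CH2O + 2 C2H4O2 -> C5H10O5, subject to non-negative amounts. Restricting
#' the minimization to this single reaction coordinate keeps the model on
#' the adopted pathway and makes elemental (C, H, O) conservation exact by
#' construction; the stationarity condition dG/dxi = 0 is solved in a log
#' coordinate so that conversions within 1e-300 of completion are resolved.
#' The product is treated as inert: the reaction extent is never negative.
#'
#' @param state A \code{mixture_state}; its temperature must lie within the
#'   span of \code{table}.
#' @param table A \code{gibbs_table}.
#' @param gly_offset Perturbation (J/mol) of the glycolaldehyde formation
#'   energy, for sensitivity analyses.
#' @param tol Convergence tolerance on the stationarity residual, as a
#'   fraction of RT.
#' @param max_iter Maximum root-finder iterations.
#' @return The equilibrated \code{mixture_state}; attributes
#'   \code{residual} (stationarity residual, J/mol) and \code{extent}
#'   (reaction extent, mol per mol H2O).
#' @export
minimize_gibbs <- function(state, table, gly_offset = 0,
                           tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(state, "mixture_state"), inherits(table, "gibbs_table"))
  n <- state$amounts
  T <- state$temperature
  mu0 <- .standard_potentials(table, T, gly_offset)
  RT <- .R_gas * T
  dG0 <- mu0[["ribose"]] - mu0[["formaldehyde"]] - 2 * mu0[["glycolaldehyde"]]

  L <- min(n[["formaldehyde"]], n[["glycolaldehyde"]] / 2)
  if (L <= 0) {  # nothing to react
    attr(state, "residual") <- 0
    attr(state, "extent") <- 0
    return(state)
  }

  ## Parameterize by h = L - xi, the distance to complete conversion, and
  ## carry the leftover reactant amounts as c0 + h and g0 + 2h, where c0
  ## and g0 are the exact full-conversion leftovers (one of them is exactly
  ## zero). This resolves conversions to within h ~ 1e-290 of completion
  ## without the catastrophic cancellation of computing n - xi directly.
  c0 <- n[["formaldehyde"]] - L
  g0 <- n[["glycolaldehyde"]] - 2 * L
  amounts_at_h <- function(h) {
    c(water = n[["water"]],
      formaldehyde = c0 + h,
      glycolaldehyde = g0 + 2 * h,
      ribose = n[["ribose"]] + (L - h))
  }
  ## dG/dxi as a function of h; monotone decreasing in h (G strictly
  ## convex along the reaction coordinate)
  f_of_h <- function(h) {
    a <- amounts_at_h(h)
    ntot <- sum(a)
    dG0 + RT * (log(a[["ribose"]] / ntot) -
                log(a[["formaldehyde"]] / ntot) -
                2 * log(a[["glycolaldehyde"]] / ntot))
  }

  ## dG/dxi as a function of the extent itself, for roots near xi = 0
  ## (unfavourable reaction): here n - xi is cancellation-free instead.
  f_of_xi <- function(xi) {
    a <- c(n[["water"]], n[["formaldehyde"]] - xi,
           n[["glycolaldehyde"]] - 2 * xi, n[["ribose"]] + xi)
    ntot <- sum(a)
    dG0 + RT * (log(a[4] / ntot) - log(a[2] / ntot) - 2 * log(a[3] / ntot))
  }

  ## Locate the unique stationary point on a log scale, measured from
  ## whichever end of [0, L] the root is near, so that both near-complete
  ## conversion (h -> 0) and a barely proceeding reaction (xi -> 0) are
  ## resolved without underflow.
  lo <- log(.Machine$double.xmin) + 30   # ~ 1e-295 in the solved variable
  hi <- log(L / 2)
  f_mid <- f_of_h(L / 2)
  if (!is.finite(f_mid))
    stop("Gibbs stationarity condition not finite at midpoint")
  if (f_mid < 0) {
    ## conversion beyond L/2: solve for the leftover h
    g <- function(lh) f_of_h(exp(lh))
    if (g(lo) <= 0) {   # complete conversion beyond resolvable leftover
      h <- exp(lo)
    } else {
      r <- stats::uniroot(g, c(lo, hi), tol = 1e-14, maxiter = max_iter)
      h <- exp(r$root)
    }
    amounts <- amounts_at_h(h)
    xi <- L - h
    res <- f_of_h(h)
  } else {
    ## conversion below L/2: solve for the extent xi
    g <- function(lx) f_of_xi(exp(lx))
    if (g(lo) >= 0) {   # reaction does not proceed measurably
      xi <- 0
      amounts <- n
      res <- 0
    } else {
      r <- stats::uniroot(g, c(lo, hi), tol = 1e-14, maxiter = max_iter)
      xi <- exp(r$root)
      amounts <- c(water = n[["water"]],
                   formaldehyde = n[["formaldehyde"]] - xi,
                   glycolaldehyde = n[["glycolaldehyde"]] - 2 * xi,
                   ribose = n[["ribose"]] + xi)
      res <- f_of_xi(xi)
    }
  }

  if (is.finite(res) && xi > 0 && xi < L && abs(res) > 1e-4 * RT)
    stop("Gibbs minimization did not converge: residual ", signif(res, 4),
         " J/mol at extent ", signif(xi, 6))
  out <- state
  out$amounts <- amounts
  attr(out, "residual") <- res
  attr(out, "extent") <- xi
  out
}

#' Time-iterated equilibrium along a temperature history
#'
#' Follows the reaction through a temperature history: at each time step
#' the mixture is (re-)equilibrated if the local temperature is at or above
#' the liquid-water threshold, carrying products and leftover reactants
#' forward as the initial composition of the next step. Below the threshold
#' the composition is frozen. Because the product is treated as inert the
#' pentose trajectory is non-decreasing in time.
#'
#' @param times Numeric vector of times (yr), strictly increasing.
#' @param temperatures Temperatures (K) at \code{times}.
#' @param scenario A \code{composition_scenario} giving the initial
#'   reactant concentrations.
#' @param table A \code{gibbs_table}.
#' @param threshold Reactive threshold in K; chemistry requires liquid
#'   water, so the default is the melting point 273.15 K.
#' @param gly_offset Passed to \code{\link{minimize_gibbs}}.
#' @return Data frame with columns \code{time_yr}, \code{temperature_K},
#'   \code{pentose_molar}, \code{ch2o_molar}, \code{gly_molar} (all molar
#'   amounts per mol H2O).
#' @export
time_iterated_equilibrium <- function(times, temperatures, scenario, table,
                                      threshold = 273.15, gly_offset = 0) {
  stopifnot(length(times) == length(temperatures), length(times) >= 1)
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  conc <- scenario_concentrations(scenario)
  state <- mixture_state(conc[["formaldehyde"]], conc[["glycolaldehyde"]])
  n0_lim <- min(conc[["formaldehyde"]], conc[["glycolaldehyde"]] / 2)

  nt <- length(times)
  pent <- ch2o <- gly <- numeric(nt)
  converged <- FALSE  # once conversion is complete, later steps are no-ops
  for (j in seq_len(nt)) {
    Tj <- temperatures[j]
    if (Tj >= threshold && !converged) {
      state$temperature <- Tj
      state <- minimize_gibbs(state, table, gly_offset = gly_offset)
      leftover <- min(state$amounts[["formaldehyde"]],
                      state$amounts[["glycolaldehyde"]] / 2)
      if (n0_lim > 0 && leftover / n0_lim < 1e-14) converged <- TRUE
    }
    pent[j] <- state$amounts[["ribose"]]
    ch2o[j] <- state$amounts[["formaldehyde"]]
    gly[j] <- state$amounts[["glycolaldehyde"]]
  }
  data.frame(time_yr = times, temperature_K = temperatures,
             pentose_molar = pent, ch2o_molar = ch2o, gly_molar = gly)
}
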