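## Gas constant, J mol^-1 K^-1
.R_gas <- 8.314462618

## Weights blending the two proxy species into the glycolaldehyde estimate.
## Deliberately NOT renormalized (they sum to 0.993): the model's results are
## insensitive to the glycolaldehyde energy as long as the reaction stays
## strongly favoured, which the perturbation tests verify.
.gly_weights <- c(acetaldehyde = 0.611, acetic_acid = 0.382)

#' Load a temperature-tabulated Gibbs free energy table
#'
#' Reads a delimited text table of molar Gibbs free energies of formation
#' for aqueous species on a shared temperature grid at 100 bar. The packaged
#' default (see \code{data-raw/make_gibbs_table.R} in the source tree) is a
#' synthetic linear-in-temperature estimate anchored to standard-state
#' aqueous formation properties; only the sign of the formose reaction Gibbs
#' energy is consumed by the model, and that sign carries a margin of
#' roughly 180 kJ/mol.
#'
#' The file format is: comment/provenance lines prefixed with \code{#},
#' then a header \code{species T_K dGf_J_per_mol} and one row per
#' (species, temperature node).
#'
#' @param path Path to the table file. Defaults to the packaged table.
#' @return An object of class \code{gibbs_table}: list with elements
#'   \code{species} (character), \code{T_grid} (K, strictly increasing),
#'   \code{energies} (matrix, nodes x species, J/mol) and
#'   \code{pressure_bar} (fixed at 100).
#' @export
gibbs_table <- function(path = system.file("extdata",
                                           "gibbs_aq_100bar_synthetic.tsv",
                                           package = "formosim")) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "T_K", "dGf_J_per_mol")
  if (!all(need %in% names(raw)))
    stop("Gibbs table must have columns: ", paste(need, collapse = ", "))
  species <- unique(raw$species)
  T_grid <- sort(unique(raw$T_K))
  if (length(T_grid) < 2 || any(diff(T_grid) <= 0))
    stop("temperature grid must be strictly increasing")
  E <- matrix(NA_real_, length(T_grid), length(species),
              dimnames = list(NULL, species))
  for (sp in species) {
    sub <- raw[raw$species == sp, ]
    sub <- sub[order(sub$T_K), ]
    if (!identical(sub$T_K, T_grid))
      stop("species '", sp, "' is not tabulated on the common grid")
    E[, sp] <- sub$dGf_J_per_mol
  }
  if (!all(is.finite(E)))
    stop("non-finite Gibbs energies in table")
  structure(list(species = species, T_grid = T_grid, energies = E,
                 pressure_bar = 100),
            class = "gibbs_table")
}

#' @export
print.gibbs_table <- function(x, ...) {
  cat("<gibbs_table> ", length(x$species), " species, ",
      length(x$T_grid), " temperature nodes (",
      min(x$T_grid), "-", max(x$T_grid), " K) at ",
      x$pressure_bar, " bar\n", sep = "")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Gibbs free energy of formation of a species at temperature T
#'
#' Tabulated values are returned exactly at grid nodes; between nodes the
#' value is linearly interpolated. No extrapolation is performed.
#'
#' @param table A \code{gibbs_table}.
#' @param species Species name present in the table.
#' @param T Temperature(s) in kelvin, within the grid span.
#' @return Molar Gibbs free energy of formation in J/mol (vectorized over
#'   \code{T}).
#' @export
gibbs_of <- function(table, species, T) {
  stopifnot(inherits(table, "gibbs_table"))
  if (length(species) != 1L || !species %in% table$species)
    stop("unknown species '", paste(species, collapse = ","),
         "'; table contains: ", paste(table$species, collapse = ", "))
  if (any(!is.finite(T)) || any(T < table$T_grid[1]) ||
      any(T > table$T_grid[length(table$T_grid)]))
    stop("temperature outside tabulated span [", table$T_grid[1], ", ",
         table$T_grid[length(table$T_grid)], "] K; no extrapolation")
  stats::approx(table$T_grid, table$energies[, species], xout = T,
                method = "linear", ties = "ordered")$y
}

#' Weighted-proxy Gibbs energy estimate for glycolaldehyde
#'
#' Glycolaldehyde is absent from standard aqueous thermodynamic databases;
#' its formation energy is estimated as a fixed blend of the acetaldehyde
#' and acetic acid values, whose functional groups together resemble
#' glycolaldehyde: 0.611 * dGf(acetaldehyde) + 0.382 * dGf(acetic acid).
#'
#' @inheritParams gibbs_of
#' @param weights Blend weights; the defaults are the calibrated values and
#'   are intentionally not renormalized.
#' @return Estimated molar Gibbs free energy of formation, J/mol.
#' @export
glycolaldehyde_weighted <- function(table, T, weights = .gly_weights) {
  weights[["acetaldehyde"]] * gibbs_of(table, "acetaldehyde", T) +
    weights[["acetic_acid"]] * gibbs_of(table, "acetic_acid", T)
}

#' Reaction Gibbs energy of the simplified formose pathway
#'
#' Stoichiometric Gibbs energy difference of
#' \deqn{CH_2O + 2\,C_2H_4O_2 \rightarrow C_5H_{10}O_5,}
#' i.e. dGf(ribose) - dGf(formaldehyde) - 2 dGf(glycolaldehyde), with the
#' glycolaldehyde term supplied by \code{\link{glycolaldehyde_weighted}}.
#' A negative value means pentose formation is thermodynamically favoured
#' at that temperature.
#'
#' @inheritParams gibbs_of
#' @param gly_offset Additive perturbation (J/mol) applied to the
#'   glycolaldehyde estimate; used for sensitivity analyses.
#' @return Reaction Gibbs energy in J/mol (vectorized over \code{T}).
#' @export
reaction_delta_g <- function(table, T, gly_offset = 0) {
  gibbs_of(table, "ribose", T) -
    gibbs_of(table, "formaldehyde", T) -
    2 * (glycolaldehyde_weighted(table, T) + gly_offset)
}
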