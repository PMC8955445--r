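#' @keywords internal
"_PACKAGE"

## Standard atomic masses (g/mol), CIAAW conventional values.
.atomic_mass <- c(C = 12.011, H = 1.008, O = 15.999)

#' Species registry for the simplified formose system
#'
#' Returns the table of chemical species used throughout the package: the
#' solvent (water), the two reactants of the simplified formose pathway
#' (formaldehyde and glycolaldehyde), the pentose product (modelled as
#' ribose, C5H10O5), and the two proxy species (acetaldehyde and acetic
#' acid) whose tabulated aqueous Gibbs energies are blended to estimate the
#' missing glycolaldehyde value.
#'
#' @return A data frame with columns \code{species}, \code{C}, \code{H},
#'   \code{O} (element counts), \code{molar_mass} (g/mol) and \code{role}
#'   (one of \code{"solvent"}, \code{"reactant"}, \code{"product"},
#'   \code{"proxy"}).
#' @examples
#' formose_species()
#' @export
formose_species <- function() {
  df <- data.frame(
    species = c("water", "formaldehyde", "glycolaldehyde", "ribose",
                "acetaldehyde", "acetic_acid"),
    C = c(0L, 1L, 2L, 5L, 2L, 2L),
    H = c(2L, 2L, 4L, 10L, 4L, 4L),
    O = c(1L, 1L, 2L, 5L, 1L, 2L),
    role = c("solvent", "reactant", "reactant", "product", "proxy", "proxy"),
    stringsAsFactors = FALSE
  )
  df$molar_mass <- species_mass(df$C, df$H, df$O)
  df[, c("species", "C", "H", "O", "molar_mass", "role")]
}

## molar mass from a C/H/O formula
species_mass <- function(C, H, O) {
  C * .atomic_mass[["C"]] + H * .atomic_mass[["H"]] + O * .atomic_mass[["O"]]
}

#' Elemental composition of a mixture
#'
#' Sums the C, H and O inventories of a mixture state, in moles per mole of
#' initially present water. Element totals are the conserved quantities of
#' the equilibrium step: any equilibration must return a state with the same
#' totals to floating-point accuracy.
#'
#' @param state A \code{mixture_state}, or a named numeric vector of species
#'   amounts (names must appear in \code{formose_species()}).
#' @return Named numeric vector with components \code{C}, \code{H}, \code{O}.
#' @examples
#' element_totals(c(water = 1))                 # (0, 2, 1)
#' element_totals(c(formaldehyde = 1, glycolaldehyde = 2))  # same as ribose
#' @export
element_totals <- function(state) {
  amounts <- if (inherits(state, "mixture_state")) state$amounts else state
  if (is.null(names(amounts)) || any(!nzchar(names(amounts))))
    stop("'state' must be a mixture_state or a named vector of amounts")
  sp <- formose_species()
  idx <- match(names(amounts), sp$species)
  if (anyNA(idx))
    stop("unknown species: ", paste(names(amounts)[is.na(idx)], collapse = ", "))
  counts <- as.matrix(sp[idx, c("C", "H", "O")])
  tot <- drop(crossprod(counts, amounts))
  names(tot) <- c("C", "H", "O")
  tot
}

#' Catalyst yield factors for ribose among pentoses
#'
#' Maximum measured fraction of ribose among all pentoses produced by the
#' formose reaction for each mineral catalyst (mol/mol, dimensionless).
#' These factors convert the modelled total-pentose abundance into a ribose
#' abundance.
#'
#' @return Named numeric vector of yields, ordered by decreasing yield.
#' @examples
#' catalyst_yields()
#' @export
catalyst_yields <- function() {
  c("Ca(OH)2" = 4.1e-2,
    "CaCO3"   = 3.5e-2,
    "K2CO3"   = 2.7e-2,
    "KOH"     = 2.4e-2)
}

#' Measured ribose concentration range in carbonaceous chondrites
#'
#' The benchmark range of ribose concentrations measured in CM2/CR2
#' carbonaceous chondrites, in parts per billion by mass.
#'
#' @return Named numeric vector \code{c(low = 4.5, high = 25)} (ppb).
#' @export
meteoritic_range <- function() {
  c(low = 4.5, high = 25)
}
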