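# Shared fixtures, built in code.

# A tiny synthetic Gibbs table with hand-chosen node values, written to a
# temp file and read back through the package loader so the file contract
# is exercised too. Energies are linear in T per species, so linear
# interpolation is exact and oracle values are trivial to compute by hand.
toy_gibbs_table <- function(slopes = NULL) {
  species <- c("water", "formaldehyde", "acetaldehyde", "acetic_acid", "ribose")
  g298 <- c(water = -237000, formaldehyde = -102000, acetaldehyde = -140000,
            acetic_acid = -396000, ribose = -757000)
  if (is.null(slopes))
    slopes <- c(water = 160, formaldehyde = 120, acetaldehyde = 130,
                acetic_acid = 170, ribose = 500)
  T_grid <- seq(270, 610, by = 20)
  rows <- do.call(rbind, lapply(species, function(sp)
    data.frame(species = sp, T_K = T_grid,
               dGf_J_per_mol = g298[[sp]] + slopes[[sp]] * (T_grid - 298.15))))
  f <- tempfile(fileext = ".tsv")
  con <- file(f, "w")
  writeLines("# toy table for tests", con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  gibbs_table(f)
}

# Constant-in-time isotope source: half-life long enough to be constant
# over any simulated interval.
constant_inventory <- function(power = 1e-8) {
  data.frame(isotope = "const", half_life_yr = 1e30,
             power_W_per_kg_rock = power)
}

empty_inventory <- function() {
  data.frame(isotope = character(), half_life_yr = numeric(),
             power_W_per_kg_rock = numeric())
}

# Small, fast thermal configuration for solver behaviour tests.
quick_config <- function(radius_km = 2, t_form_myr = 1, n = 80,
                         t_end_yr = 3e6, dt = 5e3, ...) {
  planetesimal_config(radius_km, t_form_myr, n_radial_cells = n,
                      t_end_yr = t_end_yr, dt_fine_yr = dt,
                      dt_fine_until_yr = t_end_yr, ...)
}
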