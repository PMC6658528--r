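# ionic solutions, dissociation rules and the Henderson liquid-junction potential

#' Relative ionic mobility table
#'
#' Per-equivalent limiting conductivities expressed relative to K+ (= 1.00),
#' the JPCalc-style convention. Inorganic ions follow standard limiting-
#' conductivity tables; organic anions (gluconate 0.33, HEPES- 0.30,
#' H2PO4- 0.45) follow published patch-clamp mobility measurements; the
#' nucleotide (ATP/GTP, taken dianionic at physiological pH) and
#' phosphocreatine anions are assigned 0.32 per equivalent, a documented
#' estimate for bulky phosphate anions. Charges are the dominant species at
#' pH 7.2-7.4.
#'
#' @return tibble with columns `ion`, `z`, `mobility` (relative, per equivalent).
#' @export
mobility_table <- function() {
  tibble::tribble(
    ~ion,          ~z, ~mobility,
    "K",            1, 1.0000,
    "Na",           1, 0.6818,
    "Li",           1, 0.5260,
    "Cs",           1, 1.0500,
    "H",            1, 4.7600,
    "NMDG",         1, 0.3300,
    "Mg",           2, 0.7219,
    "Ca",           2, 0.8095,
    "Cl",          -1, 1.0388,
    "Br",          -1, 1.0650,
    "NO3",         -1, 0.9720,
    "HCO3",        -1, 0.6050,
    "OH",          -1, 2.7000,
    "gluconate",   -1, 0.3300,
    "HEPES",       -1, 0.3000,
    "H2PO4",       -1, 0.4500,
    "ATP",         -2, 0.3200,
    "GTP",         -2, 0.3200,
    "PCr",         -2, 0.3200,
    "ascorbate",   -1, 0.3800,
  )
}

#' Default salt dissociation table
#'
#' Maps the species names of recipe lines to constituent ions with
#' stoichiometries. Titratable buffer species dissociate fractionally:
#' HEPES (pKa 7.5) contributes its anion scaled by the Henderson-Hasselbalch
#' fraction at the solution pH while a counter-cation in the salt form (e.g.
#' Na-HEPES) is counted fully; ascorbate (pKa 4.2) is fully anionic; glucose,
#' EGTA and other effectively immobile or neutral components carry no ions.
#'
#' @return nested tibble: `species`, `ion`, `stoichiometry`, `titratable_pKa`
#'   (NA for fixed charges).
#' @export
dissociation_table <- function() {
  tibble::tribble(
    ~species,               ~ion,        ~stoichiometry, ~titratable_pKa,
    "NaCl",                 "Na",         1, NA,
    "NaCl",                 "Cl",         1, NA,
    "KCl",                  "K",          1, NA,
    "KCl",                  "Cl",         1, NA,
    "CaCl2",                "Ca",         1, NA,
    "CaCl2",                "Cl",         2, NA,
    "MgCl2",                "Mg",         1, NA,
    "MgCl2",                "Cl",         2, NA,
    "K-gluconate",          "K",          1, NA,
    "K-gluconate",          "gluconate",  1, NA,
    "Na2-ATP",              "Na",         2, NA,
    "Na2-ATP",              "ATP",        1, NA,
    "Na-GTP",               "Na",         1, NA,
    "Na-GTP",               "GTP",        1, NA,
    "Na2-phosphocreatine",  "Na",         2, NA,
    "Na2-phosphocreatine",  "PCr",        1, NA,
    "NaH2PO4",              "Na",         1, NA,
    "NaH2PO4",              "H2PO4",      1, NA,
    "HEPES",                "HEPES",      1, 7.5,
    "Na-HEPES",             "Na",         1, NA,
    "Na-HEPES",             "HEPES",      1, 7.5,
    "ascorbate",            "ascorbate",  1, NA,
    "EGTA",                 "none",       0, NA,
    "glucose",              "none",       0, NA,
  )
}

#' Define an ionic solution from a recipe
#'
#' @param components data frame with `species`, `mM` (concentrations >= 0).
#' @param pH solution pH (used for titratable buffer species).
#' @param temperature_C temperature (degrees C).
#' @param dissociation dissociation rules, see [dissociation_table()].
#' @return object of class `solution_composition` with the resolved free-ion
#'   concentrations in `$ions` (`ion`, `z`, `mobility`, `mM`).
#' @export
solution_composition <- function(components, pH, temperature_C = 25,
                                 dissociation = dissociation_table()) {
  components <- tibble::as_tibble(components)
  if (any(components$mM < 0)) abort_pc("negative concentration")
  mob <- mobility_table()
  rows <- list()
  for (i in seq_len(nrow(components))) {
    sp <- components$species[i]
    conc <- components$mM[i]
    d <- dissociation[dissociation$species == sp, ]
    if (nrow(d) == 0L) abort_pc("no dissociation rule for species '", sp, "'")
    for (j in seq_len(nrow(d))) {
      if (d$ion[j] == "none") next
      frac <- 1
      if (!is.na(d$titratable_pKa[j])) {
        frac <- 1 / (1 + 10^(d$titratable_pKa[j] - pH))
      }
      m <- mob[mob$ion == d$ion[j], ]
      if (nrow(m) == 0L) abort_pc("ion '", d$ion[j], "' missing from the mobility table")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ion = d$ion[j], z = m$z, mobility = m$mobility,
        mM = conc * d$stoichiometry[j] * frac)
    }
  }
  ions <- dplyr::summarise(dplyr::group_by(dplyr::bind_rows(rows), .data$ion,
                                           .data$z, .data$mobility),
                           mM = sum(.data$mM), .groups = "drop")
  structure(list(components = components, pH = pH,
                 temperature_C = temperature_C, ions = ions),
            class = "solution_composition")
}

#' @export
print.solution_composition <- function(x, ...) {
  cat("<solution_composition> pH", x$pH, "at", x$temperature_C, "degC\n")
  print(x$ions)
  invisible(x)
}

#' Henderson liquid-junction potential
#'
#' Generalized Henderson equation for the junction between the pipette and
#' bath solutions, using the embedded relative mobility table. The returned
#' value is the correction applied to pipette-referenced measurements (the
#' acquisition-software convention), i.e. it is added to command potentials;
#' for a standard K-gluconate internal against a NaCl-based bath it is
#' negative (about -15 mV). Antisymmetric under swapping the arguments.
#'
#' @param pipette,bath [solution_composition()] objects.
#' @param temperature_C temperature (degrees C); defaults to the pipette
#'   solution's temperature.
#' @return junction potential correction (mV).
#' @export
henderson_ljp <- function(pipette, bath, temperature_C = pipette$temperature_C) {
  ions <- dplyr::full_join(
    dplyr::select(pipette$ions, "ion", "z", "mobility", c_pip = "mM"),
    dplyr::select(bath$ions, "ion", "z", "mobility", c_bath = "mM"),
    by = c("ion", "z", "mobility"))
  ions$c_pip[is.na(ions$c_pip)] <- 0
  ions$c_bath[is.na(ions$c_bath)] <- 0
  z <- ions$z
  u <- ions$mobility        # per-equivalent mobility == true mobility (lambda/|z|)
  dc <- ions$c_bath - ions$c_pip
  num <- sum(z * u * dc)
  den <- sum(z^2 * u * dc)
  s_pip <- sum(z^2 * u * ions$c_pip)
  s_bath <- sum(z^2 * u * ions$c_bath)
  if (s_pip <= 0 || s_bath <= 0) abort_pc("empty solution")
  e_bath_minus_pip <- if (abs(den) < 1e-300) 0 else {
    -rt_over_f(temperature_C) * (num / den) * log(s_bath / s_pip)
  }
  # pipette-referenced correction
  -e_bath_minus_pip
}
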