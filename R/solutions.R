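#' Define an ion species
#'
#' One ionic (or neutral) component of a bath solution. Hydrated-ion size
#' parameters follow the Kielland convention and are given in nanometres so
#' that they pair with the 37 degree C extended Debye-Hueckel constant
#' B = 3.31 nm^-1.
#'
#' @param name Species label, e.g. `"Na"`.
#' @param charge Signed integer valence `z`. Zero for neutral solutes
#'   (HEPES free acid, glucose, mannitol), which contribute nothing to the
#'   ionic strength.
#' @param mM Concentration in millimolar; must be finite and >= 0.
#' @param alpha_nm Effective diameter of the hydrated ion in nanometres.
#'   Required (> 0) for charged species; ignored for neutral ones.
#' @return An object of class `"ion_species"`.
#' @seealso [solution_composition()], [ringer_high()]
#' @export
ion_species <- function(name, charge, mM, alpha_nm = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  charge <- as.integer(charge)
  if (!is.finite(mM) || mM < 0)
    stop("concentration must be finite and >= 0 (species '", name, "')")
  if (charge != 0L && (!is.finite(alpha_nm) || alpha_nm <= 0))
    stop("charged species '", name, "' needs a hydrated size alpha_nm > 0")
  structure(list(name = name, charge = charge, mM = mM, alpha_nm = alpha_nm),
            class = "ion_species")
}

#' Define a bath solution composition
#'
#' A recipe of ion species at a given temperature. The net charge balance
#' `sum(c_i * z_i)` is checked against `balance_tol_mM`; imbalance produces a
#' warning rather than an error because buffer components (HEPES/NMDG) are
#' often only partially speciated and may be deliberately left out of the
#' recipe.
#'
#' @param species List of [ion_species()] objects.
#' @param temperature_K Absolute temperature, kelvin (> 0). Default 310.15
#'   (37 degrees C).
#' @param label Free-text label for the solution.
#' @param balance_tol_mM Charge-imbalance tolerance in mM-equivalents before
#'   a warning is raised.
#' @return An object of class `"solution_composition"`.
#' @export
solution_composition <- function(species, temperature_K = 310.15,
                                 label = "", balance_tol_mM = 1) {
  stopifnot(is.list(species))
  for (sp in species)
    if (!inherits(sp, "ion_species")) stop("species must be ion_species objects")
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be > 0")
  imbalance <- sum(vapply(species, function(s) s$mM * s$charge, numeric(1)))
  if (length(species) && abs(imbalance) > balance_tol_mM)
    warning(sprintf("solution '%s' has net charge imbalance %.3f mM-eq", label,
                    imbalance))
  structure(list(species = species, temperature_K = temperature_K,
                 label = label),
            class = "solution_composition")
}

#' @export
print.solution_composition <- function(x, ...) {
  cat("Solution composition:", if (nzchar(x$label)) x$label else "<unlabelled>",
      sprintf("(%.2f K)\n", x$temperature_K))
  df <- data.frame(
    species = vapply(x$species, `[[`, character(1), "name"),
    charge  = vapply(x$species, `[[`, integer(1), "charge"),
    mM      = vapply(x$species, `[[`, numeric(1), "mM"),
    alpha_nm = vapply(x$species, `[[`, numeric(1), "alpha_nm"))
  print(df, row.names = FALSE)
  cat(sprintf("ionic strength: %.4f M\n", ionic_strength(x)))
  invisible(x)
}

#' Ionic strength of a solution
#'
#' Computes `mu = 1/2 * sum(c_i * z_i^2)` over all charged species, with
#' concentrations converted from mM to mol/L.
#'
#' @param solution A [solution_composition()].
#' @return Ionic strength in molar (M).
#' @examples
#' ionic_strength(ringer_high())  # 0.1469 M
#' @export
ionic_strength <- function(solution) {
  stopifnot(inherits(solution, "solution_composition"))
  if (!length(solution$species)) return(0)
  cz2 <- vapply(solution$species,
                function(s) (s$mM / 1000) * s$charge^2, numeric(1))
  0.5 * sum(cz2)
}

#' Extended Debye-Hueckel log10 activity coefficient
#'
#' `log10(gamma) = -A * z^2 * sqrt(mu) / (1 + B * alpha * sqrt(mu))`.
#' The defaults A = 0.522 and B = 3.31 nm^-1 are the 37 degree C values
#' appropriate for physiological Ringer's solutions; `alpha` is the
#' effective diameter of the hydrated ion in nanometres.
#'
#' @param charge Integer valence `z`; `z = 0` gives `log10(gamma) = 0`.
#' @param mu Ionic strength, molar; must be >= 0.
#' @param alpha_nm Hydrated-ion size in nm (> 0 for charged species).
#' @param A,B Debye-Hueckel constants (temperature-dependent).
#' @return `log10(gamma)` (<= 0 for charged species at mu > 0).
#' @examples
#' 10^log_gamma(1, 0.1469, 0.4)   # gamma for Na+ in 140 mM Ringer's
#' @export
log_gamma <- function(charge, mu, alpha_nm, A = 0.522, B = 3.31) {
  if (any(!is.finite(mu)) || any(mu < 0)) stop("ionic strength mu must be >= 0")
  charge <- as.integer(charge)
  z2 <- charge^2
  if (any(z2 != 0 & (!is.finite(alpha_nm) | alpha_nm <= 0)))
    stop("alpha_nm must be > 0 for charged species")
  s <- sqrt(mu)
  -A * z2 * s / (1 + B * alpha_nm * s)
}

#' Single-ion activities of a solution
#'
#' Evaluates the extended Debye-Hueckel coefficient for every species at the
#' solution's own ionic strength and returns activities `a = gamma * c`.
#' Solutions with different total salt (e.g. the 70 mM apical bath) therefore
#' get their own, larger, coefficients.
#'
#' @param solution A [solution_composition()].
#' @param mu_override Optional ionic strength (M) to use instead of the one
#'   computed from the recipe, for reproducing published coefficients whose
#'   exact ionic-strength bookkeeping is unknown.
#' @param A,B Debye-Hueckel constants, passed to [log_gamma()].
#' @return An object of class `"activity_set"`: a data frame with columns
#'   `species`, `charge`, `mM`, `gamma`, `activity_mM`, plus attribute
#'   `ionic_strength_M`.
#' @examples
#' activities(ringer_high())
#' @export
activities <- function(solution, mu_override = NULL, A = 0.522, B = 3.31) {
  stopifnot(inherits(solution, "solution_composition"))
  mu <- if (is.null(mu_override)) ionic_strength(solution) else mu_override
  if (!is.finite(mu) || mu < 0) stop("ionic strength must be >= 0")
  rows <- lapply(solution$species, function(s) {
    g <- if (s$charge == 0L) 1 else 10^log_gamma(s$charge, mu, s$alpha_nm, A, B)
    data.frame(species = s$name, charge = s$charge, mM = s$mM,
               gamma = g, activity_mM = g * s$mM)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), charge = integer(), mM = numeric(),
               gamma = numeric(), activity_mM = numeric())
  attr(out, "ionic_strength_M") <- mu
  class(out) <- c("activity_set", "data.frame")
  out
}

#' Look up one species' activity (mM) in an activity set
#'
#' @param act An `"activity_set"` from [activities()].
#' @param species Species name.
#' @return Activity in mM.
#' @export
ion_activity <- function(act, species) {
  stopifnot(inherits(act, "activity_set"))
  i <- match(species, act$species)
  if (is.na(i)) stop("species '", species, "' not present in activity set")
  act$activity_mM[i]
}

# default hydrated-size table (nm), Kielland-style values
.default_alpha <- c(Na = 0.4, Cl = 0.3, K = 0.3, Ca = 0.6, Mg = 0.8,
                    gluconate = 0.45, HCO3 = 0.4)

#' The 140 mM NaCl ("high") Ringer's bath
#'
#' 140 mM NaCl, 1.2 mM calcium gluconate, 1.1 mM magnesium gluconate,
#' plus neutral HEPES/glucose. Only the fully dissociated salts contribute to
#' the ionic strength (0.1469 M); buffer speciation is excluded by default
#' but can be added to the recipe explicitly.
#'
#' @param temperature_K Temperature in kelvin.
#' @return A [solution_composition()].
#' @export
ringer_high <- function(temperature_K = 310.15) {
  .ringer(nacl_mM = 140, label = "high-NaCl Ringer's",
          temperature_K = temperature_K)
}

#' The 70 mM NaCl ("low") apical dilution bath
#'
#' Identical to [ringer_high()] except 70 mM NaCl (osmolarity restored with
#' mannitol, which is neutral and omitted from the ionic strength).
#'
#' @param temperature_K Temperature in kelvin.
#' @return A [solution_composition()].
#' @export
ringer_low <- function(temperature_K = 310.15) {
  .ringer(nacl_mM = 70, label = "low-NaCl Ringer's",
          temperature_K = temperature_K)
}

.ringer <- function(nacl_mM, label, temperature_K) {
  solution_composition(list(
    ion_species("Na", 1L, nacl_mM, .default_alpha[["Na"]]),
    ion_species("Cl", -1L, nacl_mM, .default_alpha[["Cl"]]),
    ion_species("Ca", 2L, 1.2, .default_alpha[["Ca"]]),
    ion_species("Mg", 2L, 1.1, .default_alpha[["Mg"]]),
    ion_species("gluconate", -1L, 2 * 1.2 + 2 * 1.1,
                .default_alpha[["gluconate"]])),
    temperature_K = temperature_K, label = label)
}

#' Read a solution recipe from a flat CSV file
#'
#' Expected columns: `species`, `charge`, `mM`, `alpha_nm` (alpha may be
#' blank for neutral species). An optional header comment line starting with
#' `#` is ignored. Two packaged recipes are shipped under
#' `system.file("extdata", package = "ghkselect")`:
#' `ringer_high.csv` and `ringer_low.csv`.
#'
#' @param path Path to the recipe file.
#' @param temperature_K Temperature in kelvin.
#' @param label Label; defaults to the file name.
#' @return A [solution_composition()].
#' @export
read_solution <- function(path, temperature_K = 310.15,
                          label = basename(path)) {
  if (!file.exists(path)) stop("recipe file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "charge", "mM", "alpha_nm")
  if (!all(need %in% names(df)))
    stop("recipe file must have columns: ", paste(need, collapse = ", "))
  sp <- lapply(seq_len(nrow(df)), function(i)
    ion_species(df$species[i], df$charge[i], df$mM[i], df$alpha_nm[i]))
  solution_composition(sp, temperature_K = temperature_K, label = label)
}
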