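#' Goldman-Hodgkin-Katz slope constant
#'
#' The dilution-potential slope `RT ln(10) / F` in mV. `mode = "paper"`
#' returns the conventional 37 degree C approximation 61.5 mV; `mode =
#' "exact"` evaluates the physical constants (CODATA R = 8.314462618 J/mol/K,
#' F = 96485.33212 C/mol) at the requested temperature, giving 61.54 mV at
#' 310.15 K.
#'
#' @param mode `"paper"` (61.5) or `"exact"`.
#' @param temperature_K Temperature used in exact mode.
#' @return Slope in mV per decade of activity ratio.
#' @export
ghk_slope <- function(mode = c("paper", "exact"), temperature_K = 310.15) {
  mode <- match.arg(mode)
  if (mode == "paper") return(61.5)
  R_gas <- 8.314462618
  faraday <- 96485.33212
  1000 * R_gas * temperature_K * log(10) / faraday
}

#' Subtract a liquid-junction potential
#'
#' Junction potentials induced by the asymmetric baths are measured on the
#' lysed monolayer at the end of the experiment and subtracted once from
#' every measured dilution potential.
#'
#' @param v_measured_mV Measured dilution potential, mV.
#' @param v_junction_mV Measured junction potential, mV.
#' @return Corrected potential, mV.
#' @export
junction_correct <- function(v_measured_mV, v_junction_mV) {
  if (any(!is.finite(v_measured_mV)) || any(!is.finite(v_junction_mV)))
    stop("potentials must be finite")
  v_measured_mV - v_junction_mV
}

#' Drug-pathway conductance
#'
#' The conductance added by the channel-forming compound: treated minus
#' untreated transepithelial conductance. A non-positive difference means the
#' compound opened no measurable pathway and the replicate carries no
#' selectivity information; this is an error (callers that aggregate
#' replicates catch it and flag the replicate instead of dropping it
#' silently).
#'
#' @param g_total Conductance of the treated monolayer, mS/cm^2.
#' @param g_frt Conductance of the untreated monolayer, mS/cm^2.
#' @return Drug-pathway conductance, mS/cm^2 (> 0).
#' @export
drug_conductance <- function(g_total, g_frt) {
  if (any(!is.finite(g_total)) || any(!is.finite(g_frt)) ||
      any(g_total <= 0) || any(g_frt <= 0))
    stop("conductances must be finite and > 0")
  g_drug <- g_total - g_frt
  if (any(g_drug <= 0))
    stop("invalid replicate: treated conductance does not exceed untreated ",
         "(g_drug <= 0); drug pathway undefined")
  g_drug
}

#' Decompose the treated dilution potential into the drug-pathway potential
#'
#' The treated monolayer is modelled as two parallel conductive pathways:
#' the epithelium itself (g_frt, producing v_frt) and the drug-formed
#' channels (g_drug, producing v_drug). The measured potential is their
#' conductance-weighted average,
#' `v_t = g_frt/(g_frt+g_drug) * v_frt + g_drug/(g_frt+g_drug) * v_drug`,
#' which this function solves for `v_drug`.
#'
#' @param v_t Treated (junction-corrected) dilution potential, mV.
#' @param v_frt Untreated dilution potential, mV.
#' @param g_frt Untreated conductance, mS/cm^2.
#' @param g_drug Drug-pathway conductance, mS/cm^2 (> 0).
#' @return The drug-pathway dilution potential `v_drug`, mV. Substituting it
#'   back into the weighted average reproduces `v_t` to machine precision.
#' @examples
#' decompose_dilution_potential(v_t = 4, v_frt = 10, g_frt = 2, g_drug = 2)
#' @export
decompose_dilution_potential <- function(v_t, v_frt, g_frt, g_drug) {
  if (any(!is.finite(c(v_t, v_frt, g_frt, g_drug))))
    stop("inputs must be finite")
  if (any(g_drug <= 0))
    stop("g_drug must be > 0: no drug pathway to decompose onto")
  (v_t * (g_frt + g_drug) - g_frt * v_frt) / g_drug
}

#' Recompose the treated dilution potential (forward circuit model)
#'
#' Inverse of [decompose_dilution_potential()]; mainly used for
#' consistency checks and residuals.
#'
#' @inheritParams decompose_dilution_potential
#' @param v_drug Drug-pathway potential, mV.
#' @return The composed `v_t`, mV.
#' @export
compose_dilution_potential <- function(v_drug, v_frt, g_frt, g_drug) {
  w <- g_frt / (g_frt + g_drug)
  w * v_frt + (1 - w) * v_drug
}

.check_activities <- function(a_na_baso, a_cl_baso, a_na_api, a_cl_api) {
  a <- c(a_na_baso, a_cl_baso, a_na_api, a_cl_api)
  if (any(!is.finite(a)) || any(a <= 0))
    stop("all ion activities must be finite and > 0")
}

#' Forward GHK dilution potential for a Na+/Cl- pathway
#'
#' `v = slope * log10((a_Na_baso + P * a_Cl_api) / (a_Na_api + P * a_Cl_baso))`
#' where `P = P_Cl/P_Na`. The transepithelial potential is referenced so that
#' an apical NaCl dilution through a cation-selective pathway (P < 1) gives a
#' positive potential and an anion-selective pathway (P > 1) a negative one.
#'
#' @param p_cl_na Relative permeability P_Cl/P_Na (>= 0).
#' @param a_na_baso,a_cl_baso Basolateral Na+ and Cl- activities, mM.
#' @param a_na_api,a_cl_api Apical Na+ and Cl- activities, mM.
#' @param slope_mV Slope constant, mV; see [ghk_slope()].
#' @return Dilution potential in mV.
#' @examples
#' ghk_potential(0, a_na_baso = 2, a_cl_baso = 2, a_na_api = 1, a_cl_api = 1)
#' @export
ghk_potential <- function(p_cl_na, a_na_baso, a_cl_baso, a_na_api, a_cl_api,
                          slope_mV = ghk_slope()) {
  .check_activities(a_na_baso, a_cl_baso, a_na_api, a_cl_api)
  if (any(!is.finite(p_cl_na)) || any(p_cl_na < 0))
    stop("p_cl_na must be finite and >= 0")
  slope_mV * log10((a_na_baso + p_cl_na * a_cl_api) /
                   (a_na_api + p_cl_na * a_cl_baso))
}

#' Nernstian limits of the dilution potential
#'
#' The potentials of perfectly single-ion-selective pathways: the Cl- limit
#' `slope * log10(a_Cl_api / a_Cl_baso)` (P -> Inf) and the Na+ limit
#' `slope * log10(a_Na_baso / a_Na_api)` (P -> 0). Any physically meaningful
#' Na+/Cl- pathway potential lies strictly between them.
#'
#' @inheritParams ghk_potential
#' @return Named numeric vector `c(cl = ..., na = ...)`, mV.
#' @export
nernst_limits <- function(a_na_baso, a_cl_baso, a_na_api, a_cl_api,
                          slope_mV = ghk_slope()) {
  .check_activities(a_na_baso, a_cl_baso, a_na_api, a_cl_api)
  c(cl = slope_mV * log10(a_cl_api / a_cl_baso),
    na = slope_mV * log10(a_na_baso / a_na_api))
}

#' Closed-form GHK inversion for P_Cl/P_Na
#'
#' Solves the forward relation of [ghk_potential()] for the relative
#' permeability. With `r = 10^(v/slope)`,
#' `P = (r * a_Na_api - a_Na_baso) / (a_Cl_api - r * a_Cl_baso)`.
#' The potential must lie strictly inside the Nernstian limits; a potential
#' within `guard_mV` of a limit is numerically unstable (P diverges or
#' collapses) and is rejected with an informative error, which is the usual
#' signal that the circuit decomposition produced an unphysical drug-pathway
#' potential.
#'
#' @param v_drug_mV Drug-pathway dilution potential, mV.
#' @inheritParams ghk_potential
#' @param guard_mV Guard band around the Nernstian limits, mV.
#' @return P_Cl/P_Na (>= 0); round-trips through [ghk_potential()].
#' @examples
#' v <- ghk_potential(3, 103.1, 100.3, 54.9, 53.9)
#' ghk_invert(v, 103.1, 100.3, 54.9, 53.9)  # 3
#' @export
ghk_invert <- function(v_drug_mV, a_na_baso, a_cl_baso, a_na_api, a_cl_api,
                       slope_mV = ghk_slope(), guard_mV = 0.1) {
  .check_activities(a_na_baso, a_cl_baso, a_na_api, a_cl_api)
  if (!is.finite(v_drug_mV)) stop("v_drug_mV must be finite")
  lim <- nernst_limits(a_na_baso, a_cl_baso, a_na_api, a_cl_api, slope_mV)
  lo <- min(lim); hi <- max(lim)
  if (v_drug_mV <= lo + guard_mV || v_drug_mV >= hi - guard_mV)
    stop(sprintf(paste0(
      "dilution potential %.3f mV is outside (or within %.2g mV of) the ",
      "Nernstian limits [Cl- %.3f, Na+ %.3f] mV; the circuit decomposition ",
      "produced an unphysical drug-pathway potential"),
      v_drug_mV, guard_mV, lim[["cl"]], lim[["na"]]))
  r <- 10^(v_drug_mV / slope_mV)
  p <- (r * a_na_api - a_na_baso) / (a_cl_api - r * a_cl_baso)
  if (!is.finite(p) || p < 0)
    stop(sprintf("inversion yielded invalid P_Cl/P_Na = %.4g", p))
  p
}
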