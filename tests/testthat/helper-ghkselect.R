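# shared fixtures and independent oracles for the test suite

# activities of the packaged Ringer's pair (na_baso, cl_baso, na_api, cl_api)
paper_activities <- function() {
  selectivity_activities(ringer_high(), ringer_low())
}

# independent oracle: invert the full RT/F GHK relation by bracketed
# root-solving instead of the closed form
oracle_invert <- function(v_mV, a, temperature_K = 310.15) {
  slope <- 1000 * 8.314462618 * temperature_K * log(10) / 96485.33212
  f <- function(p) {
    slope * log10((a[["na_baso"]] + p * a[["cl_api"]]) /
                    (a[["na_api"]] + p * a[["cl_baso"]])) - v_mV
  }
  stats::uniroot(f, lower = 0, upper = 1e8, tol = 1e-14)$root
}

# random valid activity tuples with basolateral > apical NaCl
rand_activity_tuples <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    base <- runif(1, 50, 200)
    dil <- runif(1, 0.2, 0.8)
    c(na_baso = base * runif(1, 0.9, 1.1), cl_baso = base * runif(1, 0.9, 1.1),
      na_api = base * dil * runif(1, 0.9, 1.1),
      cl_api = base * dil * runif(1, 0.9, 1.1))
  })
}

# a measurement row built directly from the forward circuit + GHK model
# (no trace processing), for exact-recovery fits
forward_measurement <- function(p_cl_na, g_frt = 1e-3, g_drug = 4e-3,
                                p_frt = 1, junction = 1.2, id = "r1",
                                a = paper_activities(), slope_mV = 61.5) {
  v_frt <- ghk_potential(p_frt, a[["na_baso"]], a[["cl_baso"]],
                         a[["na_api"]], a[["cl_api"]], slope_mV = slope_mV)
  v_drug <- ghk_potential(p_cl_na, a[["na_baso"]], a[["cl_baso"]],
                          a[["na_api"]], a[["cl_api"]], slope_mV = slope_mV)
  v_t <- compose_dilution_potential(v_drug, v_frt, g_frt, g_drug)
  data.frame(replicate_id = id, g_frt = g_frt, g_total = g_frt + g_drug,
             v_frt_raw = v_frt + junction, v_t_raw = v_t + junction,
             v_junction = junction, stringsAsFactors = FALSE)
}
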