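#' Estimate P_Cl/P_Na from paired dilution-potential measurements
#'
#' The package's central estimator. Each replicate (one monolayer) supplies
#' the untreated and treated transepithelial conductances and dilution
#' potentials plus the junction potential measured after lysis. Per
#' replicate the chain is: junction-correct both potentials, derive the
#' drug-pathway conductance (`g_total - g_frt`), decompose the treated
#' potential onto the drug pathway with the two-conductance circuit model,
#' and invert the Goldman-Hodgkin-Katz relation in closed form. Replicates
#' whose chain fails (no added conductance, potential outside the Nernstian
#' limits, negative P) are retained in the output with the failure reason;
#' they are never silently dropped. Valid replicates are summarized as
#' mean +/- s.e.m.
#'
#' @param data Data frame with one row per replicate and columns
#'   `replicate_id`, `g_frt`, `g_total` (mS/cm^2), `v_frt_raw`, `v_t_raw`,
#'   `v_junction` (mV).
#' @param high_solution,low_solution The basolateral (high-NaCl) and apical
#'   (diluted) bath compositions; defaults are the packaged Ringer's
#'   recipes.
#' @param slope Slope mode passed to [ghk_slope()]: `"paper"` (61.5 mV) or
#'   `"exact"`.
#' @param guard_mV Guard band around the Nernstian limits; see
#'   [ghk_invert()].
#' @param shared_gamma If `TRUE`, the apical (low) bath re-uses the
#'   basolateral bath's activity coefficients instead of its own
#'   (compatibility mode for analyses that did not recompute gamma after
#'   dilution). Default `FALSE`: each solution gets coefficients at its own
#'   ionic strength.
#' @param mu_override Optional ionic strength (M) forced on both baths'
#'   coefficient calculations; `NULL` (default) uses each recipe's own.
#' @return An object of class `"ghk_fit"`: list with `replicates` (per-
#'   replicate data frame including `p_cl_na`, `valid`, `reason`),
#'   `estimate` (`mean`, `sem`, `n`), `activities` (the four Na/Cl
#'   activities used, mM), `slope_mV`, and the call. Errors if no replicate
#'   is valid, listing every per-replicate failure.
#' @seealso [coef.ghk_fit()], [summary.ghk_fit()], [predict.ghk_fit()],
#'   [simulate.ghk_fit()]
#' @examples
#' d <- data.frame(replicate_id = "m1", g_frt = 1e-3, g_total = 5e-3,
#'                 v_frt_raw = 1.53, v_t_raw = -5.04, v_junction = 1.2)
#' fit <- fit_selectivity(d)
#' coef(fit)
#' @export
fit_selectivity <- function(data,
                            high_solution = ringer_high(),
                            low_solution = ringer_low(),
                            slope = c("paper", "exact"),
                            guard_mV = 0.1,
                            shared_gamma = FALSE,
                            mu_override = NULL) {
  slope <- match.arg(slope)
  need <- c("replicate_id", "g_frt", "g_total", "v_frt_raw", "v_t_raw",
            "v_junction")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("data must be a data frame with columns: ",
         paste(need, collapse = ", "))
  if (!nrow(data)) stop("no replicates supplied")

  slope_mV <- ghk_slope(slope, temperature_K = high_solution$temperature_K)
  act <- selectivity_activities(high_solution, low_solution,
                                shared_gamma = shared_gamma,
                                mu_override = mu_override)

  res <- data.frame(replicate_id = as.character(data$replicate_id),
                    g_frt = data$g_frt, g_total = data$g_total,
                    v_frt = NA_real_, v_t = NA_real_, g_drug = NA_real_,
                    v_drug = NA_real_, p_cl_na = NA_real_,
                    valid = FALSE, reason = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(data))) {
    step <- tryCatch({
      v_frt <- junction_correct(data$v_frt_raw[i], data$v_junction[i])
      v_t <- junction_correct(data$v_t_raw[i], data$v_junction[i])
      res$v_frt[i] <- v_frt; res$v_t[i] <- v_t
      g_drug <- drug_conductance(data$g_total[i], data$g_frt[i])
      res$g_drug[i] <- g_drug
      v_drug <- decompose_dilution_potential(v_t, v_frt, data$g_frt[i], g_drug)
      res$v_drug[i] <- v_drug
      res$p_cl_na[i] <- ghk_invert(v_drug, act["na_baso"], act["cl_baso"],
                                   act["na_api"], act["cl_api"],
                                   slope_mV = slope_mV, guard_mV = guard_mV)
      NULL
    }, error = function(e) conditionMessage(e))
    if (is.null(step)) res$valid[i] <- TRUE else res$reason[i] <- step
  }

  p <- res$p_cl_na[res$valid]
  if (!length(p))
    stop("no valid replicates; per-replicate failures:\n",
         paste(sprintf("  %s: %s", res$replicate_id, res$reason),
               collapse = "\n"))
  est <- list(mean = mean(p),
              sem = if (length(p) > 1) stats::sd(p) / sqrt(length(p)) else NA_real_,
              n = length(p))
  structure(list(replicates = res, estimate = est, activities = act,
                 slope_mV = slope_mV, guard_mV = guard_mV,
                 high_solution = high_solution, low_solution = low_solution,
                 call = match.call()),
            class = "ghk_fit")
}

#' Na+/Cl- activities for a dilution-potential pair of baths
#'
#' @inheritParams fit_selectivity
#' @return Named vector `c(na_baso, cl_baso, na_api, cl_api)` in mM.
#' @export
selectivity_activities <- function(high_solution, low_solution,
                                   shared_gamma = FALSE, mu_override = NULL) {
  a_high <- activities(high_solution, mu_override = mu_override)
  mu_low <- if (shared_gamma && is.null(mu_override))
    attr(a_high, "ionic_strength_M") else mu_override
  a_low <- activities(low_solution, mu_override = mu_low)
  c(na_baso = ion_activity(a_high, "Na"), cl_baso = ion_activity(a_high, "Cl"),
    na_api = ion_activity(a_low, "Na"), cl_api = ion_activity(a_low, "Cl"))
}

#' @export
print.ghk_fit <- function(x, digits = 3, ...) {
  cat("GHK dilution-potential selectivity fit\n")
  cat(sprintf("  P_Cl/P_Na = %.*g +/- %.*g (s.e.m.), n = %d valid of %d replicates\n",
              digits, x$estimate$mean, digits,
              x$estimate$sem, x$estimate$n, nrow(x$replicates)))
  invisible(x)
}

#' @export
coef.ghk_fit <- function(object, ...) {
  c(p_cl_na = object$estimate$mean)
}

#' Summarize a selectivity fit
#'
#' @param object A `"ghk_fit"`.
#' @param ... Unused.
#' @return The object, invisibly, after printing the per-replicate table,
#'   the aggregate estimate, and any excluded replicates with reasons.
#' @export
summary.ghk_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  slope: %.4g mV; activities (mM): Na_baso %.2f, Cl_baso %.2f, Na_api %.2f, Cl_api %.2f\n",
              object$slope_mV, object$activities["na_baso"],
              object$activities["cl_baso"], object$activities["na_api"],
              object$activities["cl_api"]))
  cat("\nPer-replicate results:\n")
  print(object$replicates, row.names = FALSE, digits = 4)
  bad <- object$replicates[!object$replicates$valid, ]
  if (nrow(bad)) {
    cat("\nExcluded replicates:\n")
    for (i in seq_len(nrow(bad)))
      cat(sprintf("  %s: %s\n", bad$replicate_id[i], bad$reason[i]))
  }
  invisible(object)
}

#' Predicted treated dilution potentials at the pooled estimate
#'
#' Recomposes, for each valid replicate, the treated potential `v_t` that the
#' pooled mean P_Cl/P_Na would produce given that replicate's conductances
#' and untreated potential.
#'
#' @param object A `"ghk_fit"`.
#' @param p_cl_na Permeability ratio to predict at; defaults to the pooled
#'   mean.
#' @param ... Unused.
#' @return Named vector of predicted `v_t` (mV), junction-corrected scale,
#'   `NA` for invalid replicates.
#' @export
predict.ghk_fit <- function(object, p_cl_na = coef(object), ...) {
  v_drug <- ghk_potential(p_cl_na, object$activities["na_baso"],
                          object$activities["cl_baso"],
                          object$activities["na_api"],
                          object$activities["cl_api"],
                          slope_mV = object$slope_mV)
  r <- object$replicates
  out <- ifelse(r$valid,
                compose_dilution_potential(v_drug, r$v_frt, r$g_frt, r$g_drug),
                NA_real_)
  names(out) <- r$replicate_id
  out
}

#' Residuals of a selectivity fit
#'
#' Observed minus predicted treated dilution potential (mV) at the pooled
#' mean P_Cl/P_Na; a direct measure of between-replicate heterogeneity on
#' the voltage scale.
#'
#' @param object A `"ghk_fit"`.
#' @param ... Unused.
#' @return Named numeric vector (mV), `NA` for invalid replicates.
#' @export
residuals.ghk_fit <- function(object, ...) {
  object$replicates$v_t - predict(object)
}

#' Plot per-replicate permeability ratios
#'
#' Dot plot of the per-replicate P_Cl/P_Na values with the pooled
#' mean +/- s.e.m. and the P = 1 (non-selective) reference line.
#'
#' @param x A `"ghk_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ghk_fit <- function(x, ...) {
  r <- x$replicates[x$replicates$valid, ]
  graphics::plot(seq_len(nrow(r)), r$p_cl_na, xlab = "replicate",
                 ylab = expression(P[Cl] / P[Na]), xaxt = "n",
                 pch = 19, ...)
  graphics::axis(1, at = seq_len(nrow(r)), labels = r$replicate_id)
  graphics::abline(h = 1, lty = 3, col = "grey50")
  graphics::abline(h = x$estimate$mean, lwd = 2)
  if (is.finite(x$estimate$sem))
    graphics::abline(h = x$estimate$mean + c(-1, 1) * x$estimate$sem,
                     lty = 2)
  invisible(x)
}

#' Simulate replicate measurement tables from a fitted selectivity
#'
#' Forward-simulates new per-replicate measurement tables (the same columns
#' [fit_selectivity()] consumes) at the fitted P_Cl/P_Na, using the median
#' observed conductances and Gaussian measurement noise on the potentials.
#'
#' @param object A `"ghk_fit"`.
#' @param nsim Number of tables to simulate.
#' @param seed Seed passed to [set.seed()]; `NULL` leaves the RNG alone.
#' @param noise_sd_mV Gaussian s.d. added to each simulated potential.
#' @param ... Unused.
#' @return A list of `nsim` data frames.
#' @export
simulate.ghk_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd_mV = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  r <- object$replicates[object$replicates$valid, ]
  v_drug <- ghk_potential(coef(object), object$activities["na_baso"],
                          object$activities["cl_baso"],
                          object$activities["na_api"],
                          object$activities["cl_api"],
                          slope_mV = object$slope_mV)
  lapply(seq_len(nsim), function(k) {
    v_frt <- stats::median(r$v_frt)
    g_frt <- stats::median(r$g_frt); g_drug <- stats::median(r$g_drug)
    n <- nrow(r)
    v_t <- compose_dilution_potential(v_drug, v_frt, g_frt, g_drug)
    data.frame(replicate_id = sprintf("sim%d_%d", k, seq_len(n)),
               g_frt = g_frt, g_total = g_frt + g_drug,
               v_frt_raw = v_frt + stats::rnorm(n, 0, noise_sd_mV),
               v_t_raw = v_t + stats::rnorm(n, 0, noise_sd_mV),
               v_junction = 0)
  })
}
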