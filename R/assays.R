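#' Construct an ion-selective-electrode chloride trace
#'
#' The liposome efflux protocol: 2 min baseline, compound addition, 10 min
#' of efflux, Triton X-100 lysis, 3 min tail (15 min total).
#'
#' @param time_min Sample times, minutes, strictly increasing.
#' @param chloride_ppm Free chloride reading, ppm.
#' @param compound_time_min Time of compound addition (default 2).
#' @param triton_time_min Time of Triton addition (default 12).
#' @return Object of class `"ise_trace"`.
#' @export
ise_trace <- function(time_min, chloride_ppm, compound_time_min = 2,
                      triton_time_min = 12) {
  stopifnot(length(time_min) == length(chloride_ppm))
  if (any(diff(time_min) <= 0)) stop("time_min must be strictly increasing")
  if (!(triton_time_min > compound_time_min && compound_time_min > 0))
    stop("need triton_time_min > compound_time_min > 0")
  structure(list(time_min = as.numeric(time_min),
                 chloride_ppm = as.numeric(chloride_ppm),
                 compound_time_min = compound_time_min,
                 triton_time_min = triton_time_min),
            class = "ise_trace")
}

#' Percent chloride efflux from an ISE trace
#'
#' Baselines the trace on its first 2 minutes (the pre-compound phase) and
#' expresses the compound-induced chloride release as a percentage of the
#' post-Triton (fully lysed, 100% efflux) level:
#' `100 * (pre-Triton plateau - baseline) / (post-Triton plateau - baseline)`.
#' Values below 0% or above 100% are reported as-is with a flag, never
#' clipped silently.
#'
#' @param trace An [ise_trace()].
#' @param window_min Plateau window (minutes) for the pre-Triton and
#'   end-of-run medians.
#' @return Numeric percent with attribute `"flag"` (`""`, `"below_0"`, or
#'   `"above_100"`). Errors if the Triton plateau does not differ from
#'   baseline.
#' @export
chloride_efflux_percent <- function(trace, window_min = 1) {
  stopifnot(inherits(trace, "ise_trace"))
  t <- trace$time_min; y <- trace$chloride_ppm
  if (max(t) <= trace$triton_time_min)
    stop("trace must extend beyond the Triton addition")
  base <- stats::median(y[t < trace$compound_time_min])
  pre <- stats::median(y[t >= trace$triton_time_min - window_min &
                           t < trace$triton_time_min])
  post <- stats::median(y[t >= max(t) - window_min])
  denom <- post - base
  if (abs(denom) < .Machine$double.eps * 100)
    stop("Triton plateau equals baseline: 100% efflux level undefined")
  pct <- 100 * (pre - base) / denom
  flag <- if (pct < 0) "below_0" else if (pct > 100) "above_100" else ""
  structure(pct, flag = flag)
}

#' Construct a plate-reader table
#'
#' @param data Data frame with columns `well`, `role` (one of `"blank"`,
#'   `"triton"`, `"compound"`), `fluorescence`, and optionally `compound`
#'   and `dose`.
#' @return Object of class `"plate_readings"` (a validated data frame).
#' @export
plate_readings <- function(data) {
  need <- c("well", "role", "fluorescence")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("plate data needs columns: ", paste(need, collapse = ", "))
  if (!all(data$role %in% c("blank", "triton", "compound")))
    stop("role must be one of blank, triton, compound")
  if (!any(data$role == "blank") || !any(data$role == "triton"))
    stop("plate needs at least one blank and one triton control well")
  structure(data, class = c("plate_readings", "data.frame"))
}

#' Percent viability from an alamarBlue plate
#'
#' Blank (untreated) wells define 100% viability and Triton X-100 wells 0%:
#' `100 * (F - mean(F_triton)) / (mean(F_blank) - mean(F_triton))` per
#' compound well. Invariant to affine rescaling (gain/offset) of the raw
#' fluorescence.
#'
#' @param plate A [plate_readings()] (or a data frame with the same
#'   columns).
#' @return Data frame of the compound wells with an added
#'   `viability_percent` column.
#' @export
viability_percent <- function(plate) {
  if (!inherits(plate, "plate_readings")) plate <- plate_readings(plate)
  f_blank <- mean(plate$fluorescence[plate$role == "blank"])
  f_triton <- mean(plate$fluorescence[plate$role == "triton"])
  if (abs(f_blank - f_triton) < .Machine$double.eps * 100)
    stop("blank and Triton control means are equal: viability scale undefined")
  out <- plate[plate$role == "compound", , drop = FALSE]
  out$viability_percent <-
    100 * (out$fluorescence - f_triton) / (f_blank - f_triton)
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

#' Construct a yeast growth table
#'
#' @param data Data frame with columns `strain` (`"WT"` or `"mutant"`),
#'   `compound`, `dose`, `replicate`, `od600` (>= 0). Vehicle wells carry
#'   `compound = "vehicle"` (any dose).
#' @return Object of class `"growth_table"`.
#' @export
growth_table <- function(data) {
  need <- c("strain", "compound", "dose", "replicate", "od600")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("growth data needs columns: ", paste(need, collapse = ", "))
  if (!all(data$strain %in% c("WT", "mutant")))
    stop("strain must be 'WT' or 'mutant'")
  if (any(data$od600 < 0)) stop("od600 must be >= 0")
  structure(data, class = c("growth_table", "data.frame"))
}

#' Percent rescue growth of channel-deficient yeast
#'
#' Expresses mutant (trk1/trk2-deleted) growth under compound treatment as a
#' percentage of wild-type growth, per compound and dose, and summarizes
#' each compound by its maximum over doses (with the dose attaining it and
#' the s.e.m. across replicates at that dose).
#'
#' Two normalization modes are provided because "% of WT" is ambiguous:
#' `"vehicle_wt"` (default) divides by vehicle-treated WT growth, so the
#' percentage isolates the rescue without WT drug effects; `"matched_wt"`
#' divides by WT treated with the same compound and dose.
#'
#' @param growth A [growth_table()] (or equivalent data frame).
#' @param mode `"vehicle_wt"` or `"matched_wt"`.
#' @return List of class `"rescue_summary"`: `by_dose` (data frame:
#'   `compound`, `dose`, `percent_of_wt`, `sem`, `n`) and `max_rescue`
#'   (one row per compound: `compound`, `dose`, `percent_of_wt`, `sem`).
#' @export
rescue_percent <- function(growth, mode = c("vehicle_wt", "matched_wt")) {
  mode <- match.arg(mode)
  if (!inherits(growth, "growth_table")) growth <- growth_table(growth)
  wt <- growth[growth$strain == "WT", , drop = FALSE]
  mut <- growth[growth$strain == "mutant", , drop = FALSE]
  if (!nrow(wt) || !nrow(mut)) stop("need both WT and mutant rows")
  wt_vehicle_mean <- mean(wt$od600[wt$compound == "vehicle"])

  ref_od <- function(compound, dose) {
    if (mode == "vehicle_wt") return(wt_vehicle_mean)
    sel <- wt$compound == compound & wt$dose == dose
    if (!any(sel)) stop("no matched WT wells for ", compound, " at dose ", dose)
    mean(wt$od600[sel])
  }
  keys <- unique(mut[, c("compound", "dose")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    cmp <- keys$compound[i]; d <- keys$dose[i]
    ref <- ref_od(cmp, d)
    if (!is.finite(ref) || ref <= 0)
      stop("reference WT OD600 is zero or undefined for ", cmp, " dose ", d)
    pct <- 100 * mut$od600[mut$compound == cmp & mut$dose == d] / ref
    data.frame(compound = cmp, dose = d, percent_of_wt = mean(pct),
               sem = if (length(pct) > 1) stats::sd(pct) / sqrt(length(pct))
                     else NA_real_,
               n = length(pct), stringsAsFactors = FALSE)
  })
  by_dose <- do.call(rbind, rows)
  max_rows <- lapply(split(by_dose, by_dose$compound), function(df) {
    df[which.max(df$percent_of_wt), c("compound", "dose", "percent_of_wt",
                                      "sem")]
  })
  structure(list(by_dose = by_dose,
                 max_rescue = do.call(rbind, c(max_rows,
                                               make.row.names = FALSE)),
                 mode = mode),
            class = "rescue_summary")
}

#' @export
print.rescue_summary <- function(x, ...) {
  cat("Yeast rescue growth (mode:", x$mode, ")\nMaximum % growth relative to WT:\n")
  print(x$max_rescue, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit a phosphorus standard curve for liposome quantification
#'
#' Least-squares line of 820 nm absorbance against nanomoles of phosphorus
#' in each standard (`volume_uL` of a `standard_mM` phosphorus solution,
#' so nmol = uL * mM).
#'
#' @param volume_uL Standard volumes, e.g. `c(0, 20, 40, ..., 140)`.
#' @param absorbance Measured absorbances, same length.
#' @param standard_mM Concentration of the phosphorus standard (default
#'   0.65 mM).
#' @return Object of class `"phosphorus_curve"`: the underlying [lm()] fit,
#'   `slope` (absorbance per nmol), `intercept`, and `r_squared`.
#' @export
phosphorus_curve <- function(volume_uL, absorbance, standard_mM = 0.65) {
  stopifnot(length(volume_uL) == length(absorbance))
  if (length(volume_uL) < 3) stop("need at least 3 standards")
  nmol <- volume_uL * standard_mM
  if (stats::var(nmol) == 0) stop("standards are all identical: cannot fit a line")
  fit <- stats::lm(absorbance ~ nmol)
  if (stats::var(absorbance) == 0 || abs(stats::coef(fit)[2]) < 1e-12)
    stop("standard absorbances carry no slope: rank-deficient standard curve")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((absorbance - mean(absorbance))^2)
  structure(list(fit = fit,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot,
                 nmol_range = range(nmol),
                 abs_range = range(stats::fitted(fit))),
            class = "phosphorus_curve")
}

#' @export
print.phosphorus_curve <- function(x, ...) {
  cat(sprintf("Phosphorus standard curve: A820 = %.5g + %.5g * nmol (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Quantify phosphorus (and lipid) from a standard curve
#'
#' Inverts the fitted line to nanomoles of phosphorus, then divides by the
#' digested sample volume to give the phosphorus concentration of the
#' liposome stock. One phosphorus per phospholipid makes this also the
#' phospholipid concentration.
#'
#' @param curve A [phosphorus_curve()].
#' @param absorbance Sample absorbance(s) at 820 nm.
#' @param sample_uL Volume of liposome stock digested (default 10 uL).
#' @return Data frame: `absorbance`, `phosphorus_nmol`, `phosphorus_mM`
#'   (= lipid mM), `extrapolated`. Warns when a sample lies outside the
#'   standards' absorbance range.
#' @export
phosphorus_quantify <- function(curve, absorbance, sample_uL = 10) {
  stopifnot(inherits(curve, "phosphorus_curve"))
  nmol <- (absorbance - curve$intercept) / curve$slope
  extrap <- absorbance < min(curve$abs_range) | absorbance > max(curve$abs_range)
  if (any(extrap))
    warning("sample absorbance outside the standard range: extrapolating")
  data.frame(absorbance = absorbance, phosphorus_nmol = nmol,
             phosphorus_mM = nmol / sample_uL, extrapolated = extrap)
}

#' Normalize per-epithelium counts to the vehicle-treated control
#'
#' @param values Treated counts (e.g. scintillation counts of secreted
#'   labelled bicarbonate).
#' @param vehicle_values Vehicle-control counts; their mean must be > 0.
#' @return `values / mean(vehicle_values)`, fold-of-vehicle.
#' @export
normalize_to_vehicle <- function(values, vehicle_values) {
  m <- mean(vehicle_values)
  if (!is.finite(m) || m <= 0)
    stop("vehicle mean must be > 0 to normalize")
  values / m
}
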