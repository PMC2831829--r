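#' Substrate cleavage fraction
#'
#' The model output: `cleaved / (cleaved + uncleaved)` reporter substrate
#' at every node and time, in `[0, 1]`. Positions with zero total
#' substrate are reported as `NA`.
#'
#' @param field A `ConcentrationField` containing the substrate pair.
#' @param substrate,cleaved Species names of the pair.
#' @return Numeric matrix (nodes x times) of fractions.
#' @export
substrate_cleavage_fraction <- function(field, substrate = "substrate",
                                        cleaved = "substrate_cleaved") {
  u <- field_species(field, substrate)
  v <- field_species(field, cleaved)
  tot <- u + v
  f <- ifelse(tot > 0, v / tot, NA_real_)
  pmin(pmax(f, 0), 1)
}

#' First threshold crossing time of a monotone trace
#'
#' Returns the first time the trace reaches `threshold`, linearly
#' interpolated between saved points. Sub-tolerance numerical ripple is
#' removed with a running maximum before interpolation. A threshold that
#' is never reached gives `NA` (a missing-value sentinel, not an error).
#'
#' @param trace Fraction-versus-time values.
#' @param times Matching time points (s).
#' @param threshold Fraction in (0, 1).
#' @return Crossing time (s) or `NA_real_`.
#' @export
threshold_crossing_time <- function(trace, times, threshold) {
  stopifnot(length(trace) == length(times))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  if (anyNA(trace)) return(NA_real_)
  tr <- cummax(trace)                       # clip integration ripple
  i <- which(tr >= threshold)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(times[1])
  t0 <- times[i - 1]; t1 <- times[i]
  f0 <- tr[i - 1]; f1 <- tr[i]
  if (f1 == f0) return(t1)
  t0 + (threshold - f0) / (f1 - f0) * (t1 - t0)
}

#' End-to-end delay at a cleavage threshold
#'
#' The anisotropy read-out: time at which the far end (`x = L`) crosses a
#' substrate-cleavage threshold minus the time at the near end (`x = 0`).
#'
#' @param field A `ConcentrationField` spanning the full domain.
#' @param threshold Cleavage fraction (standard read-outs: 0.01 for
#'   onset, 0.5 for half-maximal cleavage).
#' @param scenario_id Label stored in the output row.
#' @param diffusivity_scale Fold-factor stored in the output row (`Inf`
#'   for the no-diffusion case).
#' @return One-row data frame with columns `scenario_id`, `scale`,
#'   `threshold`, `near_time_s`, `far_time_s`, `delay_s` (`NA` when a
#'   crossing is missing).
#' @export
end_to_end_delay <- function(field, threshold, scenario_id = "scenario",
                             diffusivity_scale = 1) {
  fr <- substrate_cleavage_fraction(field)
  near <- threshold_crossing_time(fr[1, ], field$times, threshold)
  far <- threshold_crossing_time(fr[nrow(fr), ], field$times, threshold)
  data.frame(scenario_id = scenario_id, scale = diffusivity_scale,
             threshold = threshold, near_time_s = near, far_time_s = far,
             delay_s = far - near, stringsAsFactors = FALSE)
}

#' Sweep over impaired diffusivities
#'
#' Runs one simulation per fold-reduction in `scales` (every diffusivity
#' divided by the scale; `Inf` means the exact no-diffusion case) and
#' collects end-to-end delays at each threshold.
#'
#' @inheritParams simulate
#' @param scales Positive fold-reduction factors (may include `Inf`).
#' @param thresholds Cleavage fractions to evaluate.
#' @param scenario_id Label for the output rows.
#' @return A delay table (one row per scale x threshold).
#' @export
diffusivity_sweep <- function(network, grid = spatial_grid(),
                              inputs = default_wave_inputs(network),
                              scales = c(1, 10, 100, 1000, 10000),
                              thresholds = c(0.01, 0.5),
                              t_end = 3600, save_dt = 1,
                              rtol = 1e-6, atol = 1e-9,
                              scenario_id = "reference") {
  if (any(scales <= 0))
    stop("scales must be > 0 (use Inf for the no-diffusion case)", call. = FALSE)
  rows <- lapply(scales, function(s) {
    field <- simulate(network, grid, inputs, t_end = t_end, save_dt = save_dt,
                      rtol = rtol, atol = atol,
                      diffusivity_scale = if (is.infinite(s)) NULL else s,
                      no_diffusion = is.infinite(s))
    do.call(rbind, lapply(thresholds, function(th)
      end_to_end_delay(field, th, scenario_id, s)))
  })
  do.call(rbind, rows)
}

#' Delay differences against the reference model
#'
#' Subtracts reference delays from variant delays row-by-row on matching
#' `(scale, threshold)` keys. Negative values represent reduced spatial
#' anisotropy in the variant; positive values an increase.
#'
#' @param variant_table,reference_table Delay tables sharing
#'   `(scale, threshold)` keys.
#' @return The variant table with reference columns and `delta_s` =
#'   variant delay - reference delay.
#' @export
delta_to_reference <- function(variant_table, reference_table) {
  key <- c("scale", "threshold")
  if (!all(key %in% names(variant_table)) || !all(key %in% names(reference_table)))
    stop("delay tables need 'scale' and 'threshold' columns", call. = FALSE)
  ref <- reference_table[, c(key, "delay_s")]
  names(ref)[3] <- "reference_delay_s"
  out <- merge(variant_table, ref, by = key, sort = FALSE)
  if (nrow(out) != nrow(variant_table))
    stop("tables do not share all (scale, threshold) keys", call. = FALSE)
  out$delta_s <- out$delay_s - out$reference_delay_s
  out[order(out$threshold, out$scale), ]
}

#' Write a delay table as delimited text
#'
#' @param table A delay table.
#' @param path Output path (tab-separated, with header).
#' @return `path`, invisibly.
#' @export
write_delay_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
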