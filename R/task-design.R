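#' Build a per-second boxcar for one task condition
#'
#' Constructs the condition's "task timeseries": one value per second of the
#' acquisition, 1 while any event of the condition is on screen and 0
#' otherwise — the same boxcar used as a regressor in whole-brain GLMs.
#' Second `s` (0-based) is 1 iff some event satisfies
#' `onset <= s < onset + duration`.
#'
#' @param events data frame with columns `onset`, `duration` (seconds) and
#'   `condition` (label). Onsets are 0-based seconds.
#' @param condition condition label to extract.
#' @param total_seconds total acquisition length in seconds.
#' @return numeric 0/1 vector of length `total_seconds`.
#' @seealso [convolve_and_sample()], [generate_events()]
#' @export
#' @examples
#' ev <- tibble::tibble(onset = c(0, 5), duration = c(2, 2), condition = "drug")
#' build_boxcar(ev, "drug", 8)
build_boxcar <- function(events, condition, total_seconds) {
  events <- validate_events(events)
  assert_scalar_number(total_seconds, "total_seconds", positive = TRUE)
  if (!condition %in% events$condition)
    stop(sprintf("unknown condition label '%s'; events contain: %s", condition,
                 paste(unique(events$condition), collapse = ", ")), call. = FALSE)
  ev <- events[events$condition == condition, , drop = FALSE]
  if (any(ev$onset + ev$duration > total_seconds))
    stop("event span exceeds `total_seconds`", call. = FALSE)
  box <- numeric(total_seconds)
  secs <- seq_len(total_seconds) - 1  # 0-based second index
  for (k in seq_len(nrow(ev)))
    box[secs >= ev$onset[k] & secs < ev$onset[k] + ev$duration[k]] <- 1
  box
}

validate_events <- function(events) {
  events <- as_tibble(events)
  need <- c("onset", "duration", "condition")
  if (!all(need %in% names(events)))
    stop("events need columns onset, duration, condition", call. = FALSE)
  if (any(events$duration <= 0)) stop("event durations must be > 0", call. = FALSE)
  if (any(events$onset < 0)) stop("event onsets must be >= 0", call. = FALSE)
  # reject overlap between events of the same condition
  for (cond in unique(events$condition)) {
    ev <- events[events$condition == cond, ]
    ev <- ev[order(ev$onset), ]
    if (nrow(ev) > 1 &&
        any(ev$onset[-1] < (ev$onset + ev$duration)[-nrow(ev)]))
      stop(sprintf("overlapping events within condition '%s'", cond), call. = FALSE)
  }
  events
}

#' Canonical double-gamma haemodynamic response kernel
#'
#' The standard two-gamma HRF: a response gamma density (shape 6, rate 1)
#' minus an undershoot gamma density (shape 16, rate 1) scaled by 1/6,
#' evaluated on a 32 s grid at step `dt` and normalized to unit peak. Peak
#' response sits near 5 s, the undershoot near 15 s.
#'
#' @param dt grid step in seconds.
#' @return numeric kernel sampled at `0, dt, 2*dt, ..., 32`.
#' @export
#' @examples
#' h <- canonical_hrf(1)
#' which.max(h) - 1  # peak at ~5 s
canonical_hrf <- function(dt = 1) {
  assert_scalar_number(dt, "dt", positive = TRUE)
  t <- seq(0, 32, by = dt)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Convolve a boxcar with the HRF and sample at acquisition times
#'
#' Linear (causal) convolution of the per-second boxcar with the canonical
#' kernel, truncated to the acquisition span, then sampled at volume
#' timestamps `v * tr` (start-of-volume convention, volume `v` counted from
#' 0). This aligns the experimental timing with the lagged BOLD response.
#'
#' @param boxcar per-second 0/1 vector from [build_boxcar()].
#' @param kernel HRF kernel at 1 s resolution from [canonical_hrf()].
#' @param tr repetition time, seconds.
#' @param n_volumes number of acquired volumes.
#' @param condition optional condition label carried in the result.
#' @return an object of class `condition_regressor`: list with `boxcar`,
#'   `convolved` (per-second), `sampled` (per-volume), `condition`, `tr`.
#' @export
convolve_and_sample <- function(boxcar, kernel, tr, n_volumes,
                                condition = NA_character_) {
  assert_scalar_number(tr, "tr", positive = TRUE)
  assert_scalar_number(n_volumes, "n_volumes", positive = TRUE)
  total_seconds <- length(boxcar)
  if ((n_volumes - 1) * tr > total_seconds - 1)
    stop(sprintf(
      "acquisition span (%g s at the last volume) exceeds the convolved support (%d s)",
      (n_volumes - 1) * tr, total_seconds - 1), call. = FALSE)
  conv <- convolve(boxcar, rev(kernel), type = "open")[seq_len(total_seconds)]
  conv[abs(conv) < 1e-12] <- 0
  vol_times <- (seq_len(n_volumes) - 1) * tr
  sampled <- approx(x = seq_len(total_seconds) - 1, y = conv,
                    xout = vol_times, rule = 2)$y
  structure(list(boxcar = boxcar, convolved = conv, sampled = sampled,
                 condition = condition, tr = tr),
            class = "condition_regressor")
}

#' Select the volumes a condition regressor marks as "on"
#'
#' After convolution and TR-sampling the regressor is continuous, so the
#' condition's volumes are taken as those where the sampled regressor
#' reaches at least `threshold_frac` of its maximum — capturing the
#' HRF-lagged plateau of each block or trial. An all-zero regressor yields
#' an empty set.
#'
#' @param regressor a `condition_regressor` from [convolve_and_sample()].
#' @param threshold_frac fraction of the regressor maximum in `(0, 1]`.
#' @return sorted, duplicate-free integer vector of 1-based volume indices.
#' @export
select_volumes <- function(regressor, threshold_frac = 0.5) {
  stopifnot(inherits(regressor, "condition_regressor"))
  assert_scalar_number(threshold_frac, "threshold_frac")
  if (threshold_frac <= 0 || threshold_frac > 1)
    stop("`threshold_frac` must be in (0, 1]", call. = FALSE)
  s <- regressor$sampled
  mx <- max(s)
  if (mx <= 0) return(integer(0))
  which(s >= threshold_frac * mx)
}

#' Condition volume sets for a task event table
#'
#' Convenience wrapper running [build_boxcar()] + [convolve_and_sample()] +
#' [select_volumes()] for each requested condition.
#'
#' @inheritParams build_boxcar
#' @param conditions condition labels (default: all present).
#' @inheritParams convolve_and_sample
#' @inheritParams select_volumes
#' @param convolved if `FALSE`, threshold the raw (unconvolved, TR-sampled)
#'   boxcar instead of the HRF-convolved regressor.
#' @return named list of 1-based volume-index vectors.
#' @export
condition_volumes <- function(events, tr, n_volumes,
                              conditions = unique(events$condition),
                              threshold_frac = 0.5, convolved = TRUE) {
  total_seconds <- ceiling(n_volumes * tr)
  kernel <- canonical_hrf(1)
  out <- lapply(conditions, function(cond) {
    box <- build_boxcar(events, cond, total_seconds)
    if (!convolved) {
      reg <- convolve_and_sample(box, 1, tr, n_volumes, condition = cond)
      reg$sampled <- approx(seq_along(box) - 1, box,
                            xout = (seq_len(n_volumes) - 1) * tr, rule = 2)$y
      reg$convolved <- box
    } else {
      reg <- convolve_and_sample(box, kernel, tr, n_volumes, condition = cond)
    }
    select_volumes(reg, threshold_frac)
  })
  setNames(out, conditions)
}
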