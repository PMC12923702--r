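#' Default region-to-network partition
#'
#' Builds the template partition the synthetic cohort uses: `n_regions - 14`
#' cortical parcels split evenly and hemisphere-symmetrically across eight
#' canonical cortical networks, plus 14 subcortical regions. The ventromedial
#' network (VMN) — the reward/anti-reward circuit spanning accumbens, caudate,
#' pallidum, putamen, thalamus, hippocampus, amygdala and medial
#' prefrontal/orbitofrontal cortex — is formed from all 14 subcortical regions
#' plus six designated medial cortical parcels, which keep their cortical
#' network membership as well (overlapping labels are allowed and expected).
#'
#' @param n_regions total region count; default 214 (200 cortical + 14
#'   subcortical).
#' @return tibble with columns `region`, `network`, `hemisphere`,
#'   `is_cortical`; regions with overlapping membership appear on several
#'   rows.
#' @export
default_network_partition <- function(n_regions = 214) {
  n_cortical <- n_regions - 14
  if (n_cortical < 16 || n_cortical %% 2 != 0)
    stop("`n_regions` must be 14 subcortical + an even cortical count >= 16",
         call. = FALSE)
  networks8 <- c("visual", "somatomotor", "dorsal_attention",
                 "salience_ventral_attention", "limbic", "control",
                 "default_mode", "temporal_parietal")
  n_h <- n_cortical / 2
  rows <- list()
  for (hemi in c("L", "R")) {
    net <- rep(networks8, length.out = n_h)
    rows[[hemi]] <- tibble(
      region = sprintf("ctx_%s_%03d", hemi, seq_len(n_h)),
      network = net, hemisphere = hemi, is_cortical = TRUE)
  }
  cortical <- dplyr::bind_rows(rows)
  sub_names <- c("accumbens", "caudate", "putamen", "pallidum",
                 "thalamus", "hippocampus", "amygdala")
  subcortical <- tibble(
    region = c(sprintf("sub_L_%s", sub_names), sprintf("sub_R_%s", sub_names)),
    network = "vmn",
    hemisphere = rep(c("L", "R"), each = 7),
    is_cortical = FALSE)
  # six medial cortical parcels (mOFC/mPFC-like) join the VMN while keeping
  # their default_mode membership
  vmn_ctx <- cortical[cortical$network == "default_mode", ]
  vmn_ctx <- dplyr::slice_head(dplyr::group_by(vmn_ctx, .data$hemisphere), n = 3)
  vmn_ctx <- dplyr::ungroup(vmn_ctx)
  vmn_ctx$network <- "vmn"
  dplyr::bind_rows(cortical, subcortical, vmn_ctx)
}

#' Template network names in fixed order
#'
#' The fixed ordering used for state templates, 4-bit encoding and
#' deterministic tie-breaks.
#' @return character vector of the 9 template network names.
#' @export
template_networks <- function() {
  c("visual", "somatomotor", "dorsal_attention", "salience_ventral_attention",
    "limbic", "control", "default_mode", "temporal_parietal", "vmn")
}

#' Synthetic parcel geometry
#'
#' Places cortical parcel centroids on the unit sphere with a per-hemisphere
#' low-discrepancy lattice (left hemisphere in the x < 0 half, right its
#' mirror image), and subcortical regions at interior points. This is the
#' geometry consumed by the spin-test rotations.
#'
#' @param partition partition tibble from [default_network_partition()].
#' @return tibble with `region`, `x`, `y`, `z`, `hemisphere`, `is_cortical`.
#' @export
parcel_geometry <- function(partition) {
  regs <- dplyr::distinct(partition, .data$region, .data$hemisphere,
                          .data$is_cortical)
  golden <- (sqrt(5) - 1) / 2
  place_hemi <- function(n, hemi) {
    k <- seq_len(n)
    z <- -1 + 2 * (k - 0.5) / n
    phi <- pi / 2 + pi * ((k * golden) %% 1)   # cos(phi) <= 0 -> x <= 0
    r <- sqrt(pmax(0, 1 - z^2))
    x <- r * cos(phi)
    cbind(x = if (hemi == "L") x else -x, y = r * sin(phi), z = z)
  }
  out <- vector("list", 4)
  i <- 1
  for (hemi in c("L", "R")) {
    ctx <- regs[regs$is_cortical & regs$hemisphere == hemi, ]
    xyz <- place_hemi(nrow(ctx), hemi)
    out[[i]] <- tibble(region = ctx$region, x = xyz[, 1], y = xyz[, 2],
                       z = xyz[, 3], hemisphere = hemi, is_cortical = TRUE)
    i <- i + 1
    sub <- regs[!regs$is_cortical & regs$hemisphere == hemi, ]
    if (nrow(sub) > 0) {
      ks <- seq_len(nrow(sub))
      zs <- -0.5 + (ks - 0.5) / nrow(sub)
      phis <- pi / 2 + pi * ((ks * golden) %% 1)
      rs <- 0.3 * sqrt(pmax(0, 1 - zs^2))
      xs <- rs * cos(phis)
      out[[i]] <- tibble(region = sub$region,
                         x = if (hemi == "L") xs else -xs,
                         y = rs * sin(phis), z = 0.3 * zs,
                         hemisphere = hemi, is_cortical = FALSE)
      i <- i + 1
    }
  }
  dplyr::bind_rows(out)
}

#' Specify a synthetic two-group, two-task cohort
#'
#' Collects every knob of the synthetic-cohort generative model. Defaults
#' emulate the study design this package targets: 22 vs 25 subjects, 214
#' regions, TR 2 s, an event-related monetary-incentive-delay (MID) task and
#' a block-design cue reactivity task.
#'
#' @param n_group_a,n_group_b subjects per group (group A plays the
#'   healthy-control role, group B the patient role).
#' @param n_regions total regions (see [default_network_partition()]).
#' @param tr repetition time, seconds.
#' @param n_volumes named vector of volumes per task (any subset of
#'   `mid`/`cue`), e.g. `c(mid = 300, cue = 240)`: a 10 min event-related
#'   run and an 8 min block run at TR 2.
#' @param network_partition region-network membership tibble.
#' @param coupling_effects tibble (`network_a`, `network_b`, `group`, `gain`)
#'   of between-network coupling gains; `group = NA` applies to both groups;
#'   gains are multiplicative on the base coupling amplitude.
#' @param condition_effects tibble (`network_a`, `network_b`, `condition`,
#'   `group`, `gain`): extra multiplicative coupling gain applied inside the
#'   named condition's event windows.
#' @param state_mean_dwell mean dwell time (seconds) of the hidden network
#'   state sequence.
#' @param state_probs occupancy weights over the 9 template networks
#'   (recycled/normalized); default uniform.
#' @param state_boost amplitude multiplier on a network's latent while that
#'   network is the hidden state (episodic network dominance).
#' @param coupling_base base amplitude of planted network-pair latents.
#' @param private_sd SD of each region's private band-limited neural
#'   fluctuation (network latents have unit SD): the idiosyncratic regional
#'   activity that keeps non-dominant networks from being perfectly
#'   phase-locked.
#' @param noise_sd white measurement-noise SD added to the sampled BOLD
#'   signal (the haemodynamic signal is standardized per region, so this is
#'   1/SNR).
#' @param loading_range range of per-region loadings on network latents.
#' @param seed integer master seed; required.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 22, n_group_b = 25, n_regions = 214,
                        tr = 2, n_volumes = c(mid = 300, cue = 240),
                        network_partition = default_network_partition(n_regions),
                        coupling_effects = NULL, condition_effects = NULL,
                        state_mean_dwell = 30, state_probs = NULL,
                        state_boost = 5, coupling_base = 1,
                        private_sd = 1.5, noise_sd = 0.5,
                        loading_range = c(0.8, 1.2), seed = NULL) {
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  spec <- structure(list(
    n_group_a = n_group_a, n_group_b = n_group_b, n_regions = n_regions,
    tr = tr, n_volumes = n_volumes, network_partition = network_partition,
    coupling_effects = coupling_effects, condition_effects = condition_effects,
    state_mean_dwell = state_mean_dwell,
    state_probs = state_probs %||% rep(1 / 9, 9), state_boost = state_boost,
    coupling_base = coupling_base, private_sd = private_sd,
    noise_sd = noise_sd,
    loading_range = loading_range, seed = as.integer(seed)),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_group_a < 1 || n_group_b < 1 || n_regions < 2)
      stop("non-positive dimensions in cohort spec", call. = FALSE)
    if (any(n_volumes < 2) || tr <= 0) stop("invalid n_volumes/tr", call. = FALSE)
    if (is.null(names(n_volumes)) || !all(names(n_volumes) %in% c("mid", "cue")))
      stop("`n_volumes` must be named with tasks 'mid'/'cue'", call. = FALSE)
    nets <- unique(network_partition$network)
    missing_nets <- setdiff(template_networks(), nets)
    if (length(missing_nets) > 0)
      stop("empty template networks: ", paste(missing_nets, collapse = ", "),
           call. = FALSE)
    n_regs <- dplyr::n_distinct(network_partition$region)
    if (n_regs != n_regions)
      stop(sprintf("partition covers %d regions, spec says %d", n_regs,
                   n_regions), call. = FALSE)
    for (eff in list(coupling_effects, condition_effects))
      if (!is.null(eff) && any(eff$gain <= 0))
        stop("all effect gains must be > 0", call. = FALSE)
    if (state_boost <= 0 || coupling_base < 0 || noise_sd < 0 ||
        (private_sd %||% 0) < 0)
      stop("invalid amplitude parameters", call. = FALSE)
  })
  invisible(spec)
}

#' Generate a synthetic task event table
#'
#' `mid`: interleaved trials, each a 4 s anticipation period (condition drawn
#' evenly and in seeded random order from reward/neutral/loss), a brief
#' target, and an outcome, separated by a fixed inter-trial interval.
#' `cue`: alternating drug / neutral blocks with inter-block rest.
#' All timings are configurable stand-ins; onsets are 0-based seconds.
#'
#' @param task `"mid"` or `"cue"`.
#' @param n_volumes,tr acquisition geometry the events must fit into.
#' @param n_trials MID trials; `NULL` fits as many as the acquisition
#'   allows (rounded down to a multiple of 3 for an even condition split).
#' @param anticipation_dur,target_dur,outcome_dur,iti MID timings, seconds.
#' @param n_blocks_per_condition,block_dur,interblock_rest cue timings;
#'   `NULL` block count fits the acquisition.
#' @param lead_in initial rest, seconds.
#' @param seed seed for the anticipation-condition ordering.
#' @return tibble with columns `onset`, `duration`, `condition`.
#' @export
generate_events <- function(task = c("mid", "cue"), n_volumes, tr,
                            n_trials = NULL, anticipation_dur = 4,
                            target_dur = 0.5, outcome_dur = 2, iti = 2.5,
                            n_blocks_per_condition = NULL, block_dur = 20,
                            interblock_rest = 10, lead_in = 10, seed = 1) {
  task <- match.arg(task)
  total <- n_volumes * tr
  if (task == "mid") {
    conds <- c("reward_anticipation", "neutral_anticipation",
               "loss_anticipation")
    trial_len <- anticipation_dur + target_dur + outcome_dur + iti
    if (is.null(n_trials)) {
      n_trials <- 3 * ((total - lead_in) %/% trial_len %/% 3)
      if (n_trials < 3) stop("acquisition too short for any MID trials",
                             call. = FALSE)
    }
    ant <- with_seed(seed, sample(rep(conds, length.out = n_trials)))
    t0 <- lead_in + (seq_len(n_trials) - 1) * trial_len
    ev <- dplyr::bind_rows(
      tibble(onset = t0, duration = anticipation_dur, condition = ant),
      tibble(onset = t0 + anticipation_dur, duration = target_dur,
             condition = "target"),
      tibble(onset = t0 + anticipation_dur + target_dur,
             duration = outcome_dur, condition = "outcome"))
  } else {
    if (is.null(n_blocks_per_condition)) {
      n_blocks_per_condition <-
        (((total - lead_in + interblock_rest) %/%
            (block_dur + interblock_rest)) %/% 2)
      if (n_blocks_per_condition < 1)
        stop("acquisition too short for any cue blocks", call. = FALSE)
    }
    n_blocks <- 2 * n_blocks_per_condition
    t0 <- lead_in + (seq_len(n_blocks) - 1) * (block_dur + interblock_rest)
    ev <- tibble(onset = t0, duration = block_dur,
                 condition = rep(c("drug", "neutral"),
                                 length.out = n_blocks))
  }
  ev <- dplyr::arrange(ev, .data$onset, .data$condition)
  if (max(ev$onset + ev$duration) > total)
    stop(sprintf("task design spans %.1f s but the acquisition is %.1f s",
                 max(ev$onset + ev$duration), total), call. = FALSE)
  validate_events(ev)
}

#' Generate a spatially autocorrelated receptor-availability map
#'
#' Draws one map from a Gaussian process on the parcel centroids with
#' covariance `exp(-d / autocorr_length)` (great-circle distance between
#' cortical centroids, Euclidean otherwise), shifts it to strictly positive
#' values, then multiplies the VMN regions by `vmn_enrichment` — emulating
#' the disproportionate availability of some receptors in subcortical
#' reward circuitry.
#'
#' @param geometry geometry tibble from [parcel_geometry()].
#' @param autocorr_length spatial autocorrelation length scale, radians (on
#'   the unit sphere).
#' @param vmn_enrichment multiplicative enrichment of VMN regions.
#' @param vmn_regions character vector of VMN region ids.
#' @param seed integer seed.
#' @return tibble with `region`, `value` (nonnegative, arbitrary binding
#'   units).
#' @export
generate_receptor_map <- function(geometry, autocorr_length = 0.5,
                                  vmn_enrichment = 1,
                                  vmn_regions = character(), seed = 1) {
  assert_scalar_number(autocorr_length, "autocorr_length", positive = TRUE)
  n <- nrow(geometry)
  xyz <- as.matrix(geometry[, c("x", "y", "z")])
  d <- receptor_distances(xyz, geometry$is_cortical)
  cv <- exp(-d / autocorr_length)
  diag(cv) <- diag(cv) + 1e-8
  L <- chol(cv)
  z <- with_seed(seed, as.vector(crossprod(L, rnorm(n))))
  val <- z - min(z) + 1            # strictly positive baseline
  enrich <- geometry$region %in% vmn_regions
  val[enrich] <- val[enrich] * vmn_enrichment
  tibble(region = geometry$region, value = val)
}

receptor_distances <- function(xyz, is_cortical) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  both_ctx <- outer(is_cortical, is_cortical, "&")
  if (any(both_ctx)) {
    dots <- tcrossprod(xyz)           # unit vectors for cortical rows
    gc <- acos(pmin(1, pmax(-1, dots)))
    d[both_ctx] <- gc[both_ctx]
  }
  d
}

#' Generate a full synthetic cohort
#'
#' Realizes the generative model for every subject and task of a
#' [cohort_spec()]:
#' \enumerate{
#'   \item a hidden semi-Markov state sequence over the 9 template networks
#'     (gamma-distributed dwell times, mean `state_mean_dwell`);
#'   \item per network, a band-limited (0.02-0.1 Hz) unit-variance latent
#'     signal at 1 s resolution, amplitude-boosted by `state_boost` while
#'     that network is the hidden state;
#'   \item region neural signal = loading-weighted sum of its networks'
#'     latents, plus planted network-pair latents whose amplitude is
#'     `coupling_base` times the group's coupling gain times any
#'     condition-window gain;
#'   \item convolution with the canonical HRF, sampling at the TR, and
#'     additive white measurement noise.
#' }
#' The hidden state sequence (per volume) is returned as ground truth. Same
#' spec + seed gives bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: list with `spec`, `subjects`
#'   (tibble `subject_id`, `group`), `events` (per task), `geometry`,
#'   `partition`, `receptors`, `timeseries` (`timeseries[[task]][[subject]]`
#'   is a `regional_timeseries`), and `state_truth` (per-task, per-subject
#'   factor of hidden network labels, one per volume).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  part <- spec$network_partition
  regions <- sort(unique(part$region))
  R <- length(regions)
  nets <- template_networks()
  geometry <- parcel_geometry(part)
  geometry <- geometry[match(regions, geometry$region), ]
  vmn_regs <- part$region[part$network == "vmn"]
  receptors <- dplyr::bind_rows(
    dplyr::mutate(
      generate_receptor_map(geometry, vmn_enrichment = 3,
                            vmn_regions = vmn_regs,
                            seed = derive_seed(spec$seed, "receptor_mor")),
      receptor = "MOR"),
    dplyr::mutate(
      generate_receptor_map(geometry, vmn_enrichment = 1.5,
                            vmn_regions = vmn_regs,
                            seed = derive_seed(spec$seed, "receptor_d2dr")),
      receptor = "D2DR"))
  receptors$provenance <- "synthetic"

  n_subj <- spec$n_group_a + spec$n_group_b
  subjects <- tibble(
    subject_id = sprintf("sub%03d", seq_len(n_subj)),
    group = rep(c("A", "B"), c(spec$n_group_a, spec$n_group_b)))

  # membership loadings structure: regions x networks indicator
  memb <- matrix(0, R, length(nets), dimnames = list(regions, nets))
  memb[cbind(match(part$region, regions), match(part$network, nets))] <- 1

  tasks <- names(spec$n_volumes)
  events <- lapply(setNames(tasks, tasks), function(tk)
    generate_events(tk, spec$n_volumes[[tk]], spec$tr,
                    seed = derive_seed(spec$seed, paste0("events_", tk))))

  if (!is.null(spec$condition_effects)) {
    all_conds <- unique(unlist(lapply(events, function(e) e$condition)))
    bad <- setdiff(spec$condition_effects$condition, all_conds)
    if (length(bad) > 0)
      stop("condition_effects name condition(s) absent from every task: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  pairs <- planted_pairs(spec)
  kernel <- canonical_hrf(1)

  timeseries <- list()
  state_truth <- list()
  for (tk in tasks) {
    n_vol <- spec$n_volumes[[tk]]
    total_sec <- ceiling(n_vol * spec$tr)
    cond_windows <- condition_window_masks(events[[tk]], total_sec)
    ts_list <- list()
    st_list <- list()
    for (s in seq_len(n_subj)) {
      sid <- subjects$subject_id[s]
      grp <- subjects$group[s]
      sim <- with_seed(
        derive_seed(spec$seed, paste("subject", sid, tk)),
        simulate_subject(spec, memb, pairs, cond_windows, grp, total_sec,
                         n_vol, kernel))
      ts_list[[sid]] <- structure(
        list(data = sim$bold, tr = spec$tr, subject_id = sid, group = grp,
             task = tk), class = "regional_timeseries")
      st_list[[sid]] <- sim$hidden_vol
    }
    timeseries[[tk]] <- ts_list
    state_truth[[tk]] <- st_list
  }
  structure(list(spec = spec, subjects = subjects, events = events,
                 geometry = geometry, partition = part,
                 receptors = as_tibble(receptors),
                 timeseries = timeseries, state_truth = state_truth),
            class = "synthetic_cohort")
}

# union of network pairs named by coupling_effects / condition_effects
planted_pairs <- function(spec) {
  eff <- dplyr::bind_rows(
    if (!is.null(spec$coupling_effects))
      spec$coupling_effects[, c("network_a", "network_b")],
    if (!is.null(spec$condition_effects))
      spec$condition_effects[, c("network_a", "network_b")])
  if (is.null(eff) || nrow(eff) == 0) return(NULL)
  key <- apply(eff, 1, function(r) paste(sort(r), collapse = "|"))
  dplyr::distinct(tibble(network_a = eff$network_a, network_b = eff$network_b,
                         key = key), .data$key, .keep_all = TRUE)
}

# per-second 0/1 mask per condition
condition_window_masks <- function(events, total_sec) {
  conds <- unique(events$condition)
  sapply(setNames(conds, conds),
         function(cd) build_boxcar(events, cd, total_sec))
}

simulate_subject <- function(spec, memb, pairs, cond_windows, grp, total_sec,
                             n_vol, kernel) {
  nets <- colnames(memb)
  K <- length(nets)
  R <- nrow(memb)
  hidden <- draw_state_sequence(total_sec, K, spec$state_probs,
                                spec$state_mean_dwell)
  lat <- band_limited_noise(total_sec, K)
  amp <- matrix(1, total_sec, K)
  amp[cbind(seq_len(total_sec), hidden)] <- spec$state_boost
  load <- memb * matrix(runif(R * K, spec$loading_range[1],
                              spec$loading_range[2]), R, K)
  neural <- (lat * amp) %*% t(load)
  if ((spec$private_sd %||% 0) > 0)
    neural <- neural + spec$private_sd * band_limited_noise(total_sec, R)
  if (!is.null(pairs)) {
    u <- band_limited_noise(total_sec, nrow(pairs))
    for (q in seq_len(nrow(pairs))) {
      na <- pairs$network_a[q]; nb <- pairs$network_b[q]
      a <- rep(spec$coupling_base, total_sec)
      a <- a * effect_gain(spec$coupling_effects, na, nb, grp)
      a <- a * condition_gain(spec$condition_effects, na, nb, grp,
                              cond_windows, total_sec)
      members <- memb[, na] > 0 | memb[, nb] > 0
      neural[, members] <- neural[, members] + (u[, q] * a)
    }
  }
  bold_sec <- hrf_convolve_matrix(neural, kernel)
  # arbitrary BOLD units: standardize each region's haemodynamic signal so
  # `noise_sd` is the measurement noise per unit of signal SD (1/SNR)
  bold_sec <- scale(bold_sec)
  vol_t <- (seq_len(n_vol) - 1) * spec$tr
  bold <- sample_at_times(bold_sec, vol_t)
  bold <- bold + matrix(rnorm(length(bold), sd = spec$noise_sd),
                        nrow(bold), ncol(bold))
  dimnames(bold) <- list(NULL, rownames(memb))
  hidden_vol <- factor(nets[hidden[pmin(floor(vol_t) + 1, total_sec)]],
                       levels = nets)
  list(bold = bold, hidden_vol = hidden_vol)
}

draw_state_sequence <- function(total_sec, n_states, probs, mean_dwell) {
  probs <- rep_len(probs, n_states)
  probs <- probs / sum(probs)
  seq_out <- integer(0)
  prev <- 0L
  while (length(seq_out) < total_sec) {
    repeat {
      st <- sample.int(n_states, 1, prob = probs)
      if (st != prev || n_states == 1) break
    }
    dwell <- max(8, round(rgamma(1, shape = 4, scale = mean_dwell / 4)))
    seq_out <- c(seq_out, rep(st, dwell))
    prev <- st
  }
  seq_out[seq_len(total_sec)]
}

effect_gain <- function(effects, na, nb, grp) {
  if (is.null(effects)) return(1)
  hit <- ((effects$network_a == na & effects$network_b == nb) |
          (effects$network_a == nb & effects$network_b == na)) &
         (is.na(effects$group) | effects$group == grp)
  if (!any(hit)) 1 else prod(effects$gain[hit])
}

condition_gain <- function(effects, na, nb, grp, cond_windows, total_sec) {
  g <- rep(1, total_sec)
  if (is.null(effects)) return(g)
  hit <- ((effects$network_a == na & effects$network_b == nb) |
          (effects$network_a == nb & effects$network_b == na)) &
         (is.na(effects$group) | effects$group == grp)
  for (k in which(hit)) {
    cond <- effects$condition[k]
    # a condition from the other task simply has no windows here
    if (!cond %in% colnames(cond_windows)) next
    w <- cond_windows[, cond] > 0
    g[w] <- g[w] * effects$gain[k]
  }
  g
}

# causal convolution of every column with the HRF kernel via FFT
hrf_convolve_matrix <- function(x, kernel) {
  n <- nrow(x); m <- length(kernel)
  nf <- stats::nextn(n + m - 1, 2)
  fx <- mvfft(rbind(x, matrix(0, nf - n, ncol(x))))
  fk <- fft(c(kernel, numeric(nf - m)))
  out <- Re(mvfft(fx * fk, inverse = TRUE)) / nf
  out[seq_len(n), , drop = FALSE]
}

# linear interpolation of each column at arbitrary times (1 s input grid,
# time 0 = first row)
sample_at_times <- function(x, times) {
  n <- nrow(x)
  i0 <- pmin(floor(times), n - 1)
  frac <- times - i0
  lo <- x[i0 + 1, , drop = FALSE]
  hi <- x[pmin(i0 + 2, n), , drop = FALSE]
  lo * (1 - frac) + hi * frac
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%d A / %d B), %d regions, tasks: %s\n",
    nrow(x$subjects), sum(x$subjects$group == "A"),
    sum(x$subjects$group == "B"),
    dplyr::n_distinct(x$partition$region),
    paste(names(x$timeseries), collapse = ", ")))
  invisible(x)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n=%d+%d, %d regions, tr=%gs, volumes: %s, seed=%d\n",
    x$n_group_a, x$n_group_b, x$n_regions, x$tr,
    paste(sprintf("%s=%d", names(x$n_volumes), x$n_volumes), collapse = " "),
    x$seed))
  invisible(x)
}
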