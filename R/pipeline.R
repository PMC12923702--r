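#' Assemble a pipeline run configuration
#'
#' Bundles every stage's parameters with a single master seed. All
#' randomness (cohort synthesis, permutations, spins) is derived from this
#' seed via named substreams, so re-running an identical configuration
#' reproduces identical outputs, and toggling one stage never shifts
#' another's draws.
#'
#' @param seed master integer seed (required).
#' @param mode `"synthetic"` (generate the cohort) or `"load"` (read a
#'   cohort directory written by [write_cohort()]).
#' @param spec a [cohort_spec()] for synthetic mode; defaults to the study
#'   design (22 vs 25 subjects, 214 regions) with the pipeline's seed.
#' @param input_dir cohort directory for load mode.
#' @param tasks tasks to analyse.
#' @param conditions per task, the condition of interest and its neutral
#'   comparator.
#' @param n_bins,threshold_frac miFC estimator bins and volume-selection
#'   threshold.
#' @param min_volumes estimator floor for condition-restricted miFC;
#'   condition windows cover only part of a run, so the pipeline default is
#'   `4 * n_bins` rather than the stricter whole-run default.
#' @param n_perm,alpha permutation count and familywise level.
#' @param n_spin spin permutations for the PLS stage.
#' @param block_len BDMC block length (bits).
#' @param out_dir output directory (optional; no files written if `NULL`).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, mode = c("synthetic", "load"), spec = NULL,
                       input_dir = NULL, tasks = c("mid", "cue"),
                       conditions = list(
                         mid = c(interest = "reward_anticipation",
                                 neutral = "neutral_anticipation"),
                         cue = c(interest = "drug", neutral = "neutral")),
                       n_bins = 8, threshold_frac = 0.5,
                       min_volumes = 4 * n_bins, n_perm = 1000,
                       alpha = 0.05, n_spin = 1000, block_len = 12,
                       out_dir = NULL) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  mode <- match.arg(mode)
  if (mode == "load" && is.null(input_dir))
    stop("`input_dir` required in load mode", call. = FALSE)
  structure(list(seed = as.integer(seed), mode = mode, spec = spec,
                 input_dir = input_dir, tasks = tasks,
                 conditions = conditions, n_bins = n_bins,
                 threshold_frac = threshold_frac, min_volumes = min_volumes,
                 n_perm = n_perm,
                 alpha = alpha, n_spin = n_spin, block_len = block_len,
                 out_dir = out_dir), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates synthesize-or-load, task design, miFC (whole task,
#' condition of interest, condition-versus-neutral contrast), edge-wise
#' max-T group inference with direction proportions and network summaries,
#' per-region degree and eigenvector centrality, brain-state dynamics with
#' group tests, and the receptor PLS with spin nulls. With `out_dir` set,
#' every table is flushed to TSV/JSON as its stage completes and a run
#' manifest (config hash, stage wall-times, file checksums, warnings) is
#' written.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return object of class `pipeline_result`: list with `cohort`, per-task
#'   `mifc` results (`edge_tests`, `direction`, `network_pairs`, `degree`,
#'   `ec`), `dynamics` (per-subject metrics and group tests), `pls`
#'   (fit, spin table, VIP, network scores, response correlations), and
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t_all <- proc.time()[["elapsed"]]
  say <- function(...) if (!quiet) message(sprintf(...))
  stage_times <- c()
  warnings_log <- character(0)
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, sprintf("[%s] %s", name,
                                               conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    stage_times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  say("stage: cohort (%s mode)", config$mode)
  cohort <- timed("cohort", {
    if (config$mode == "synthetic") {
      spec <- config$spec %||% cohort_spec(seed = derive_seed(config$seed,
                                                              "cohort"))
      generate_cohort(spec)
    } else read_cohort(config$input_dir)
  })
  report <- validate_inputs(cohort, conditions = config$conditions)
  if (nrow(report) > 0)
    warnings_log <- c(warnings_log, paste("[validate]", report$message))

  groups <- split(cohort$subjects$subject_id, cohort$subjects$group)
  out <- list(cohort = cohort, config = config, tasks = list())
  ec_diff <- list(); degree <- list()

  for (tk in intersect(config$tasks, names(cohort$timeseries))) {
    say("stage: task design + miFC [%s]", tk)
    ts_list <- cohort$timeseries[[tk]]
    tr <- ts_list[[1]]$tr
    n_vol <- nrow(ts_list[[1]]$data)
    conds <- config$conditions[[tk]]
    vols <- timed(paste0("volumes_", tk),
                  condition_volumes(cohort$events[[tk]], tr, n_vol,
                                    conditions = unname(conds),
                                    threshold_frac = config$threshold_frac))
    mats <- timed(paste0("mifc_", tk), {
      lapply(ts_list, function(ts) list(
        whole = mifc_matrix(ts, n_bins = config$n_bins),
        condition = mifc_matrix(ts, vols[[conds[["interest"]]]],
                                n_bins = config$n_bins,
                                min_volumes = config$min_volumes),
        contrast = contrast_mifc(ts, vols[[conds[["interest"]]]],
                                 vols[[conds[["neutral"]]]],
                                 n_bins = config$n_bins,
                                 min_volumes = config$min_volumes)))
    })
    say("stage: group stats [%s]", tk)
    stats_tk <- timed(paste0("stats_", tk), {
      families <- c("whole", "condition", "contrast")
      tests <- lapply(setNames(families, families), function(fam) {
        edge_permutation_test(
          lapply(mats[groups$A], `[[`, fam),
          lapply(mats[groups$B], `[[`, fam),
          n_perm = config$n_perm, alpha = config$alpha,
          seed = derive_seed(config$seed, paste("perm", tk, fam)))
      })
      list(edge_tests = tests,
           direction = purrr::map_dfr(tests, direction_proportions,
                                      .id = "family"),
           network_pairs = purrr::map_dfr(
             tests, network_pair_summary, partition = cohort$partition,
             .id = "family"))
    })
    ec_subj <- t(sapply(mats, function(m)
      eigenvector_centrality(m$whole)))
    ec_diff[[tk]] <- ec_group_difference(ec_subj[groups$A, , drop = FALSE],
                                         ec_subj[groups$B, , drop = FALSE])
    degree[[tk]] <- degree_from_significance(stats_tk$edge_tests$whole)

    say("stage: dynamics [%s]", tk)
    dyn <- timed(paste0("dynamics_", tk), {
      per_subj <- purrr::map_dfr(names(ts_list), function(sid) {
        st <- hbsd_states(ts_list[[sid]], cohort$partition)
        ds <- dynamics_summary(st, block_len = config$block_len)
        dplyr::bind_cols(
          tibble(subject_id = sid,
                 group = cohort$subjects$group[
                   cohort$subjects$subject_id == sid]),
          tidyr::pivot_wider(
            ds$per_state[, c("state", "probability")],
            names_from = "state", values_from = "probability",
            names_prefix = "prob_"),
          ds$scalars[, c("lzc", "bdmc", "te0", "te1", "te2", "te3", "te4")])
      })
      tests <- dynamics_group_test(per_subj,
                                   n_perm = config$n_perm,
                                   alpha = config$alpha,
                                   seed = derive_seed(config$seed,
                                                      paste("dynperm", tk)))
      list(per_subject = per_subj, group_tests = tests)
    })
    out$tasks[[tk]] <- c(stats_tk, list(ec = ec_diff[[tk]],
                                        degree = degree[[tk]],
                                        dynamics = dyn,
                                        volume_sets = vols))
  }

  if (all(c("mid", "cue") %in% names(out$tasks))) {
    say("stage: receptor PLS")
    out$pls <- timed("pls", {
      responses <- dplyr::left_join(
        dplyr::left_join(
          setNames(ec_diff$mid[, c("region", "ec_difference")],
                   c("region", "ec_diff_mid")),
          setNames(ec_diff$cue[, c("region", "ec_difference")],
                   c("region", "ec_diff_cue")), by = "region"),
        dplyr::left_join(
          setNames(degree$mid, c("region", "degree_mid")),
          setNames(degree$cue, c("region", "degree_cue")), by = "region"),
        by = "region")
      input <- pls_input(cohort$receptors, responses)
      geom <- cohort$geometry[match(input$regions, cohort$geometry$region), ]
      spin <- build_spin_null(geom, n_perm = config$n_spin,
                              seed = derive_seed(config$seed, "spin"))
      fit <- pls_fit(input)
      spin_tbl <- pls_spin_test(input, spin)
      lv1 <- fit$x_scores[, 1]
      names(lv1) <- input$regions
      resp_cor <- purrr::map_dfr(fit$responses, function(rn) {
        if (sd(input$Y[, rn]) == 0)
          return(tibble(response = rn, rho = NA_real_, p = NA_real_,
                        p_spin = NA_real_))
        dplyr::mutate(spearman_spin(lv1, input$Y[, rn], spin),
                      response = rn, .before = 1)
      })
      list(input = input, fit = fit, spin_table = spin_tbl,
           vip = fit$vip,
           network_scores = network_mean_scores(lv1, cohort$partition),
           response_correlations = resp_cor)
    })
  }

  manifest <- list(
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("mifcdyn")),
    stage_seconds = as.list(stage_times),
    total_seconds = round(proc.time()[["elapsed"]] - t_all, 2),
    warnings = warnings_log)
  out$manifest <- manifest
  class(out) <- "pipeline_result"
  if (!is.null(config$out_dir))
    out$manifest <- write_pipeline_outputs(out, config$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> tasks: %s; %.1f s total\n",
              paste(names(x$tasks), collapse = ", "),
              x$manifest$total_seconds))
  invisible(x)
}

# max-T permutation test across the dynamics feature family
dynamics_group_test <- function(per_subj, n_perm, alpha, seed) {
  feats <- setdiff(names(per_subj), c("subject_id", "group"))
  keep <- feats[vapply(feats, function(f) stats::var(per_subj[[f]]) > 0,
                       logical(1))]
  data <- as.matrix(per_subj[, keep, drop = FALSE])
  ia <- which(per_subj$group == "A")
  n <- nrow(data)
  perms <- with_seed(seed, t(replicate(n_perm, sample.int(n, length(ia)))))
  res <- maxt_perm_cpp(data, ia - 1L, perms - 1L)
  p <- vapply(abs(res$t_obs),
              function(tt) (1 + sum(res$max_t >= tt)) / (n_perm + 1),
              numeric(1))
  d <- vapply(keep, function(f)
    cohens_d(per_subj[[f]][ia], per_subj[[f]][-ia]), numeric(1))
  tibble(feature = keep, t_stat = res$t_obs, p_fwe = p,
         significant = p < alpha, cohens_d = d)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  cfg <- config
  cfg$spec$network_partition <- NULL  # hashed via its own fields below
  writeLines(jsonlite::toJSON(
    lapply(unclass(cfg), function(x) if (is.data.frame(x)) as.list(x) else x),
    auto_unbox = TRUE, force = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Validate cohort inputs for consistency
#'
#' Checks region-id alignment across timeseries, geometry, receptor and
#' network tables, TR consistency across subjects, and (when `conditions`
#' is given) that each task's event table covers the configured condition
#' labels. Misaligned region sets are fatal, reported with the symmetric
#' difference; everything else is a listed warning.
#'
#' @param cohort a `synthetic_cohort` (or the list returned by
#'   [read_cohort()]).
#' @param conditions optional per-task condition labels (see
#'   [run_config()]).
#' @return tibble report with columns `level`, `message`; zero rows when
#'   clean.
#' @export
validate_inputs <- function(cohort, conditions = NULL) {
  msgs <- tibble(level = character(0), message = character(0))
  regions <- sort(unique(cohort$partition$region))
  check_set <- function(set, what) {
    if (!setequal(set, regions)) {
      bad <- c(setdiff(regions, set), setdiff(set, regions))
      stop(sprintf("region sets misaligned in %s; symmetric difference: %s",
                   what, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_set(cohort$geometry$region, "geometry")
  check_set(unique(cohort$receptors$region), "receptors")
  trs <- c()
  for (tk in names(cohort$timeseries))
    for (ts in cohort$timeseries[[tk]]) {
      check_set(colnames(ts$data),
                sprintf("timeseries %s/%s", tk, ts$subject_id))
      if (anyNA(ts$data))
        stop(sprintf("missing values in %s/%s", tk, ts$subject_id),
             call. = FALSE)
      trs <- c(trs, ts$tr)
    }
  if (length(unique(trs)) > 1)
    msgs <- dplyr::add_row(msgs, level = "warning",
                           message = "TR differs across subjects")
  if (!is.null(conditions)) {
    for (tk in intersect(names(conditions), names(cohort$events))) {
      missing_lbl <- setdiff(conditions[[tk]],
                             unique(cohort$events[[tk]]$condition))
      if (length(missing_lbl) > 0)
        stop(sprintf("events for task '%s' lack condition label(s): %s",
                     tk, paste(missing_lbl, collapse = ", ")), call. = FALSE)
    }
  }
  msgs
}

#' Write / read a cohort as flat TSV + JSON files
#'
#' One timeseries TSV per subject and task (header = region ids, one row
#' per volume), BIDS-style `events.tsv` per task (`onset`, `duration`,
#' `trial_type`; seconds, 0-based onsets), geometry / network / receptor
#' tables as TSV, hidden state sequences as TSV, and the generating spec's
#' scalar fields as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir target directory (created if needed).
#' @return `dir` (write) / a `synthetic_cohort` (read), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  for (tk in names(cohort$timeseries)) {
    ev <- cohort$events[[tk]]
    wt(data.frame(onset = ev$onset, duration = ev$duration,
                  trial_type = ev$condition), sprintf("%s_events.tsv", tk))
    for (ts in cohort$timeseries[[tk]])
      wt(as.data.frame(ts$data),
         sprintf("%s_%s_timeseries.tsv", ts$subject_id, tk))
    if (!is.null(cohort$state_truth[[tk]]))
      for (sid in names(cohort$state_truth[[tk]]))
        wt(data.frame(volume = seq_along(cohort$state_truth[[tk]][[sid]]),
                      state = as.character(cohort$state_truth[[tk]][[sid]])),
           sprintf("%s_%s_states.tsv", sid, tk))
  }
  wt(cohort$geometry, "geometry.tsv")
  wt(cohort$partition, "networks.tsv")
  wt(cohort$receptors, "receptors.tsv")
  wt(cohort$subjects, "subjects.tsv")
  meta <- cohort$spec[c("n_group_a", "n_group_b", "n_regions", "tr",
                        "state_mean_dwell", "state_boost", "coupling_base",
                        "noise_sd", "seed")]
  meta$n_volumes <- as.list(cohort$spec$n_volumes)
  jsonlite::write_json(meta, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rt <- function(name) as_tibble(read.table(
    file.path(dir, name), sep = "\t", header = TRUE, check.names = FALSE))
  subjects <- rt("subjects.tsv")
  partition <- rt("networks.tsv")
  geometry <- rt("geometry.tsv")
  receptors <- rt("receptors.tsv")
  spec_meta <- jsonlite::read_json(file.path(dir, "spec.json"),
                                   simplifyVector = TRUE)
  tasks <- sub("_events\\.tsv$", "",
               basename(Sys.glob(file.path(dir, "*_events.tsv"))))
  events <- list(); timeseries <- list(); state_truth <- list()
  for (tk in tasks) {
    ev <- rt(sprintf("%s_events.tsv", tk))
    names(ev)[names(ev) == "trial_type"] <- "condition"
    events[[tk]] <- ev
    ts_list <- list(); st_list <- list()
    for (sid in subjects$subject_id) {
      f <- file.path(dir, sprintf("%s_%s_timeseries.tsv", sid, tk))
      if (!file.exists(f)) next
      m <- as.matrix(rt(sprintf("%s_%s_timeseries.tsv", sid, tk)))
      ts_list[[sid]] <- structure(
        list(data = m, tr = spec_meta$tr, subject_id = sid,
             group = subjects$group[subjects$subject_id == sid], task = tk),
        class = "regional_timeseries")
      fs <- file.path(dir, sprintf("%s_%s_states.tsv", sid, tk))
      if (file.exists(fs))
        st_list[[sid]] <- factor(rt(sprintf("%s_%s_states.tsv", sid, tk))$state,
                                 levels = template_networks())
    }
    timeseries[[tk]] <- ts_list
    if (length(st_list) > 0) state_truth[[tk]] <- st_list
  }
  structure(list(spec = spec_meta, subjects = subjects, events = events,
                 geometry = geometry, partition = partition,
                 receptors = receptors, timeseries = timeseries,
                 state_truth = state_truth), class = "synthetic_cohort")
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wt <- function(df, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  for (tk in names(result$tasks)) {
    res <- result$tasks[[tk]]
    for (fam in names(res$edge_tests))
      wt(tidy(res$edge_tests[[fam]]),
         sprintf("%s_%s_edges.tsv", tk, fam))
    wt(res$direction, sprintf("%s_direction.tsv", tk))
    wt(res$network_pairs, sprintf("%s_network_pairs.tsv", tk))
    wt(res$degree, sprintf("%s_degree.tsv", tk))
    wt(res$ec, sprintf("%s_ec.tsv", tk))
    wt(res$dynamics$per_subject, sprintf("%s_dynamics.tsv", tk))
    wt(res$dynamics$group_tests, sprintf("%s_dynamics_tests.tsv", tk))
    jsonlite::write_json(
      lapply(res$volume_sets, as.integer),
      file.path(dir, sprintf("%s_volume_sets.json", tk)), auto_unbox = FALSE)
    files <- c(files, file.path(dir, sprintf("%s_volume_sets.json", tk)))
  }
  if (!is.null(result$pls)) {
    wt(result$pls$spin_table, "pls_components.tsv")
    wt(tibble(predictor = names(result$pls$vip), vip = result$pls$vip),
       "pls_vip.tsv")
    wt(result$pls$network_scores, "pls_network_scores.tsv")
    wt(result$pls$response_correlations, "pls_response_correlations.tsv")
  }
  manifest <- result$manifest
  manifest$files <- lapply(setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
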