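test_that("default partition covers all 9 networks with overlapping VMN", {
  part <- default_network_partition(214)
  expect_equal(dplyr::n_distinct(part$region), 214)
  expect_setequal(unique(part$network), template_networks())
  vmn <- part[part$network == "vmn", ]
  expect_equal(nrow(vmn), 20)  # 14 subcortical + 6 medial cortical
  expect_equal(sum(!vmn$is_cortical), 14)
  overlap <- intersect(vmn$region,
                       part$region[part$network == "default_mode"])
  expect_length(overlap, 6)
  expect_error(default_network_partition(15), "14 subcortical")
})

test_that("geometry puts cortical centroids on the unit sphere, mirrored", {
  part <- default_network_partition(214)
  geom <- parcel_geometry(part)
  ctx <- geom[geom$is_cortical, ]
  expect_equal(sqrt(ctx$x^2 + ctx$y^2 + ctx$z^2), rep(1, nrow(ctx)),
               tolerance = 1e-12)
  expect_true(all(ctx$x[ctx$hemisphere == "L"] <= 0))
  expect_true(all(ctx$x[ctx$hemisphere == "R"] >= 0))
  expect_equal(sum(geom$hemisphere == "L"), sum(geom$hemisphere == "R"))
  sub <- geom[!geom$is_cortical, ]
  expect_true(all(sqrt(sub$x^2 + sub$y^2 + sub$z^2) < 1))
})

test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(), "seed")
  expect_error(cohort_spec(n_group_a = 0, seed = 1), "dimensions")
  expect_error(cohort_spec(seed = 1, n_volumes = c(rest = 100)), "named")
  part <- default_network_partition(214)
  part2 <- part[part$network != "limbic", ]
  expect_error(cohort_spec(network_partition = part2, seed = 1),
               "limbic")
  eff <- tibble::tibble(network_a = "vmn", network_b = "control",
                        group = "B", gain = -1)
  expect_error(cohort_spec(coupling_effects = eff, seed = 1), "gains")
})

test_that("generated cohorts have the requested size and are seed-stable", {
  co <- tiny_cohort(seed = 30, n_a = 4, n_b = 5)
  expect_equal(nrow(co$subjects), 9)
  expect_equal(sum(co$subjects$group == "A"), 4)
  expect_length(co$timeseries$mid, 9)
  ts <- co$timeseries$mid[[1]]
  expect_false(anyNA(ts$data))
  expect_equal(ncol(ts$data), 50)
  co2 <- tiny_cohort(seed = 30, n_a = 4, n_b = 5)
  expect_identical(co$timeseries$mid[["sub003"]]$data,
                   co2$timeseries$mid[["sub003"]]$data)
  expect_identical(co$receptors$value, co2$receptors$value)
  co3 <- tiny_cohort(seed = 31, n_a = 4, n_b = 5)
  expect_false(identical(co$timeseries$mid[[1]]$data,
                         co3$timeseries$mid[[1]]$data))
})

test_that("event tables are valid designs for both tasks", {
  ev <- generate_events("cue", n_volumes = 240, tr = 2,
                        n_blocks_per_condition = 6, seed = 1)
  expect_equal(nrow(ev), 12)
  expect_equal(as.character(ev$condition[1:4]),
               c("drug", "neutral", "drug", "neutral"))
  ev_mid <- generate_events("mid", n_volumes = 300, tr = 2, n_trials = 60,
                            seed = 2)
  ant <- ev_mid[grepl("anticipation", ev_mid$condition), ]
  expect_equal(nrow(ant), 60)
  expect_equal(unname(table(ant$condition)), rep(20L, 3), ignore_attr = TRUE)
  # events always fit the acquisition (property over random timings)
  set.seed(33)
  for (k in 1:100) {
    nv <- sample(200:400, 1)
    tr <- sample(c(1, 2, 2.5), 1)
    nt <- sample(10:40, 1)
    ev_k <- try(generate_events("mid", nv, tr, n_trials = nt, seed = k),
                silent = TRUE)
    if (!inherits(ev_k, "try-error"))
      expect_lte(max(ev_k$onset + ev_k$duration), nv * tr)
  }
  expect_error(generate_events("mid", n_volumes = 40, tr = 2,
                               n_trials = 60, seed = 1), "spans")
})

test_that("null cohorts show no planted group difference", {
  co <- tiny_cohort(seed = 34, n_a = 6, n_b = 6)
  mats <- lapply(co$timeseries$mid, function(ts) mifc_matrix(ts$data))
  up <- upper.tri(mats[[1]])
  edges <- t(sapply(mats, function(m) m[up]))
  d <- colMeans(edges[1:6, ]) - colMeans(edges[7:12, ])
  se <- sqrt(apply(edges[1:6, ], 2, var) / 6 + apply(edges[7:12, ], 2, var) / 6)
  # paired edge-wise mean |delta| below 3x its Monte-Carlo SE
  expect_lt(mean(abs(d)), 3 * mean(se))
})

test_that("planted coupling raises miFC on the planted edges in most replicates", {
  hits <- 0
  n_rep <- 30
  for (k in seq_len(n_rep)) {
    eff <- tibble::tibble(network_a = "vmn", network_b = "control",
                          group = "B", gain = 1.5)
    co <- tiny_cohort(seed = 4000 + k, n_a = 3, n_b = 3,
                      n_volumes = c(mid = 300), coupling_effects = eff)
    part <- co$partition
    vmn <- unique(part$region[part$network == "vmn"])
    ctl <- setdiff(unique(part$region[part$network == "control"]), vmn)
    vmn <- setdiff(vmn, unique(part$region[part$network == "control"]))
    pm <- sapply(co$timeseries$mid, function(ts)
      mean(mifc_matrix(ts$data)[vmn, ctl]))
    hits <- hits + (mean(pm[4:6]) > mean(pm[1:3]))
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("receptor maps are nonnegative, VMN-enriched, and autocorrelated", {
  part <- default_network_partition(64)
  geom <- parcel_geometry(part)
  vmn <- unique(part$region[part$network == "vmn"])
  m <- generate_receptor_map(geom, vmn_enrichment = 3, vmn_regions = vmn,
                             seed = 1)
  expect_true(all(m$value >= 0))
  expect_gt(mean(m$value[m$region %in% vmn]),
            mean(m$value[!m$region %in% vmn]))
  # white-noise limit: region values mutually uncorrelated (each draw is
  # centred first to remove the deliberate positivity shift, a per-draw
  # constant)
  draws <- sapply(1:100, function(s)
    generate_receptor_map(geom, autocorr_length = 1e-3, seed = s)$value)
  draws <- scale(draws, center = TRUE, scale = FALSE)   # centre each draw
  cc <- cor(t(draws))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.1)
  # Moran's I increases with the autocorrelation length
  xyz <- as.matrix(geom[, c("x", "y", "z")])
  mi_at <- function(len) mean(sapply(1:50, function(s)
    morans_i(generate_receptor_map(geom, autocorr_length = len,
                                   seed = 100 + s)$value, xyz)))
  mis <- c(mi_at(0.1), mi_at(0.5), mi_at(1.0))
  expect_true(all(diff(mis) > 0))
})

test_that("hidden state ground truth aligns with episodic dominance", {
  co <- tiny_cohort(seed = 36, n_a = 2, n_b = 2, n_regions = 214,
                    n_volumes = c(mid = 300))
  truth <- co$state_truth$mid[[1]]
  expect_length(truth, 300)
  expect_true(all(levels(truth) == template_networks()))
  # dwell times respect the generator floor (8 s at TR 2), up to the
  # truncated final run and volume-grid alignment
  runs <- rle(as.integer(truth))$lengths
  expect_gte(min(head(runs, -1)), 3)
})
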