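test_that("bandpass keeps in-band and rejects out-of-band sinusoids", {
  tr <- 2
  t <- seq(0, by = tr, length.out = 600)
  inband <- matrix(sin(2 * pi * 0.05 * t), ncol = 1)
  out <- bandpass(inband, tr = tr)
  core <- 100:500
  expect_gte(var(out[core, 1]) / var(inband[core, 1]), 0.9)
  lowf <- matrix(sin(2 * pi * 0.005 * t), ncol = 1)
  out2 <- bandpass(lowf, tr = tr)
  expect_lt(var(out2[core, 1]) / var(lowf[core, 1]), 0.05)
  expect_equal(bandpass(matrix(0, 100, 2), tr = 2), matrix(0, 100, 2))
  expect_error(bandpass(inband, tr = 6), "Nyquist")
})

test_that("analytic phase recovers the phase ramp of a cosine", {
  t <- 0:499
  w <- 2 * pi * 0.04
  x <- matrix(cos(w * t), ncol = 1)
  ph <- analytic_phase(x)
  core <- 50:450
  expected <- (w * t) %% (2 * pi)
  got <- ph$phase[, 1] %% (2 * pi)
  d <- abs(got[core] - expected[core])
  expect_lt(max(pmin(d, 2 * pi - d)), 1e-2)
  expect_equal(ph$amplitude[core, 1], rep(1, length(core)), tolerance = 1e-2)
  # phase of -x is phase of x shifted by pi
  ph2 <- analytic_phase(-x)
  dd <- abs((ph2$phase[core, 1] - ph$phase[core, 1]) %% (2 * pi) - pi)
  expect_lt(max(pmin(dd, 2 * pi - dd)), 1e-6)
})

test_that("coherence snapshot hits its closed-form anchors", {
  m <- coherence_snapshot(c(0, 0, pi, pi / 2))
  expect_equal(m[1, 2], 1)
  expect_equal(m[1, 3], -1)
  expect_equal(m[1, 4], 0)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), rep(1, 4))
})

test_that("state assignment picks the phase-locked template and breaks ties by order", {
  set.seed(20)
  n_vol <- 50
  # template 1 (regions 1-4) phase-locked; the rest independent random
  phase <- matrix(runif(n_vol * 10, -pi, pi), n_vol, 10)
  phase[, 1:4] <- phase[, 1]
  ph <- structure(list(phase = phase, amplitude = phase * 0 + 1, tr = 2,
                       regions = paste0("r", 1:10)),
                  class = "phase_timeseries")
  tpl <- list(locked = 1:4, loose1 = 5:7, loose2 = 8:10)
  st <- assign_states(ph, tpl)
  expect_true(all(st$labels == "locked"))
  expect_equal(max(st$coherence[, "locked"]), 1, tolerance = 1e-12)
  # all regions identical phase -> full tie, first template wins, tie logged
  phase2 <- matrix(rep(runif(n_vol, -pi, pi), 10), n_vol, 10)
  ph2 <- structure(list(phase = phase2, amplitude = phase2 * 0 + 1, tr = 2,
                        regions = paste0("r", 1:10)),
                   class = "phase_timeseries")
  st2 <- assign_states(ph2, tpl)
  expect_true(all(st2$labels == "locked"))
  expect_equal(st2$ties, seq_len(n_vol))
  expect_error(assign_states(ph, list(a = 1:2, b = 3)), ">= 2 member")
})

test_that("template means equal the explicit pairwise upper-triangle mean", {
  set.seed(21)
  phase <- matrix(runif(20 * 6, -pi, pi), 20, 6)
  ph <- structure(list(phase = phase, amplitude = phase * 0 + 1, tr = 2,
                       regions = paste0("r", 1:6)),
                  class = "phase_timeseries")
  st <- assign_states(ph, list(a = 1:4, b = 5:6))
  for (v in c(1, 7, 20)) {
    fc <- coherence_snapshot(phase[v, 1:4])
    expect_lt(abs(st$coherence[v, "a"] - mean(fc[upper.tri(fc)])), 1e-10)
  }
})

test_that("lifetime and probability follow their defining formulas", {
  m <- state_metrics(factor(c("A", "A", "B", "B"), levels = c("A", "B", "C")),
                     tr = 2)
  expect_equal(m$probability[m$state == "A"], 0.5)
  expect_equal(m$lifetime[m$state == "A"], 4)
  expect_equal(m$n_volumes[m$state == "C"], 0L)
  single <- state_metrics(factor(rep("A", 7)), tr = 1.5)
  expect_equal(single$probability, 1)
  expect_equal(single$lifetime, 7 * 1.5)
})

test_that("4-bit encoding is big-endian and invertible for 9 states", {
  lv <- template_networks()
  expect_equal(encode_states_4bit(factor(lv[6], levels = lv)),
               c(0L, 1L, 0L, 1L))  # index 5 -> 0101
  expect_equal(encode_states_4bit(factor(lv[1:2], levels = lv)),
               c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L))
  set.seed(22)
  seqs <- factor(sample(lv, 200, replace = TRUE), levels = lv)
  expect_identical(decode_states_4bit(encode_states_4bit(seqs), lv), seqs)
})

test_that("LZ76 matches a brute-force parse on random sequences and anchors", {
  expect_equal(lzc(rep(0, 300)), 2)
  expect_equal(lzc(rep(c(0, 1), 150)), 3)
  expect_error(lzc(c(0, 1, 2)), "non-binary")
  set.seed(23)
  for (k in 1:40) {
    bits <- sample(0:1, sample(5:60, 1), replace = TRUE)
    expect_equal(lzc(bits), lz76_oracle(bits))
  }
})

test_that("BDMC follows its block formula and ranks random above periodic", {
  tab <- ctm_table(12)
  expect_length(tab, 4096)
  block <- rep(c(1, 0, 0), 4)
  seq10 <- rep(block, 10)
  expect_equal(as.numeric(bdmc(seq10)),
               unname(tab[paste(block, collapse = "")]) + log2(10))
  expect_warning(val <- bdmc(c(0, 1, 0), block_len = 12), "shorter")
  expect_equal(as.numeric(val), 0)
  set.seed(24)
  wins <- 0
  for (k in 1:20) {
    rand <- sample(0:1, 1200, replace = TRUE)
    period <- rep(c(0, 1, 1, 0, 1), length.out = 1200)
    wins <- wins + (bdmc(rand) > bdmc(period))
  }
  expect_equal(wins, 20)
})

test_that("transition entropy matches hand-computed block entropies", {
  expect_equal(transition_entropy(rep("A", 50), order = 0), 0)
  for (o in 0:4) expect_equal(transition_entropy(rep("A", 50), o), 0)
  ab <- rep(c("A", "B"), 5)
  h_hand <- -(5 / 9) * log2(5 / 9) - (4 / 9) * log2(4 / 9)
  expect_equal(transition_entropy(ab, order = 1), h_hand, tolerance = 1e-12)
  # iid uniform: entropy increases with order; order 0 approaches log2 k
  set.seed(25)
  s <- sample(LETTERS[1:4], 4000, replace = TRUE)
  hs <- sapply(0:4, function(o) transition_entropy(s, o))
  expect_true(all(diff(hs) > 0))
  expect_equal(hs[1], 2, tolerance = 0.01)
  # conditional variant is the block-entropy difference
  expect_equal(transition_entropy(s, 2, conditional = TRUE),
               transition_entropy(s, 2) - transition_entropy(s, 1))
})

test_that("dynamics summary bundles per-state and scalar metrics", {
  set.seed(26)
  lv <- template_networks()
  labs <- factor(sample(lv, 120, replace = TRUE), levels = lv)
  ds <- dynamics_summary(labs, tr = 2)
  expect_equal(sum(ds$per_state$probability), 1)
  expect_equal(ds$per_state$lifetime,
               ds$per_state$probability * 120 * 2)
  expect_true(ds$scalars$lzc > 10)
  expect_equal(ds$scalars$ctm_provenance, "synthetic-entropy")
})
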