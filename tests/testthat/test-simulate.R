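test_that("zero-amplitude artifact-free trials are exactly zero", {
  map <- default_activation_map()
  map$cms <- 0
  map$dms <- 0
  tr <- generate_trial(clean_config(activation_map = map), "NC", seed = 1)
  for (ch in tr$recording$channels) {
    expect_identical(tr$recording$series[[ch]]$Hb, rep(0, 160))
    expect_identical(tr$recording$series[[ch]]$HbO2, rep(0, 160))
  }
})

test_that("with no differential component Hb equals HbO2 everywhere", {
  map <- default_activation_map()
  map$dms <- 0
  tr <- generate_trial(clean_config(activation_map = map), "LF", seed = 2)
  for (ch in tr$recording$channels) {
    expect_equal(tr$recording$series[[ch]]$Hb, tr$recording$series[[ch]]$HbO2,
                 tolerance = 1e-14)
  }
})

test_that("plateau levels match the configured activation map", {
  cfg <- clean_config()
  tr <- generate_trial(cfg, "SE", seed = 3)
  plateau <- 70:90  # well inside the activation, away from both ramps
  map <- cfg$activation_map
  for (ch in c("RDT", "RES", "LOEA", "LES")) {
    amp <- map[map$class == "SE" & map$channel == ch, ]
    cms <- dbsi(tr$recording$series[[ch]]$Hb,
                tr$recording$series[[ch]]$HbO2)
    expect_equal(mean(cms$series_a[plateau]), amp$cms, tolerance = 1e-3)
    expect_equal(mean(cms$series_b[plateau]), amp$dms, tolerance = 1e-3)
  }
  # executing-side trapezius and erector spinae dominate shoulder elevation
  plateau_cms <- vapply(tr$recording$channels, function(ch) {
    mean(dbsi(tr$recording$series[[ch]]$Hb,
              tr$recording$series[[ch]]$HbO2)$series_a[plateau])
  }, numeric(1))
  expect_setequal(names(sort(abs(plateau_cms), decreasing = TRUE)[1:2]),
                  c("RDT", "RES"))
})

test_that("dbsi on artifact-free recordings recovers the ground truth exactly", {
  tr <- tiny_trial("TR", seed = 4)
  for (ch in tr$recording$channels) {
    s <- dbsi(tr$recording$series[[ch]]$Hb, tr$recording$series[[ch]]$HbO2)
    expect_equal(s$series_a, tr$truth[[ch]]$cms, tolerance = 1e-12)
    expect_equal(s$series_b, tr$truth[[ch]]$dms, tolerance = 1e-12)
  }
})

test_that("trial generation is deterministic and validates inputs", {
  cfg <- sim_config()
  a <- generate_trial(cfg, "LF", seed = 5)
  b <- generate_trial(cfg, "LF", seed = 5)
  expect_identical(a, b)
  c_ <- generate_trial(cfg, "LF", seed = 6)
  expect_false(identical(a$recording$series, c_$recording$series))

  expect_error(generate_trial(cfg, "UD", seed = 1), "unknown label")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(rise_time = 20), "rise_time")
  bad_map <- default_activation_map()
  bad_map <- bad_map[bad_map$channel != "RES", ]
  expect_error(sim_config(activation_map = bad_map), "missing entries")
})

test_that("dataset counts, balance and determinism hold", {
  cfg <- sim_config()
  ds <- generate_dataset(cfg, n_subjects = 1, trials_per_class = 1, seed = 7)
  expect_length(ds, 4)

  ds2 <- generate_dataset(cfg, n_subjects = 1, seed = 8,
                          trials_per_class = c(NC = 10, LF = 20, TR = 20, SE = 20))
  expect_length(ds2, 70)
  labs <- vapply(ds2, function(el) el$recording$label, character(1))
  expect_identical(as.vector(table(labs)[c("NC", "LF", "TR", "SE")]),
                   c(10L, 20L, 20L, 20L))

  expect_identical(generate_dataset(cfg, 2, 2, seed = 9),
                   generate_dataset(cfg, 2, 2, seed = 9))
})

test_that("missing-sample fraction converges to the configured rate", {
  cfg <- sim_config(missing_rate = 0.05, trial_duration = 30)
  ds <- generate_dataset(cfg, n_subjects = 1, trials_per_class = 2, seed = 10)
  masks <- unlist(lapply(ds, function(el) el$recording$missing_mask))
  n <- length(masks)
  expect_gt(n, 1e4)
  p_hat <- mean(masks)
  # protected prefix slightly lowers the effective rate; 3 binomial SDs
  p_eff <- 0.05 * (480 - 4) / 480
  expect_lt(abs(p_hat - p_eff), 3 * sqrt(0.05 * 0.95 / n))
  # first four samples of every channel always present
  first4 <- unlist(lapply(ds, function(el)
    lapply(el$recording$missing_mask, function(m) m[1:4])))
  expect_false(any(first4))
})

test_that("plateau features separate classes more than within-class spread", {
  cfg <- sim_config()
  ds <- generate_dataset(cfg, n_subjects = 3, trials_per_class = 4, seed = 11)
  plateau <- 70:90
  feats <- t(vapply(ds, function(el) {
    unlist(lapply(el$recording$channels, function(ch) {
      s <- dbsi(pad_missing(el$recording$series[[ch]]$Hb),
                pad_missing(el$recording$series[[ch]]$HbO2))
      c(mean(s$series_a[plateau]), mean(s$series_b[plateau]))
    }))
  }, numeric(12)))
  labs <- vapply(ds, function(el) el$recording$label, character(1))
  centroids <- apply(feats, 2, tapply, labs, mean)
  between <- mean(dist(centroids))
  within <- mean(vapply(unique(labs), function(cl) {
    mean(sqrt(rowSums(sweep(feats[labs == cl, , drop = FALSE], 2,
                            centroids[cl, ])^2)))
  }, numeric(1)))
  expect_gt(between, within)
})
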