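test_that("event generation is deterministic and hits its target median", {
  a <- generate_events(median = 500, log_sd = 0.45, n = 5000, seed = 123)
  b <- generate_events(median = 500, log_sd = 0.45, n = 5000, seed = 123)
  expect_identical(a$yfp, b$yfp)
  expect_identical(a$fsc, b$fsc)

  # zero spread: every event equals the median
  z <- generate_events(median = 42, log_sd = 0, n = 100, seed = 1)
  expect_equal(z$yfp, rep(42, 100))

  # closed-form log-normal median at large n (no background)
  big <- generate_events(median = 500, log_sd = 0.45, n = 2e5, seed = 9)
  expect_equal(median(big$yfp), 500, tolerance = 0.005)

  expect_error(generate_events(500, 0.45, n = 0, seed = 1), "n must")
})

test_that("dataset generation is bit-identical for a given spec and seed", {
  spec <- synthetic_dataset_spec(device = "TES", n_events = 500,
                                 input_grid = c(0.01, 0.1, 1, 6.6),
                                 tuner_grid = c(0.03, 2.6), seed = 77)
  d1 <- generate_device_dataset(spec)
  d2 <- generate_device_dataset(spec)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(lapply(d1$samples, `[[`, "yfp"),
                   lapply(d2$samples, `[[`, "yfp"))
  expect_equal(length(d1$samples), 4 * 2 * 3)
  expect_length(d1$controls$autofluorescence, 3)
  expect_length(d1$controls$rpu_standard, 3)
})

test_that("noise-free large-n datasets reproduce model medians downstream", {
  spec <- synthetic_dataset_spec(device = "TES", n_events = 4e4,
                                 input_grid = c(0.05, 0.5, 2, 6.6),
                                 tuner_grid = c(0.43, 2.6),
                                 replicate_sd = 0, event_log_sd = 0.2,
                                 seed = 5)
  ds <- generate_device_dataset(spec)
  an <- analyze_dataset(ds, gate_bins = 128)
  cond <- ds$manifest$conditions
  for (i in seq_len(nrow(an$medians))) {
    row <- an$medians[i, ]
    truth <- cond$true_corrected_median_au[
      cond$input_rpu == row$input_activity_rpu &
        cond$tuner_rpu == row$tuner_activity_rpu &
        cond$replicate == row$replicate]
    expect_equal(row$median_yfp_au, truth, tolerance = 0.05)
  }
})

test_that("the booster design raises on-state medians at every tuner level", {
  grids <- list(input_grid = c(0.5, 2, 4, 6.6),
                tuner_grid = c(0.03, 0.43, 2.6))
  orig <- do.call(synthetic_dataset_spec,
                  c(list(device = "TES", design = "original", n_events = 1,
                         seed = 1), grids))
  boost <- do.call(synthetic_dataset_spec,
                   c(list(device = "TES", design = "booster", n_events = 1,
                          seed = 1), grids))
  co <- generate_device_dataset(orig)$manifest$conditions
  cb <- generate_device_dataset(boost)$manifest$conditions
  on_o <- co[co$input_rpu == 6.6 & co$replicate == 1, ]
  on_b <- cb[cb$input_rpu == 6.6 & cb$replicate == 1, ]
  expect_true(all(on_b$true_median_au >= on_o$true_median_au))
})

test_that("NOR datasets respect the truth-table corners and input symmetry", {
  spec <- synthetic_dataset_spec(device = "NOR", n_events = 1, replicates = 1,
                                 seed = 2)
  ds <- generate_nor_dataset(spec)
  cond <- ds$manifest$conditions
  lo_t <- cond[cond$tuner_rpu == min(cond$tuner_rpu), ]
  corner <- function(a, b) {
    lo_t$true_median_au[lo_t$input_rpu == a & lo_t$input_b_rpu == b]
  }
  a_rng <- range(lo_t$input_rpu)
  b_rng <- range(lo_t$input_b_rpu)
  # both inputs at grid minimum: the brightest cell of the whole grid
  expect_equal(corner(a_rng[1], b_rng[1]), max(lo_t$true_median_au))
  expect_gt(corner(a_rng[1], b_rng[1]), corner(a_rng[2], b_rng[1]))
  expect_gt(corner(a_rng[1], b_rng[1]), corner(a_rng[1], b_rng[2]))
  expect_gte(corner(a_rng[2], b_rng[1]), corner(a_rng[2], b_rng[2]))

  # swapping which promoter is A or B with symmetric grids transposes outputs
  sym <- synthetic_dataset_spec(device = "NOR", n_events = 1, replicates = 1,
                                input_grid = c(0.01, 0.1, 1, 3),
                                input_grid_b = c(0.01, 0.1, 1, 3),
                                tuner_grid = c(0.03, 2.6), seed = 2)
  cs <- generate_nor_dataset(sym)$manifest$conditions
  for (i in seq_len(nrow(cs))) {
    mirror <- cs$true_median_au[cs$input_rpu == cs$input_b_rpu[i] &
                                  cs$input_b_rpu == cs$input_rpu[i] &
                                  cs$tuner_rpu == cs$tuner_rpu[i] &
                                  cs$replicate == cs$replicate[i]]
    expect_equal(cs$true_median_au[i], mirror, tolerance = 1e-10)
  }
})

test_that("pipeline recovers manifest Hill parameters on a seeded dataset", {
  spec <- synthetic_dataset_spec(device = "TES", n_events = 1e4,
                                 replicate_sd = 0.05, seed = 11)
  ds <- generate_device_dataset(spec)
  an <- analyze_dataset(ds, gate_bins = 256)
  truth <- ds$manifest$hill_truth
  est <- vapply(an$fits, `[[`, numeric(1), "K")
  ok <- truth$reliable & vapply(an$fits, `[[`, logical(1), "reliable")
  expect_gte(sum(ok), 4)
  expect_true(all(abs(est[ok] / truth$K[ok] - 1) < 0.15))
  expect_lt(median(abs(est[ok] / truth$K[ok] - 1)), 0.10)
})
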