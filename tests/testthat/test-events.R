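test_that("a single programmed step is detected at the right size and force", {
  p <- fit_params(40, 1.4, 3.7)
  cyc <- make_eq1_cycle(p, steps = data.frame(force = 20, gain = 17))
  ev <- detect_events(cyc)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$phase, "extension")
  # the oracle is the ground-truth log: realized jump and event force
  expect_lt(abs(ev$size_nm - cyc$events$size_nm), 0.5)
  expect_lt(abs(ev$force_pN - 20), 1)
})

test_that("step-free traces yield no events, noisy or not", {
  p <- fit_params(63.8, 2.4, 2.5)
  expect_identical(nrow(detect_events(make_eq1_cycle(p))), 0L)
  set.seed(501)
  noisy <- make_eq1_cycle(p, noise_sd = 0.3)
  expect_identical(nrow(detect_events(noisy)), 0L)
  short <- make_cycle(c(1, 2, 1), c(1, 2, 1))
  expect_error(detect_events(short), "50")
})

test_that("two steps of different sizes are both recovered under noise", {
  p <- fit_params(40, 1.4, 3.7)
  set.seed(502)
  cyc <- make_eq1_cycle(p, steps = data.frame(force = c(12, 35),
                                              gain = c(5, 30)),
                        noise_sd = 0.3)
  ev <- detect_events(cyc)
  ev <- ev[ev$phase == "extension", ]
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$size_nm, cyc$events$size_nm, tolerance = 0.5 / 5)
  expect_lt(max(abs(ev$size_nm - cyc$events$size_nm)), 0.5)
})

test_that("segments tile each phase between events", {
  p <- fit_params(40, 1.4, 3.7)
  cyc <- make_eq1_cycle(p, steps = data.frame(force = c(15, 30),
                                              gain = c(6, 20)))
  ev <- detect_events(cyc)
  segs <- segment_cycle(cyc, ev)
  ext <- segs[segs$phase == "extension", ]
  expect_identical(nrow(ext), sum(ev$phase == "extension") + 1L)
  # tiling: spans cover the phase without overlap
  idx <- unlist(Map(seq, ext$start, ext$end))
  expect_identical(sort(idx), which(cyc$samples$phase == "extension"))
  rel <- segs[segs$phase == "relaxation", ]
  expect_identical(nrow(rel), sum(ev$phase == "relaxation") + 1L)
  # relaxation ordinals ascend with force, i.e. run backwards in time
  expect_identical(rel$ordinal[which.max(rel$end)], 1L)

  none <- segment_cycle(cyc, detect_events(make_eq1_cycle(p)))
  expect_identical(nrow(none[none$phase == "extension", ]), 1L)
  bad <- ev; bad$index <- nrow(cyc$samples) + 5L
  expect_error(segment_cycle(cyc, bad), "range")
})

test_that("per-cycle unfolding totals sum positive extension-phase steps", {
  ev <- data.frame(phase = c("extension", "extension", "relaxation"),
                   size_nm = c(4.5, 7.0, 3.0))
  expect_equal(total_unfolding_per_cycle(ev), 11.5)
  expect_equal(total_unfolding_per_cycle(ev[0, ]), 0)
  expect_equal(total_unfolding_per_cycle(ev, "relaxation"), 3.0)
  # order invariance and exclusion of refolding (negative) steps
  ev2 <- ev[c(2, 1, 3), ]; ev2$size_nm[1] <- -ev2$size_nm[1]
  expect_equal(total_unfolding_per_cycle(ev2), 4.5)
  # additivity over disjoint phases
  expect_equal(total_unfolding_per_cycle(ev) +
                 total_unfolding_per_cycle(ev, "relaxation"),
               sum(ev$size_nm))
})

test_that("detection recall and false positives meet the quality bar", {
  # Monte-Carlo over simulated cycles from two event-rich presets
  set.seed(503)
  n_match <- 0L; n_gt <- 0L; n_fp <- 0L; n_det <- 0L
  for (key in list(c("wild-type", "0 M EDTA"), c("V507D", "20 uM"))) {
    cfg <- condition_presets(key[1], key[2])
    ds <- simulate_dataset(cfg, 100)
    thr <- max(1.5, 3 * cfg$noise_sd)
    for (cyc in ds$cycles) {
      ev <- detect_events(cyc)
      gt <- cyc$events
      used <- rep(FALSE, nrow(ev))
      for (i in seq_len(nrow(gt))) {
        hit <- which(!used & ev$phase == gt$phase[i] &
                       abs(ev$index - gt$index[i]) <= 15)
        if (gt$size_nm[i] >= thr) {
          n_gt <- n_gt + 1L
          if (length(hit)) n_match <- n_match + 1L
        }
        if (length(hit)) used[hit[1]] <- TRUE
      }
      n_det <- n_det + nrow(ev)
      for (j in seq_len(nrow(ev))) {
        near <- any(gt$phase == ev$phase[j] & abs(gt$index - ev$index[j]) <= 15)
        if (!near) n_fp <- n_fp + 1L
      }
    }
  }
  expect_gt(n_gt, 200)
  expect_gte(n_match / n_gt, 0.95)
  expect_lte(n_fp / n_det, 0.05)
})

test_that("mixture decomposition recovers bimodal event-size classes", {
  set.seed(504)
  sizes <- c(rnorm(250, 2.0, 0.3), rnorm(250, 6.6, 0.5))
  g <- event_size_distribution(sizes, 2)
  expect_lt(abs(g$mean[1] - 2.0), 3 * g$sem[1])
  expect_lt(abs(g$mean[2] - 6.6), 3 * g$sem[2])
  expect_false(attr(g, "overlapping"))
  expect_equal(sum(g$weight), 1, tolerance = 1e-6)

  # degenerate inputs
  same <- event_size_distribution(rep(4.2, 30), 1)
  expect_equal(same$mean, 4.2)
  expect_equal(same$sem, 0)
  set.seed(505)
  over <- event_size_distribution(rnorm(200, 5, 0.5), 2)
  expect_true(attr(over, "overlapping"))
  expect_error(event_size_distribution(rnorm(15), 2), "at least")
})
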