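test_that("state definition recovers a six-level mixture", {
  true_means <- c(40, 52, 82, 112, 130, 202)
  set.seed(701)
  x <- rnorm(600, rep(true_means, each = 100), 3)
  m <- define_states(x, 6)
  expect_identical(m$n_states, 6L)
  expect_true(all(diff(m$means) > 0))
  for (s in 1:6) expect_lt(abs(m$means[s] - true_means[s]), 3 * m$sems[s])
  # gaps between recovered states match the generating gaps
  d <- state_differences(m)
  expect_equal(d$delta_nm, diff(true_means), tolerance = 0.15)

  # order invariance
  m2 <- define_states(sample(x), 6)
  expect_identical(m$means, m2$means)
  expect_identical(sort(m$reference$x_e), sort(m2$reference$x_e))

  expect_error(define_states(rep(5, 100), 6), "distinct")
  expect_error(define_states(rnorm(20), 6), "at least")
})

test_that("state differences propagate uncertainty in quadrature", {
  m <- structure(list(n_states = 2L, means = c(10, 22), sems = c(0.3, 0.4),
                      counts = c(5L, 5L),
                      reference = data.frame(x_e = c(10, 22),
                                             state = c(1L, 2L))),
                 class = "state_model")
  d <- state_differences(m)
  expect_equal(d$delta_nm, 12)
  expect_equal(d$sem_nm, 0.5)
})

test_that("kNN assignment equals exhaustive brute force", {
  set.seed(702)
  x <- rnorm(600, rep(c(40, 52, 82, 112, 130, 202), each = 100), 3)
  m <- define_states(x, 6)
  # a query equal to a reference point inherits that reference's state
  expect_identical(classify_segment(m, m$reference$x_e[7], k = 1),
                   m$reference$state[7])
  queries <- seq(30, 215, length.out = 1000)
  expect_identical(classify_segment(m, queries, k = 3),
                   as.integer(knn_oracle(m, queries, k = 3)))
  # random queries too, and at other k
  q2 <- runif(500, 20, 230)
  expect_identical(classify_segment(m, q2, k = 5),
                   as.integer(knn_oracle(m, q2, k = 5)))
  expect_error(classify_segment(m, 50, k = 0), "k")
  expect_error(classify_segment(list(), 50), "state_model")
})

test_that("vote ties break toward the lower state", {
  m <- structure(list(n_states = 2L, means = c(10, 20), sems = c(0, 0),
                      counts = c(2L, 2L),
                      reference = data.frame(x_e = c(10, 10, 20, 20),
                                             state = c(1L, 1L, 2L, 2L))),
                 class = "state_model")
  # 2-2 vote at k = 4: conservative lower state wins
  expect_identical(classify_segment(m, 15, k = 4), 1L)
})

test_that("transition maps count consecutive segments and conserve totals", {
  seg1 <- data.frame(cycle_uid = rep(sprintf("c%02d", 1:10), each = 2),
                     phase = "extension",
                     ordinal = rep(1:2, 10), state = 1L, n_samples = 50L)
  tm <- build_transition_map(seg1, n_states = 3)
  expect_identical(sum(tm$counts), 10L)
  expect_identical(tm$counts[1, 1], 10L)
  expect_equal(unname(tm$occupancy[1]), 1)

  # ladder 1 -> 2 -> 3 in every cycle
  seg2 <- data.frame(cycle_uid = rep(sprintf("c%02d", 1:7), each = 3),
                     phase = "extension", ordinal = rep(1:3, 7),
                     state = rep(1:3, 7), n_samples = 10L)
  tm2 <- build_transition_map(seg2, n_states = 3)
  expect_identical(tm2$counts[1, 2], 7L)
  expect_identical(tm2$counts[2, 3], 7L)
  expect_identical(sum(tm2$counts), nrow(seg2) - 7L)  # segments - cycles
  expect_equal(sum(tm2$occupancy), 1)

  bad <- seg2; bad$state[4] <- NA
  expect_error(build_transition_map(bad, n_states = 3), "nclassified")
})

test_that("state ordinals never decrease along the extension phase", {
  set.seed(703)
  pool <- list(condition_presets("V507D", "20 uM"),
               condition_presets("wild-type", "0 M EDTA"))
  fits_all <- NULL
  for (cfg in pool) {
    ds <- simulate_dataset(cfg, 15)
    k <- enthalpic_stiffness(ds$cycles)$value
    for (cyc in ds$cycles) {
      segs <- segment_cycle(cyc, detect_events(cyc))
      fits <- rampfold:::.fit_cycle_segments(cyc, segs, k)
      fits$cycle_uid <- paste(cfg$construct, cfg$calcium,
                              cyc$meta$cycle_index)
      fits_all <- rbind(fits_all, fits)
    }
  }
  m <- define_states(fits_all$x_e[fits_all$phase == "relaxation"], 4)
  fits_all$state <- classify_segment(m, fits_all$x_e)
  ext <- fits_all[fits_all$phase == "extension", ]
  ok <- vapply(split(ext, ext$cycle_uid), function(d) {
    d <- d[order(d$ordinal), ]
    all(diff(d$state) >= 0)
  }, logical(1))
  expect_gte(mean(ok), 0.97)  # unfolding only increases extension
})

test_that("refolding summaries recover a configured probability", {
  # Bernoulli refolding of a single domain observed through ground truth
  p <- fit_params(40, 2, 2.5)
  lad <- domain_ladder("dom", 30, k0 = 2e-3, dx_nm = 0.5, refold_p = 0.6)
  cfg <- simulation_config(p, lad, 0)
  set.seed(704)
  rows <- NULL
  for (d in 1:10) {
    ds <- simulate_dataset(cfg, 50, dataset_id = sprintf("d%02d", d))
    for (cyc in ds$cycles) {
      open_ever <- !cyc$start_folded[1] || nrow(cyc$events) > 0
      rows <- rbind(rows, data.frame(
        dataset = ds$meta$dataset_id, cycle = cyc$meta$cycle_index,
        first_state = if (cyc$start_folded[1]) 1L else 3L,
        max_state = if (open_ever) 3L else 1L))
    }
  }
  rs <- refolding_summary(rows)
  expect_gt(rs$n_qualifying, 200)
  se <- sqrt(0.6 * 0.4 / rs$n_qualifying)
  expect_lt(abs(rs$percent / 100 - 0.6), 2 * se)

  # all qualifying cycles refolded
  all_ref <- data.frame(dataset = "a", cycle = 1:4,
                        first_state = c(1L, 1L, 1L, 1L),
                        max_state = c(4L, 4L, 1L, 4L))
  expect_equal(refolding_summary(all_ref)$percent, 100)

  # never above state 2: undefined, not an error
  low <- data.frame(dataset = "a", cycle = 1:5, first_state = 1L,
                    max_state = 2L)
  und <- refolding_summary(low)
  expect_true(is.na(und$percent))
  expect_identical(und$n_datasets, 0L)
})

test_that("per-state stiffness follows the analytic force dependence", {
  # two states generated directly from the model, no noise
  mk <- function(x_e, uid) {
    f <- seq(0.5, 60, by = 0.01)
    p <- fit_params(x_e, 2.4, 2.5)
    data.frame(state = if (x_e > 60) 2L else 1L, segment_uid = uid,
               force_pN = f, extension_nm = extension_at_force(p, f))
  }
  samples <- rbind(mk(40, "a"), mk(100, "b"))
  st <- entropic_stiffness_by_state(samples, breaks = seq(0, 60, by = 5))
  s1 <- st[st$state == 1L, ]
  s2 <- st[st$state == 2L, ]
  # stiffness rises with force toward the enthalpic limit
  expect_true(all(diff(s1$stiffness) > 0))
  expect_true(all(diff(s2$stiffness) > 0))
  expect_lt(abs(s1$stiffness[nrow(s1)] - 2.5) / 2.5, 0.1)
  # the more extended state is softer at every force
  common <- intersect(s1$force_mid, s2$force_mid)
  expect_true(all(s2$stiffness[match(common, s2$force_mid)] <
                    s1$stiffness[match(common, s1$force_mid)]))
  # agreement with the analytic derivative dF/dx at bin centres
  p1 <- fit_params(40, 2.4, 2.5)
  analytic <- 1 / (p1$x_e * p1$f_half / (s1$force_mid + p1$f_half)^2 + 1 / p1$k)
  expect_equal(s1$stiffness, analytic, tolerance = 0.05)
})
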