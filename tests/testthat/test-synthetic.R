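test_that("condition presets are deterministic and validated", {
  a <- condition_presets("wild-type", "20 uM")
  b <- condition_presets("wild-type", "20 uM")
  expect_identical(a, b)
  expect_error(condition_presets("wild-type", "5 mM"), "calcium")
  expect_error(condition_presets("V528D", "3 mM"), "construct")
  # wild type at saturating calcium can never open a domain-scale unit
  wt3 <- condition_presets("wild-type", "3 mM")
  dom <- !(wt3$ladder$unit %in% c("linkerA", "linkerB"))
  expect_true(all(wt3$ladder$k0[dom] == 0))
  expect_true(all(wt3$ladder$gain_nm[!dom] < 10))
  # refolding ordering: EDTA preset refolds less than physiological calcium
  p20 <- condition_presets("wild-type", "20 uM")$ladder
  p0 <- condition_presets("wild-type", "0 M EDTA")$ladder
  expect_lt(p0$refold_p[p0$unit == "ec_dom1"],
            p20$refold_p[p20$unit == "ec_dom1"])
})

test_that("a kinetics-free molecule traces identical extension and relaxation", {
  p <- fit_params(40, 1.4, 3.7)
  lad <- domain_ladder("u", gain_nm = 17, k0 = 0, dx_nm = 0, refold_p = 1)
  cfg <- simulation_config(p, lad, noise_sd = 0)
  cyc <- simulate_cycle(cfg)
  expect_identical(nrow(cyc$events), 0L)
  s <- cyc$samples
  n <- nrow(s)
  up <- s$extension_nm[s$phase == "extension"]
  down <- s$extension_nm[s$phase == "relaxation"]
  # symmetric schedule: relaxation retraces the extension curve exactly
  expect_equal(down, rev(up[-length(up)]), tolerance = 1e-12)
})

test_that("ground truth logs record programmed gains and realized jumps", {
  p <- fit_params(40, 1.4, 3.7)
  lad <- domain_ladder("u", gain_nm = 17, k0 = 1e9, dx_nm = 0, refold_p = 1)
  cfg <- simulation_config(p, lad, noise_sd = 0)
  set.seed(301)
  cyc <- simulate_cycle(cfg)
  expect_identical(nrow(cyc$events), 1L)
  expect_identical(cyc$events$gain_nm, 17)
  f <- cyc$events$force_pN
  expect_equal(cyc$events$size_nm, 17 * f / (f + 1.4), tolerance = 1e-12)
  # the trace jumps by exactly the logged size at the logged sample
  i <- cyc$events$index
  if (i > 1) {
    trend <- extension_at_force(p, cyc$samples$force_pN[i]) -
      extension_at_force(p, cyc$samples$force_pN[i - 1])
    jump <- cyc$samples$extension_nm[i] - cyc$samples$extension_nm[i - 1]
    expect_equal(jump - trend, cyc$events$size_nm, tolerance = 1e-9)
  }
})

test_that("the same seed reproduces a cycle bit for bit", {
  cfg <- condition_presets("V507D", "0 M EDTA")
  set.seed(42); a <- simulate_cycle(cfg)
  set.seed(42); b <- simulate_cycle(cfg)
  expect_identical(a, b)
  set.seed(42); da <- simulate_dataset(cfg, 5)
  set.seed(42); db <- simulate_dataset(cfg, 5)
  expect_identical(da, db)
})

test_that("inter-cycle refolding controls the carried fold state", {
  p <- fit_params(40, 2, 2.5)
  # certain refolding: every cycle starts fully folded
  lad1 <- domain_ladder("u", 30, k0 = 0.05, dx_nm = 0.3, refold_p = 1)
  ds <- simulate_dataset(simulation_config(p, lad1, 0), 20, seed = 302)
  expect_true(all(vapply(ds$cycles, function(c) all(c$start_folded),
                         logical(1))))
  # irreversible single unfolder: at most one event in the whole dataset
  lad0 <- domain_ladder("u", 30, k0 = 0.05, dx_nm = 0.3, refold_p = 0)
  ds0 <- simulate_dataset(simulation_config(p, lad0, 0), 40, seed = 303)
  expect_lte(sum(vapply(ds0$cycles, function(c) nrow(c$events), integer(1))),
             1L)
})

test_that("EDTA-destabilized mutant molecules start later cycles extended", {
  cfg <- condition_presets("V507D", "0 M EDTA")
  ds <- simulate_dataset(cfg, 60, seed = 304)
  open_at_start <- vapply(ds$cycles, function(c) sum(!c$start_folded),
                          numeric(1))
  expect_identical(open_at_start[1], 0)
  expect_gt(mean(open_at_start[31:60]), 0.5)
  # baseline extension near the resting force grows accordingly
  base <- vapply(ds$cycles, function(c) c$samples$extension_nm[1], numeric(1))
  expect_gt(mean(base[31:60]), mean(base[1:5]))
})

test_that("mean unfolding force rises with loading rate (Bell-Evans)", {
  p <- fit_params(40, 2, 2.5)
  mean_force <- vapply(c(5, 40), function(r) {
    lad <- domain_ladder("d", 30, k0 = 0.05, dx_nm = 0.5, refold_p = 1)
    cfg <- simulation_config(p, lad, 0,
                             protocol = ramp_protocol(peak_force = 80,
                                                      loading_rate = r))
    set.seed(305)
    f <- replicate(500, {
      cyc <- simulate_cycle(cfg)
      if (nrow(cyc$events)) cyc$events$force_pN[1] else NA_real_
    })
    mean(f, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean_force[2], mean_force[1] + 3)
})

test_that("unfolding activity ranks with calcium and the mutation", {
  # ground-truth event totals over repeated simulations
  counts <- matrix(0, 2, 3,
                   dimnames = list(c("wild-type", "V507D"),
                                   c("3 mM", "20 uM", "0 M EDTA")))
  set.seed(306)
  for (rep in 1:20) {
    for (cons in rownames(counts)) for (ca in colnames(counts)) {
      ds <- simulate_dataset(condition_presets(cons, ca), 8)
      counts[cons, ca] <- counts[cons, ca] +
        sum(vapply(ds$cycles, function(c) nrow(c$events), integer(1)))
    }
  }
  # events increase as calcium decreases, for both constructs
  expect_true(all(diff(counts["wild-type", ]) > 0))
  expect_true(all(diff(counts["V507D", ]) > 0))
  # the mutant unfolds more than wild type at every calcium level
  expect_true(all(counts["V507D", ] > counts["wild-type", ]))
})

test_that("relaxation-phase unfolding is rarer than extension-phase unfolding", {
  set.seed(307)
  for (key in list(c("wild-type", "0 M EDTA"), c("V507D", "20 uM"))) {
    ds <- simulate_dataset(condition_presets(key[1], key[2]), 50)
    gt <- do.call(rbind, lapply(ds$cycles, function(c) c$events))
    expect_gt(sum(gt$phase == "extension"), sum(gt$phase == "relaxation"))
  }
})

test_that("domain ladders validate their invariants", {
  expect_error(domain_ladder("a", -1, 0.1, 0.5, 1), "positive")
  expect_error(domain_ladder("a", 5, 0.1, 0.5, 1.4), "refold_p")
  expect_error(domain_ladder(c("a", "b"), 5, 0.1, 0.5, 1,
                             requires = c("b", NA)), "earlier unit")
  expect_error(ramp_protocol(resting_force = 60, peak_force = 10), "below")
  cfg <- condition_presets("wild-type", "3 mM")
  expect_error(simulate_cycle(cfg, folded = c(TRUE, FALSE)), "ladder unit")
})
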