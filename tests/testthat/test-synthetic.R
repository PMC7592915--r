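test_that("birth-death trees: size, ultrametricity, unit height, seeding", {
  tr <- simulate_tree(50, seed = 13)
  expect_equal(ape::Ntip(tr), 50)
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-12)
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_tree(50, seed = 13)))
  expect_false(identical(ape::write.tree(tr),
                         ape::write.tree(simulate_tree(50, seed = 14))))
  expect_error(simulate_tree(2, seed = 1), "at least 3")
  expect_error(simulate_tree(10, birth = 0.5, death = 0.7, seed = 1),
               "birth > death")
})

test_that("Brownian evolution of ln E matches its closed-form variance", {
  tr <- simulate_tree(30, seed = 23)
  sc <- evolution_scenario("BM")
  # across replicates, a given tip's ln E varies with variance rate * depth
  tip1 <- vapply(1:400, function(r)
    evolve_parameters(tr, sc, seed = r)$tips$ln_e[1], numeric(1))
  expect_equal(var(tip1), unname(sc$rates["ln_e"]), tolerance = 0.25 * 0.2)
  expect_equal(mean(tip1), unname(sc$roots["ln_e"]), tolerance = 0.1)
  # constraints hold everywhere
  ev <- evolve_parameters(tr, sc, seed = 5)
  expect_true(all(ev$tips$e < ev$tips$e_d))
  expect_true(all(ev$tips$t_pk > t_ref_default))
})

test_that("a simulated trend is recovered from the true node states", {
  tr <- simulate_tree(50, seed = 7)
  sc <- evolution_scenario("BM+trend", trend = -0.5)
  slopes <- vapply(1:30, function(r) {
    ev <- evolve_parameters(tr, sc, seed = r)
    trend_regression(tr, setNames(ev$tips$ln_e, ev$tips$species_id),
                     node_states = setNames(ev$nodes$ln_e,
                                            ev$nodes$node))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 0.5), 0.05)
})

test_that("jumps fatten the tails of the tip distribution", {
  kurt <- function(v) mean((v - mean(v))^4) / var(v)^2 - 3
  tr <- simulate_tree(100, seed = 2)
  k_bm <- vapply(1:20, function(r)
    kurt(evolve_parameters(tr, evolution_scenario("BM"),
                           seed = r)$tips$ln_e), numeric(1))
  k_j <- vapply(1:20, function(r)
    kurt(evolve_parameters(tr, evolution_scenario("BM+jumps"),
                           seed = r)$tips$ln_e), numeric(1))
  expect_gt(median(k_j), 0)
  expect_gt(median(k_j), median(k_bm))
})

test_that("measurement generation: determinism, noiseless round-trip, flags", {
  tr <- simulate_tree(10, seed = 33)
  ev <- evolve_parameters(tr, evolution_scenario("BM"), seed = 34)
  des <- measurement_design(seq(2, 46, by = 4), noise_sd = 0.05, seed = 35)
  m1 <- generate_measurements(ev$tips, des)
  m2 <- generate_measurements(ev$tips, des)
  expect_identical(m1, m2)
  # zero noise: fitting returns the generating parameters
  des0 <- measurement_design(seq(2, 46, by = 4), noise_sd = 0, seed = 1)
  m0 <- generate_measurements(ev$tips[1, ], des0)
  cv <- tpc_curve(m0$curve_id[1], m0$species_id[1], m0$temperature_C,
                  m0$trait_value, unit = "C")
  f <- fit_sharpe_schoolfield(cv)
  expect_lt(abs(f$params$e - ev$tips$e[1]) / ev$tips$e[1], 1e-3)
  expect_lt(abs(f$params$t_pk - ev$tips$t_pk[1]), 0.01)
  # a rise-deficient design is flagged and rejected downstream
  tip_hot <- data.frame(species_id = "hot", b0 = 0.5, e = 0.65,
                        t_pk = celsius_to_kelvin(20), e_d = 3)
  des_def <- measurement_design(c(12, 16, 19, 22, 25, 28, 31),
                                noise_sd = 0, seed = 1)
  md <- generate_measurements(tip_hot, des_def)
  expect_true("hot" %in% attr(md, "deficient"))
  cvd <- tpc_curve(md$curve_id[1], "hot", md$temperature_C,
                   md$trait_value, unit = "C")
  fd <- suppressWarnings(fit_sharpe_schoolfield(cvd))
  expect_false(fd$qc[["e"]])
})

test_that("latitudes: null independence, linkage, determinism", {
  lnE <- setNames(rnorm(80, log(0.65), 0.4), paste0("s", 1:80))
  l1 <- assign_latitudes(lnE, slope = 0, seed = 3)
  expect_identical(l1, assign_latitudes(lnE, slope = 0, seed = 3))
  cors <- vapply(1:20, function(r) {
    set.seed(1000 + r)
    z <- setNames(rnorm(80, log(0.65), 0.4), paste0("s", 1:80))
    cor(z, abs(assign_latitudes(z, slope = 0, seed = r)))
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.15)
  # a noiseless inversion reproduces the linear model where not truncated
  l2 <- suppressMessages(assign_latitudes(lnE, slope = -0.01,
                                          intercept = log(0.65),
                                          noise_sd = 0, seed = 4))
  inside <- abs(l2) > 1e-9 & abs(l2) < 66 - 1e-9
  expect_equal(unname(lnE[inside]),
               unname(log(0.65) - 0.01 * abs(l2[inside])),
               tolerance = 1e-10)
  expect_true(all(abs(l2) <= 66))
})
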