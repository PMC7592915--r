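test_that("noiseless curves are recovered essentially exactly", {
  cv <- make_curve("rt", c(5, 9, 13, 17, 21, 25, 29, 31, 35, 38, 41, 44),
                   b0 = 0.3, e = 0.8, t_pk = 303.15, e_d = 3.5)
  f <- fit_sharpe_schoolfield(cv)
  expect_true(f$converged)
  expect_lt(abs(f$params$e - 0.8) / 0.8, 0.01)
  expect_lt(abs(f$params$t_pk - 303.15), 0.1)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  # multi-start is deterministic: refitting reproduces the optimum exactly
  f2 <- fit_sharpe_schoolfield(cv)
  expect_identical(unclass(f$params), unclass(f2$params))
})

test_that("r_squared follows its definition", {
  obs <- c(1, 2, 3, 5)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  # hand-computed: SSE = 0.10, SST = 8.75
  expect_equal(r_squared(obs, c(1.1, 1.9, 3.2, 4.8)), 1 - 0.10 / 8.75,
               tolerance = 1e-12)
  expect_warning(r2 <- r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_true(is.na(r2))
})

test_that("quality filters reproduce the per-parameter rules on the fixture", {
  fx <- filter_fixture()
  fits <- lapply(fx, function(cv) suppressWarnings(fit_sharpe_schoolfield(cv)))
  flag <- function(nm) fits[[nm]]$qc
  expect_equal(flag("all_ok"),
               c(b0 = TRUE, e = TRUE, w_op = TRUE, t_pk = TRUE,
                 b_pk = TRUE, e_d = TRUE))
  # 3 points below the peak: rise-side quantities rejected
  expect_equal(flag("few_below"),
               c(b0 = FALSE, e = FALSE, w_op = FALSE, t_pk = TRUE,
                 b_pk = TRUE, e_d = TRUE))
  # steep rise above the 4 eV cap; only 2 points after the peak
  expect_equal(flag("high_e"),
               c(b0 = TRUE, e = FALSE, w_op = TRUE, t_pk = TRUE,
                 b_pk = TRUE, e_d = FALSE))
  # a single point after the peak: fall-side quantities rejected
  expect_equal(flag("one_above"),
               c(b0 = TRUE, e = TRUE, w_op = FALSE, t_pk = FALSE,
                 b_pk = FALSE, e_d = FALSE))
  # a single point before the peak
  expect_equal(flag("one_below"),
               c(b0 = FALSE, e = FALSE, w_op = FALSE, t_pk = FALSE,
                 b_pk = FALSE, e_d = TRUE))
  # the R-squared gate rejects everything
  expect_lt(fits[["low_r2"]]$r_squared, 0.5)
  expect_false(any(flag("low_r2")))
  # filters are pure: reapplication gives identical flags
  expect_identical(apply_quality_filters(fits[["all_ok"]]),
                   fits[["all_ok"]]$qc)
})

test_that("tiny curves are fitted but never accepted", {
  cv <- tpc_curve("tiny", "sp_t", celsius_to_kelvin(c(10, 20, 30)),
                  c(0.2, 0.5, 1.1))
  f <- suppressWarnings(fit_sharpe_schoolfield(cv))
  expect_false(any(f$qc))
})

test_that("standard errors behave: zero at zero noise, seeded, shrink with n", {
  cv0 <- make_curve("se0", seq(5, 44, by = 3), b0 = 0.3, e = 0.8,
                    t_pk = 303.15, e_d = 3.5)
  f0 <- fit_sharpe_schoolfield(cv0)
  se0 <- estimate_uncertainty(f0, cv0, n_boot = 20, seed = 1)
  expect_true(all(se0 < 1e-6))

  grid8 <- seq(8, 43, by = 5)
  grid32 <- seq(6.5, 45.25, by = 1.25)
  cv8 <- make_curve("n8", grid8, noise_sd = 0.05, seed = 31)
  cv32 <- make_curve("n32", grid32, noise_sd = 0.05, seed = 31)
  f8 <- suppressWarnings(fit_sharpe_schoolfield(cv8))
  f32 <- suppressWarnings(fit_sharpe_schoolfield(cv32))
  se8 <- estimate_uncertainty(f8, cv8, n_boot = 0)
  se32 <- estimate_uncertainty(f32, cv32, n_boot = 0)
  expect_lt(se32["ln_e"], se8["ln_e"])

  seA <- estimate_uncertainty(f8, cv8, n_boot = 30, seed = 9)
  seB <- estimate_uncertainty(f8, cv8, n_boot = 30, seed = 9)
  expect_identical(seA, seB)
})

test_that("transformed trait rows honour the acceptance flags", {
  cv <- make_curve("tr", c(13, 17, 21, 25, 29, 31, 35, 38, 41, 44), e = 1)
  f <- fit_sharpe_schoolfield(cv)
  rows <- transform_parameters(f)
  expect_setequal(rows$variable,
                  c("ln_b0", "ln_e", "ln_w_op", "t_pk", "ln_b_pk",
                    "ln_e_d"))
  expect_equal(rows$value[rows$variable == "ln_e"], 0, tolerance = 1e-6)
  expect_equal(exp(rows$value[rows$variable == "ln_e"]), f$params$e,
               tolerance = 1e-12)
  # reject the E flag: its row disappears
  f$qc["e"] <- FALSE
  rows2 <- transform_parameters(f)
  expect_false("ln_e" %in% rows2$variable)
})

test_that("best fit per species: highest R2, then more points, then id", {
  mk <- function(id, sp, r2, np) {
    structure(list(curve_id = id, species_id = sp, trait_name = "r_max",
                   latitude = NA_real_, n_points = np, converged = TRUE,
                   r_squared = r2), class = "tpc_fit")
  }
  fits <- list(mk("a", "sp1", 0.6, 10), mk("b", "sp1", 0.9, 8),
               mk("c", "sp2", 0.7, 8), mk("d", "sp2", 0.7, 12),
               mk("e", "sp3", 0.8, 6))
  best <- best_fit_per_species(fits)
  expect_equal(best[["sp1"]]$curve_id, "b")   # higher R2
  expect_equal(best[["sp2"]]$curve_id, "d")   # tie -> more points
  expect_equal(best[["sp3"]]$curve_id, "e")   # single fit -> itself
})
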