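test_that("equilibrium solver handles the limiting regimes exactly", {
  # no protein: all probe free
  f <- solve_equilibrium(binding_params(2.4, 1), 0, 1)
  expect_equal(as.numeric(f), c(1, 0, 0))

  # p = k with negligible DNA and omega = 1: independent sites, weights 1:2:1
  f <- solve_equilibrium(binding_params(10, 1), 10, 1e-9)
  expect_equal(as.numeric(f), c(0.25, 0.5, 0.25), tolerance = 1e-6)
})

test_that("equilibrium solver matches the bisection oracle under depletion", {
  f <- solve_equilibrium(binding_params(5, 50), 400, 100)
  expect_equal(as.numeric(f), oracle_equilibrium(5, 50, 400, 100),
               tolerance = 1e-8)

  set.seed(101)
  for (i in 1:100) {
    k <- runif(1, 0.5, 3000)
    omega <- exp(runif(1, log(0.2), log(200)))
    p <- runif(1, 0.1, 3000)
    d <- runif(1, 0.5, 300)
    f <- solve_equilibrium(binding_params(k, omega), p, d)
    expect_equal(as.numeric(f), oracle_equilibrium(k, omega, p, d),
                 tolerance = 1e-8)
  }
})

test_that("mass conservation holds for arbitrary valid inputs", {
  set.seed(7)
  for (i in 1:50) {
    k <- runif(1, 0.5, 2000); omega <- exp(runif(1, log(0.1), log(300)))
    p <- runif(1, 0, 2000); d <- runif(1, 0.5, 500)
    f <- solve_equilibrium(binding_params(k, omega), p, d)
    p_free <- attr(f, "p_free")
    expect_lt(abs(p_free + d * (f[["f_mono"]] + 2 * f[["f_dim"]]) - p),
              1e-8 * max(1, p))
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }
})

test_that("omega estimator inverts the forward model at any concentration", {
  # non-cooperative weights 1:2:1 score exactly omega = 1
  expect_equal(estimate_omega(c(0.25, 0.5, 0.25)), 1.0)
  # dropping the statistical factor divides by 4
  expect_equal(estimate_omega(c(0.25, 0.5, 0.25), statistical_factor = 1), 0.25)

  set.seed(11)
  for (i in 1:50) {
    omega <- exp(runif(1, log(0.2), log(300)))
    k <- runif(1, 1, 2000)
    p <- runif(1, 0.5, 3000)
    d <- runif(1, 0.5, 400)
    f <- solve_equilibrium(binding_params(k, omega), p, d)
    expect_equal(estimate_omega(f), omega, tolerance = 1e-6)
  }
})

test_that("omega estimator distinguishes all-dimer from all-free degeneracy", {
  expect_error(estimate_omega(c(0, 0, 1)), "fully dimer-bound")
  expect_error(estimate_omega(c(1, 0, 0)), "essentially free")
})

test_that("dimer fraction grows with omega and free probe shrinks with protein", {
  omegas <- c(0.5, 1, 5, 50, 200)
  fd <- vapply(omegas, function(w)
    solve_equilibrium(binding_params(100, w), 300, 100)[["f_dim"]], numeric(1))
  expect_true(all(diff(fd) > 0))

  ps <- c(10, 50, 200, 800, 2500)
  ff <- vapply(ps, function(p)
    solve_equilibrium(binding_params(100, 5), p, 100)[["f_free"]], numeric(1))
  expect_true(all(diff(ff) < 0))
})

test_that("titration simulation is deterministic and noise-calibrated", {
  bp <- binding_params(2250, 56.3)
  exact <- simulate_titration(bp, c(100, 400, 1600), 100, noise_sd = 0)
  for (i in seq_len(nrow(exact))) {
    f <- solve_equilibrium(bp, exact$p_total_nM[i], 100)
    expect_equal(c(exact$f_free[i], exact$f_mono[i], exact$f_dim[i]),
                 as.numeric(f), tolerance = 1e-12)
  }

  a <- simulate_titration(bp, rep(400, 20), 100, noise_sd = 0.02, seed = 5)
  b <- simulate_titration(bp, rep(400, 20), 100, noise_sd = 0.02, seed = 5)
  expect_identical(a, b)

  # empirical residual SD per fraction: renormalization projects the three
  # independent errors onto the simplex, giving sd 0.02 * sqrt(2/3); check
  # the observed value stays within 20% of the nominal 0.02
  big <- simulate_titration(bp, rep(400, 1000), 100, noise_sd = 0.02, seed = 9)
  f0 <- as.numeric(solve_equilibrium(bp, 400, 100))
  for (j in 1:3) {
    resid_sd <- sd(big[[c("f_free", "f_mono", "f_dim")[j]]] - f0[j])
    expect_gt(resid_sd, 0.8 * 0.02 * sqrt(2 / 3))
    expect_lt(resid_sd, 1.2 * 0.02)
  }

  expect_error(simulate_titration(bp, c(-1, 10), 100), "non-negative")
})

test_that("isotherm fit recovers K exactly from noiseless data", {
  P <- c(2500 / 2^(0:12), 0)
  bound <- depletion_isotherm(P, 1, 2.4)
  series <- data.frame(probe_id = "m", replicate = 1L, p_total_nM = P,
                       d_total_nM = 1, f_free = 1 - bound, f_mono = bound,
                       f_dim = 0)
  fit <- fit_kd_single_site(series, "monomer-band")
  expect_equal(fit$estimate, 2.4, tolerance = 1e-6)
})

test_that("isotherm fit rejects non-identifiable series", {
  P <- c(500, 1000, 2000, 4000)
  all_bound <- data.frame(probe_id = "x", replicate = 1L, p_total_nM = P,
                          d_total_nM = 1, f_free = 0.01, f_mono = 0.99,
                          f_dim = 0)
  expect_error(fit_kd_single_site(all_bound, "monomer-band"),
               "non-identifiable")
  all_free <- within(all_bound, { f_free <- 0.99; f_mono <- 0.01 })
  expect_error(fit_kd_single_site(all_free, "monomer-band"),
               "non-identifiable")
  expect_error(fit_kd_single_site(all_bound[1:3, ], "monomer-band"),
               "at least 4")
})

test_that("noisy replicate protocols recover the planted parameters with small bias", {
  # omega at the two cooperativity regimes: relative bias < 15%
  for (preset in c("div", "con")) {
    truth <- titration_presets()[[preset]]$params$omega
    set.seed(202)
    est <- replicate(200, {
      tt <- make_titrations(preset, seed = sample.int(1e7, 1))
      mean(vapply(split(tt, tt$replicate), estimate_omega_series, numeric(1)))
    })
    expect_lt(abs(mean(est) - truth) / truth, 0.15)
  }

  # dissociation constants: relative bias < 10%
  for (preset in c("monomer", "kd_apparent")) {
    truth <- titration_presets()[[preset]]$params$k_half
    bound_def <- if (preset == "monomer") "monomer-band" else "monomer-plus-dimer"
    set.seed(303)
    est <- replicate(60, {
      tt <- make_titrations(preset, seed = sample.int(1e7, 1))
      mean(vapply(split(tt, tt$replicate), function(s)
        fit_kd_single_site(s, bound_def)$estimate, numeric(1)))
    })
    expect_lt(abs(mean(est) - truth) / truth, 0.10)
  }
})

test_that("derived quantities follow their closed forms", {
  expect_equal(derive_kd_dimer(2.4, 1), 2.4)
  expect_equal(derive_kd_dimer(2.4, 56.3), 2.4 / 56.3)
  # negative cooperativity increases the dimer dissociation constant
  expect_equal(derive_kd_dimer(10, 0.5), 20)
  expect_error(derive_kd_dimer(-1, 2), "positive")

  s <- summarize_replicates(c(2, 4))
  expect_equal(s$estimate, 3)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(summarize_replicates(c(1, 1, 1))$sd, 0)
  one <- summarize_replicates(56.3)
  expect_equal(one$estimate, 56.3)
  expect_equal(one$sd, 0)
  expect_equal(one$n, 1L)

  expect_equal(reporter_score(100, 0.5), 50)
  expect_equal(reporter_score(123, 0), 0)
  expect_equal(reporter_score(37.2, 0.81), 30.132)
  expect_error(reporter_score(10, 1.2), "\\[0, 1\\]")
})

test_that("titration tables round-trip through TSV", {
  tt <- make_titrations("con", seed = 3, n_replicates = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_titrations(tt, path)
  back <- read_titrations(path)
  expect_equal(back$f_mono, tt$f_mono, tolerance = 1e-12)
  expect_equal(back$probe_id, tt$probe_id)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("probe_id\treplicate\tp_total_nM", bad)
  expect_error(read_titrations(bad), "lacks columns")
})
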