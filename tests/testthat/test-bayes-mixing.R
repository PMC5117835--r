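sym_sources <- data.frame(
  name = c("a", "b"),
  d13c_mean = c(-60, -40), d13c_sd = c(1, 1),
  d14c_mean = c(-200, 0), d14c_sd = c(5, 5))
no_tef <- trophic_enrichment(0, 0, 0, 0)

test_that("dependence-weighted OM radiocarbon averages correctly", {
  x <- c(-30, -10, 10, -50)
  plain <- weighted_om_d14c(x, rep(0, 4))
  expect_equal(plain$mean, mean(x))
  expect_equal(plain$sd, stats::sd(x) * sqrt(3 / 4))  # frequency convention
  one <- weighted_om_d14c(-20, 0.3)
  expect_equal(one$mean, -20); expect_equal(one$sd, 0)
  # weight 1 - f: an individual with f = 1 contributes nothing
  r <- weighted_om_d14c(c(0, -100), c(0.5, 1.0))
  expect_equal(r$mean, 0)
  # out-of-range f capped into [0, 1] weights
  r2 <- weighted_om_d14c(c(0, -100), c(-0.5, 2))
  expect_equal(r2$mean, 0)
  expect_error(weighted_om_d14c(c(1, 2), c(1, 1)), "zero")
})

test_that("the four scenarios carry the printed source values", {
  sc <- build_scenarios()
  expect_named(sc, c("Avg-Aged", "Avg-Anc", "Cons-Aged", "Cons-Anc"))
  aa <- sc[["Avg-Aged"]]$sources
  aged <- aa[aa$name == "methane_aged", ]
  expect_equal(aged$d14c_mean, -580); expect_equal(aged$d14c_sd, 7.2)
  expect_equal(aged$d13c_mean, -68.79); expect_equal(aged$d13c_sd, 8.52)
  anc <- sc[["Avg-Anc"]]$sources
  expect_equal(anc$d14c_mean[anc$name == "methane_ancient"], -1000)
  ca <- sc[["Cons-Aged"]]$sources
  expect_equal(ca$d13c_mean[ca$name == "methane_aged"], -100.86)
  # modern methane follows its scenario's OM radiocarbon estimate
  expect_equal(aa$d14c_mean[aa$name == "methane_modern"], -13.7)
  expect_equal(ca$d14c_mean[ca$name == "methane_modern"], -65.6)
  sc2 <- build_scenarios(modern_follows = "avg")
  ca2 <- sc2[["Cons-Aged"]]$sources
  expect_equal(ca2$d14c_mean[ca2$name == "methane_modern"], -13.7)
  om <- aa[aa$name == "organic_matter", ]
  expect_equal(om$d13c_mean, -27.83); expect_equal(om$d13c_sd, 2.49)
})

test_that("symmetric sources around the data yield a half-half posterior", {
  x <- data.frame(d13c = rep(-50, 12), d14c = rep(-100, 12))
  fit <- mix_fit(x, scenario = sym_sources, tef = no_tef,
                 n_iter = 4000, burn_in = 500, seed = 5)
  expect_equal(unname(coef(fit)[1, ]), c(0.5, 0.5), tolerance = 0.05)
})

test_that("data at one source's mean pins the posterior on that source", {
  sep <- data.frame(
    name = c("near", "far1", "far2"),
    d13c_mean = c(-60, -20, -100), d13c_sd = c(1, 1, 1),
    d14c_mean = c(-500, 0, 0), d14c_sd = c(5, 5, 5))
  set.seed(6)
  x <- data.frame(d13c = stats::rnorm(15, -60, 1),
                  d14c = stats::rnorm(15, -500, 5))
  fit <- mix_fit(x, scenario = sep, tef = no_tef,
                 n_iter = 4000, burn_in = 500, seed = 6)
  expect_gte(coef(fit)[1, "near"], 0.90)
})

test_that("every retained draw lies exactly on the simplex", {
  x <- data.frame(d13c = c(-45, -52, -40), d14c = c(-150, -300, -80))
  fit <- mix_fit(x, scenario = build_scenarios()[["Avg-Anc"]],
                 n_iter = 1500, burn_in = 300, seed = 8)
  d <- fit$draws[[1]]
  expect_true(all(abs(rowSums(d) - 1) < 1e-12))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("identical seeds give identical draws and summaries", {
  x <- data.frame(d13c = c(-45, -52, -40, -60), d14c = c(-150, -300, -80, -400))
  g <- c("w1", "w1", "w2", "w2")
  sc <- build_scenarios()[["Avg-Aged"]]
  f1 <- mix_fit(x, g, sc, n_iter = 1200, burn_in = 200, seed = 99)
  f2 <- mix_fit(x, g, sc, n_iter = 1200, burn_in = 200, seed = 99)
  expect_identical(f1$draws, f2$draws)
  expect_identical(summary(f1), summary(f2))
})

test_that("prior-only runs recover the uniform-simplex mean", {
  x <- data.frame(d13c = -50, d14c = -100)
  fit <- mix_fit(x, scenario = build_scenarios()[["Avg-Aged"]],
                 n_iter = 11000, burn_in = 1000, seed = 10,
                 prior_only = TRUE)
  expect_equal(unname(coef(fit)[1, ]), rep(1 / 3, 3), tolerance = 0.03)
})

test_that("source order in the input never affects results", {
  x <- data.frame(d13c = c(-45, -52, -40), d14c = c(-150, -300, -80))
  sc <- build_scenarios()[["Avg-Aged"]]
  perm <- sc
  perm$sources <- perm$sources[c(3, 1, 2), ]
  f1 <- mix_fit(x, scenario = sc, n_iter = 1200, burn_in = 200, seed = 12)
  f2 <- mix_fit(x, scenario = perm, n_iter = 1200, burn_in = 200, seed = 12)
  expect_identical(summary(f1), summary(f2))
})

test_that("pulling a lone individual toward -1000 permil raises the
           ancient-methane share monotonically", {
  sc <- build_scenarios()[["Avg-Anc"]]
  means <- vapply(c(-100, -500, -900), function(d14) {
    fit <- mix_fit(data.frame(d13c = -55, d14c = d14), scenario = sc,
                   n_iter = 4000, burn_in = 500, seed = 13)
    coef(fit)[1, "methane_ancient"]
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("posterior summaries expose intervals and diagnostics", {
  x <- data.frame(d13c = c(-45, -52, -40), d14c = c(-150, -300, -80))
  fit <- mix_fit(x, scenario = build_scenarios()[["Avg-Aged"]],
                 n_iter = 1500, burn_in = 300, seed = 14)
  s <- summary(fit)
  expect_setequal(names(s)[1:7],
                  c("group", "source", "mean", "sd", "q_lo", "q_hi", "ess"))
  expect_true(all(s$q_lo <= s$mean & s$mean <= s$q_hi))
  expect_true(all(s$ess > 0))
  # per group, posterior means close on the simplex
  expect_equal(sum(s$mean), 1, tolerance = 0.02)
  short <- mix_fit(x, scenario = build_scenarios()[["Avg-Aged"]],
                   n_iter = 120, burn_in = 60, seed = 14)
  expect_error(summary(short), "too few")
})

test_that("simulate and residuals methods reflect the fitted model", {
  set.seed(15)
  x <- data.frame(d13c = stats::rnorm(20, -45, 3),
                  d14c = stats::rnorm(20, -150, 30))
  fit <- mix_fit(x, scenario = build_scenarios()[["Avg-Aged"]],
                 n_iter = 1500, burn_in = 300, seed = 15)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_equal(dim(sims[[1]]), dim(fit$data))
  r <- residuals(fit)
  expect_equal(dim(r), dim(fit$data))
  # fitted means sit inside the observed tracer range for centred data
  expect_lt(abs(mean(r[, "d13c"])), 5)
})

test_that("degenerate inputs error cleanly", {
  sc <- build_scenarios()[["Avg-Aged"]]
  expect_error(mix_fit(data.frame(d13c = numeric(0), d14c = numeric(0)),
                       scenario = sc), "no observations")
  expect_error(mix_fit(data.frame(d13c = NA_real_, d14c = 1), scenario = sc),
               "non-finite")
  expect_error(mix_fit(data.frame(x = 1), scenario = sc), "d13c")
})
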