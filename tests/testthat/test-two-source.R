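test_that("two-endmember inversion matches hand-checked mixtures", {
  # the thermogenic bound on the oldest methane sample: -70.6 between
  # -50 (thermogenic) and -100 (microbial) -> 58.8% microbial, 59% rounded
  # thermogenic when roles are exchanged
  f_microbial <- solve_two_endmember(-70.6, -100, -50)
  expect_equal(round(100 * (1 - f_microbial)), 59)
  expect_equal(solve_two_endmember(-27.83, -68.79, -27.83), 0)
  expect_equal(solve_two_endmember(-68.79, -68.79, -27.83), 1)
  expect_error(solve_two_endmember(-50, -60, -60), "degenerate")
})

test_that("inversion agrees with a brute-force grid search", {
  set.seed(31)
  for (i in 1:100) {
    a <- stats::runif(1, -110, -60)
    b <- stats::runif(1, -40, -10)
    f_true <- stats::runif(1)
    mix <- f_true * a + (1 - f_true) * b
    grid <- seq(0, 1, by = 1e-6)
    f_grid <- grid[which.min(abs(grid * a + (1 - grid) * b - mix))]
    expect_lt(abs(solve_two_endmember(mix, a, b) - f_grid), 1e-5)
  }
})

test_that("exchanging endmember roles maps f to 1 - f", {
  set.seed(32)
  mix <- stats::runif(20, -100, -30)
  expect_equal(solve_two_endmember(mix, -100.86, -27.83),
               1 - solve_two_endmember(mix, -27.83, -100.86),
               tolerance = 1e-12)
})

test_that("MOB endmember conventions shift methane lighter", {
  expect_equal(mob_endmember(-68.79, 0), -68.79)
  expect_equal(mob_endmember(-68.79, 30.3, "linear"), -99.09)
  expect_equal(mob_endmember(-68.79, 30.3, "ratio"), -96.1758711055033,
               tolerance = 1e-10)
  expect_lt(mob_endmember(-60, 16), -60)
  expect_error(mob_endmember(-60, -1), ">= 0")
})

test_that("average methane endmember filters on concentration strictly", {
  s <- data.frame(d13c_permil = c(-60, -80, -50),
                  conc_umol_l = c(2, 5, 0.5))
  r <- methane_endmember_from_samples(s)
  expect_equal(r$mean, -70)
  expect_equal(r$sd, 14.142135623731, tolerance = 1e-10)
  expect_equal(r$n, 2)
  # exactly at the threshold does not qualify (strictly greater than)
  s2 <- data.frame(d13c_permil = c(-70, -60), conc_umol_l = c(1.0, 2))
  expect_equal(methane_endmember_from_samples(s2)$n, 1)
  one <- methane_endmember_from_samples(
    data.frame(d13c_permil = -70, conc_umol_l = 3))
  expect_equal(one$mean, -70); expect_true(is.na(one$sd))
  # censored concentrations never qualify
  s3 <- data.frame(d13c_permil = c(-70, -60), conc_umol_l = c(2, 2),
                   conc_censored = c(TRUE, FALSE))
  expect_equal(methane_endmember_from_samples(s3)$n, 1)
  expect_error(methane_endmember_from_samples(
    data.frame(d13c_permil = -70, conc_umol_l = 0.2)), "threshold")
})

test_that("per-individual fractions reproduce the printed floodplain rows", {
  r <- f_methane(-55.1)
  expect_equal(r$f_avg, 0.6658, tolerance = 1e-4)
  expect_equal(r$f_cons, 0.3734, tolerance = 1e-4)
  expect_false(r$out_of_range)
  at_om <- f_methane(-27.83)
  expect_equal(at_om$f_avg, 0); expect_equal(at_om$f_cons, 0)
  heavy <- f_methane(-20)
  expect_true(heavy$out_of_range)
  expect_lt(heavy$f_avg, 0)
  # conservative below average whenever biomass is lighter than OM
  light <- f_methane(seq(-100, -28, by = 2))
  expect_true(all(light$f_cons < light$f_avg))
})

test_that("stratified summary averages well means, not individuals", {
  s <- stratified_summary(c(0, 0.2, 0.4, 0.6), c("a", "a", "b", "b"))
  expect_equal(s$mean, 0.3)
  expect_equal(s$n_strata, 2)
  one <- stratified_summary(c(0.2, 0.4), c("w", "w"))
  expect_equal(one$mean, 0.3); expect_true(is.na(one$se))
  expect_equal(one$n_strata, 1)
  const <- stratified_summary(rep(0.5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(const$mean, 0.5); expect_equal(const$se, 0)
  # unbalanced strata: the grand mean weights wells equally
  s2 <- stratified_summary(c(0, 0, 0, 0.5), c("a", "a", "a", "b"))
  expect_equal(s2$mean, 0.25)
})

test_that("affine consistency: f of the stratified mean delta equals the
           stratified mean of per-individual f", {
  set.seed(33)
  d <- stats::runif(60, -90, -30)
  wells <- sample(letters[1:5], 60, replace = TRUE)
  fr <- f_methane(d)
  em <- default_endmembers()
  m_delta <- stratified_summary(d, wells)$mean
  expect_equal(stratified_summary(fr$f_avg, wells)$mean,
               solve_two_endmember(m_delta, em$mob_avg, em$om_d13c),
               tolerance = 1e-12)
  expect_equal(stratified_summary(fr$f_cons, wells)$mean,
               solve_two_endmember(m_delta, em$mob_cons, em$om_d13c),
               tolerance = 1e-12)
})

test_that("Keeling intercept recovers a known source signature", {
  concs <- c(2, 4, 8, 16, 32)
  flat <- suppressWarnings(keeling_intercept(concs, rep(-70, 5)))
  expect_equal(flat$intercept, -70)
  expect_equal(flat$slope, 0)
  # exact two-component mixing: background 1 umol/l at -28, source -70
  bg_c <- 1; bg_d <- -28; src_d <- -70
  add <- c(0.5, 1, 2, 5, 10)
  total <- bg_c + add
  d_mix <- (bg_c * bg_d + add * src_d) / total
  k <- suppressWarnings(keeling_intercept(total, d_mix))
  expect_equal(k$intercept, src_d, tolerance = 1e-8)
  expect_equal(k$r2, 1, tolerance = 1e-10)
  expect_error(keeling_intercept(c(1, 2), c(-70, -69)), ">= 3")
  expect_error(keeling_intercept(c(1, 0, 2), c(-70, -69, -68)), "> 0")
  expect_error(keeling_intercept(rep(2, 4), c(-70, -69, -68, -67)),
               "rank deficient")
})

test_that("age-dependence regression recovers simulated slopes", {
  f <- seq(0.05, 0.95, length.out = 30)
  y <- exp(1.2 * f + 7.2) - 1000           # exactly linear in log(age+1000)
  perfect <- suppressWarnings(age_dependence_regression(y, f))
  expect_equal(perfect$r2, 1, tolerance = 1e-10)
  expect_equal(perfect$slope, 1.2, tolerance = 1e-8)
  const <- age_dependence_regression(c(100, 200, 300), rep(0.4, 3))
  expect_true(is.na(const$slope)); expect_equal(const$r2, 0)
  # noisy simulation: recovered slope within 2 SE of truth
  set.seed(34)
  f2 <- stats::runif(52)
  age2 <- exp(2 * f2 + 7.5 + stats::rnorm(52, 0, 0.15)) - 1000
  fit <- age_dependence_regression(age2, f2)
  se <- summary(fit$fit)$coefficients[2, 2]
  expect_lt(abs(fit$slope - 2), 2 * se)
  expect_equal(fit$n, 52)
  # post-bomb ages enter at zero and are counted
  pb <- age_dependence_regression(c(-5, 100, 400, 900),
                                  c(0.1, 0.3, 0.5, 0.7))
  expect_equal(pb$n_post_bomb, 1)
})

test_that("floodplain table aggregates to well-stratified percentages", {
  em <- default_endmembers()
  b <- data.frame(floodplain = "X", well_id = c("w1", "w1"),
                  d13c_permil = c(em$om_d13c, em$om_d13c))
  t0 <- floodplain_table(b)
  expect_equal(t0$pct_average, 0); expect_equal(t0$pct_conservative, 0)
  # a floodplain whose stratified mean sits at the printed Nyack mean
  b2 <- data.frame(floodplain = "Y",
                   well_id = rep(c("w1", "w2"), each = 2),
                   d13c_permil = c(-54.1, -56.1, -53.1, -57.1))
  t2 <- floodplain_table(b2)
  expect_equal(t2$mean_d13c, -55.1)
  expect_equal(t2$pct_average, 66.577, tolerance = 1e-3)
  expect_warning(
    floodplain_table(data.frame(floodplain = c("A", "B"),
                                well_id = c("w", "v"),
                                d13c_permil = c(-50, NA))),
    "omitted")
})

test_that("floodplain estimate recovers a known generative fraction", {
  # individuals generated from the forward mixture at true f = 0.5
  set.seed(35)
  em <- default_endmembers()
  f_true <- 0.5
  mu <- f_true * em$mob_avg + (1 - f_true) * em$om_d13c
  b <- data.frame(floodplain = "Z",
                  well_id = rep(sprintf("w%d", 1:5), each = 12),
                  d13c_permil = stats::rnorm(60, mu, 2))
  tz <- floodplain_table(b)
  expect_lt(abs(tz$pct_average - 50), 2 * tz$pct_average_se + 1e-9)
})
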