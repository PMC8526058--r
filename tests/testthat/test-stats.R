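test_that("coefficient of variation is SD over mean, scale-invariant", {
  expect_equal(coefficientOfVariation(c(5, 5, 5)), 0)
  set.seed(1)
  a <- rlnorm(50, 3, 0.2)
  expect_equal(coefficientOfVariation(3.7 * a), coefficientOfVariation(a))
  expect_error(coefficientOfVariation(c(1, 2)),
               class = "optomap_invalid_input")
  expect_error(coefficientOfVariation(c(-3, -3, -3)),
               class = "optomap_invalid_input")
})

test_that("binomial-release CV converges to sqrt((1-p)/(Np)) across the parameter grid", {
  set.seed(2)
  q <- 12
  for (N in c(5, 20, 100)) for (p in c(0.2, 0.5, 0.8)) {
    amps <- q * rbinom(20000, N, p)
    amps <- amps[amps > 0] + 0   # a failure sweep has no measurable peak
    # closed-form oracle ignores the rare zero-release exclusions
    if (p * N < 3) amps <- q * rbinom(20000, N, p)
    cv <- sd(amps) / mean(amps)
    expect_equal(cv, sqrt((1 - p) / (N * p)), tolerance = 0.05,
                 label = sprintf("N=%d p=%.1f", N, p))
  }
  amps <- 12 * rbinom(10000, 20, 0.5)
  expect_equal(coefficientOfVariation(amps), sqrt(0.5 / 10), tolerance = 0.03)
})

test_that("percent change satisfies its exact identities and rounding", {
  expect_equal(percentChange(100, 100), 0)
  a <- 137.5
  for (r in c(10, 25, 40)) expect_equal(percentChange(a, a * (1 - r / 100)), r)
  expect_equal(percentChange(80, 100), 100 - 100 * (100 / 80))
  expect_equal(percentChange(200, 123, roundingStep = 5), 40)
  expect_error(percentChange(0, 10), class = "optomap_invalid_input")
})

test_that("the omnibus normality statistic matches the reference implementation", {
  # expected values computed once with an independent reference
  # implementation of the same K2 statistic (skew/kurtosis Z transforms)
  g <- c(-0.5605, -0.2302, 1.5587, 0.0705, 0.1293, 1.7151, 0.4609, -1.2651,
         -0.6869, -0.4457, 1.2241, 0.3598, 0.4008, 0.1107, -0.5558, 1.7869,
         0.4979, -1.9666, 0.7014, -0.4728)
  e <- c(1.4031, 1.4792, 1.2558, 1.1704, 0.3374, 0.0059, 0.8974, 0.9718,
         1.1265, 0.7076, 2.4456, 1.2736, 1.2206, 0.1391, 0.6962, 0.5633,
         1.9096, 0.4427, 0.1446, 1.8172, 1.2723, 1.9935, 0.6458, 0.3569,
         1.758)
  rg <- dagostinoPearsonTest(g)
  expect_equal(rg$statistic, 0.0791017336, tolerance = 1e-6)
  expect_equal(rg$p.value, 0.9612210585, tolerance = 1e-6)
  expect_equal(rg$z_skew, -0.1516423186, tolerance = 1e-6)
  expect_equal(rg$z_kurt, 0.2368677706, tolerance = 1e-6)
  re <- dagostinoPearsonTest(e)
  expect_equal(re$statistic, 0.7151610406, tolerance = 1e-6)
  expect_equal(re$p.value, 0.6993663835, tolerance = 1e-6)
  expect_error(dagostinoPearsonTest(rnorm(7)),
               class = "optomap_invalid_input")
})

test_that("the gate selects the paired t for Gaussian and Wilcoxon for skewed differences", {
  set.seed(5)
  gauss <- replicate(100, choosePairedTest(rnorm(20))$test)
  expect_gte(mean(gauss == "paired t"), 0.9)
  skewed <- replicate(100, choosePairedTest(rexp(20) - 0.2)$test)
  expect_gt(mean(skewed == "Wilcoxon"), 0.5)
  expect_equal(choosePairedTest(rep(2, 20))$test, "Wilcoxon")
  expect_warning(small <- choosePairedTest(rnorm(5)), "n = 8")
  expect_equal(small$test, "Wilcoxon")
})

test_that("paired comparison handles ties, incomplete pairs and reports the gate", {
  eq <- data.frame(pair_id = 1:10, wt = 1:10, ko = 1:10)
  r <- pairedCompare(eq)
  expect_equal(r@p, 1)
  expect_equal(r@statistic, 0)
  withNA <- data.frame(wt = c(rnorm(10, 10), NA), ko = c(rnorm(10, 8), 5))
  expect_message(r2 <- pairedCompare(withNA), "1 incomplete")
  expect_equal(r2@n, 10L)
  expect_true(r2@test %in% c("paired t", "Wilcoxon"))
  expect_error(pairedCompare(data.frame(wt = 1:2, ko = 2:3)),
               class = "optomap_invalid_input")
})

test_that("the gated test detects the genotype effect and keeps its size under the null", {
  # power at the study effect
  set.seed(6)
  rej <- vapply(1:50, function(s) {
    pm <- simulateLedPairMeasures(synthConfig(seed = 7000 + s, n_pairs = 15))
    pairedCompare(pm)@p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
  # size under the null (quick check; the full calibration runs elsewhere)
  rej0 <- vapply(1:200, function(s) {
    pm <- simulateLedPairMeasures(synthConfig(seed = 8000 + s, n_pairs = 15,
                                              ko_scale = 1))
    pairedCompare(pm)@p < 0.05
  }, logical(1))
  expect_gte(mean(rej0), 0.01)
  expect_lte(mean(rej0), 0.10)
})

test_that("the sign-flip permutation test agrees with analytic expectations", {
  set.seed(8)
  d <- rnorm(15, 2, 1)          # strong effect: tiny p
  expect_lt(signFlipTest(d, nPerm = 2000)$p.value, 0.01)
  d0 <- rnorm(15, 0, 1)
  p <- signFlipTest(d0, nPerm = 2000)$p.value
  tp <- t.test(d0)$p.value
  expect_lt(abs(p - tp), 0.2)
})

test_that("interaction ANOVA returns F with its dfs and degenerates sanely", {
  dd <- expand.grid(genotype = c("WT", "KO"), age = c("young", "adult"),
                    rep = 1:10)
  dd$value <- 1
  r <- interactionAnova(dd, "value", "genotype", "age")
  expect_equal(r@statistic, 0)
  expect_equal(r@p, 1)
  # crossover effect: F grows monotonically with the effect size
  set.seed(9)
  noise <- rnorm(nrow(dd))
  Fs <- vapply(c(0.5, 1, 2), function(d_) {
    v <- ifelse(dd$genotype == "KO", 1, -1) *
      ifelse(dd$age == "adult", d_, -d_) + noise
    dd$value <- v
    interactionAnova(dd, "value", "genotype", "age")@statistic
  }, numeric(1))
  expect_true(all(diff(Fs) > 0))
  expect_equal(interactionAnova(dd, "value", "genotype", "age")@df[1], 1)
  expect_error(interactionAnova(dd[dd$genotype == "WT" | dd$age == "young", ],
                                "value", "genotype", "age"),
               class = "optomap_invalid_design")
  # Sidak pairwise on request
  dd$value <- rnorm(nrow(dd))
  rs <- interactionAnova(dd, "value", "genotype", "age", sidak = TRUE)
  expect_s4_class(rs$result, "TestResult")
  expect_equal(nrow(rs$pairwise), 6)   # all pairs of the 4 design cells
})

test_that("the additive null keeps the interaction rejection rate near alpha", {
  set.seed(10)
  dd <- expand.grid(genotype = c("WT", "KO"), age = c("young", "adult"),
                    rep = 1:10)
  rej <- vapply(1:200, function(i) {
    dd$value <- (dd$genotype == "KO") * 1 + (dd$age == "adult") * 2 +
      rnorm(nrow(dd))
    interactionAnova(dd, "value", "genotype", "age")@p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.11)
})
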