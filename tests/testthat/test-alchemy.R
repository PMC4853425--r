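RT298 <- thermalRT(298.15)

test_that("a constant perturbation returns itself and extreme outliers do
           not overflow", {
  expect_equal(zwanzig(rep(2.5, 50)), 2.5, tolerance = 1e-12)
  expect_true(is.finite(zwanzig(c(rnorm(100), -1e6))))
  expect_error(zwanzig(numeric(0)), "samples")
})

test_that("Gaussian perturbations converge to the exponential-average
           closed form with bias shrinking in n", {
  mu <- 1.0; s <- 0.6
  want <- mu - s^2 / (2 * RT298)
  set.seed(11)
  errAt <- function(n, reps = 12) {
    abs(mean(vapply(seq_len(reps), function(i)
      zwanzig(stats::rnorm(n, mu, s)), numeric(1))) - want)
  }
  e3 <- errAt(1e3); e5 <- errAt(1e5)
  expect_lt(e5, 0.01)
  expect_lte(e5, e3 + 0.003)
  ## single large-n draw within 3 spread units of the closed form
  reps <- vapply(1:10, function(i) zwanzig(stats::rnorm(1e5, mu, s)),
                 numeric(1))
  expect_lt(abs(mean(reps) - want), 3 * se(reps))
})

test_that("the restraint schedule interpolates its stated endpoints
           monotonically", {
  expect_equal(restraintSchedule(0), 0)
  expect_equal(restraintSchedule(1), 10)
  expect_equal(restraintSchedule(0.5), 5)
  lams <- seq(0, 1, by = 0.01)
  expect_true(all(diff(restraintSchedule(lams)) >= 0))
  expect_error(restraintSchedule(1.2), "lam")
  ## pluggable monotone form keeps the endpoints
  expect_equal(restraintSchedule(1, form = sqrt), 10)
  expect_equal(restraintSchedule(0.25, form = sqrt), 5)
})

test_that("the harmonic restraint volume matches 3-D quadrature to six
           digits", {
  for (k in c(1e-3, 1, 10, 500)) {
    vq <- stats::integrate(function(r)
      4 * pi * r^2 * exp(-k * r^2 / (2 * RT298)), 0, Inf,
      rel.tol = 1e-10)$value
    expect_equal(restraintVolume(k), vq, tolerance = 1e-6)
  }
  expect_error(restraintVolume(0), "positive")
})

test_that("the standard-state correction obeys the concentration logarithm
           identity and diverges only logarithmically in k", {
  c1 <- standardStateCorrection(10, cStandard = 1)
  c2 <- standardStateCorrection(10, cStandard = 2)
  expect_equal(c2 - c1, -RT298 * log(2), tolerance = 1e-10)
  ks <- 10^seq(-3, 6, by = 1)
  cs <- vapply(ks, standardStateCorrection, numeric(1))
  expect_true(all(is.finite(cs)))
  expect_true(all(diff(cs) > 0))          # tighter restraint, larger term
  ## log-linear growth in k: constant increments per decade
  expect_equal(diff(cs)[1], diff(cs)[5], tolerance = 1e-9)
  expect_error(standardStateCorrection(0), "positive")
})

test_that("importance reweighting removes a known harmonic bias", {
  expect_equal(importanceReweight(1:10, rep(0, 10)), mean(1:10))
  expect_equal(importanceReweight(1:10, rep(3.3, 10)), mean(1:10),
               tolerance = 1e-12)
  expect_error(importanceReweight(1:5, 1:4), "equal length")
  ## x sampled under U0 + Ubias with harmonic a, b: reweighting recovers
  ## the unbiased <x^2> = RT / a
  a <- 2; b <- 3
  set.seed(21)
  ests <- vapply(1:10, function(i) {
    x <- stats::rnorm(4000, 0, sqrt(RT298 / (a + b)))
    importanceReweight(x^2, b * x^2 / 2)
  }, numeric(1))
  expect_lt(abs(mean(ests) - RT298 / a), 3 * se(ests))
})

test_that("decoupling a particle between harmonic wells matches the
           partition-function ratio", {
  fx <- generateFepFixture("harmonic", kCoupled = 20, kDecoupled = 10)
  expect_equal(fx$meta$analyticDeltaG, 1.5 * RT298 * log(10 / 20),
               tolerance = 1e-12)
  sch <- lambdaSchedule(10, equilSweeps = 200, collectSweeps = 2500,
                        sampleEvery = 2)
  vals <- vapply(1:6, function(s)
    runTransformation(fx$factory, sch, 1, 1, "forward",
                      seed = s)$deltaGDecoupling, numeric(1))
  expect_lt(abs(mean(vals) - fx$meta$analyticDeltaG), 3 * se(vals))
})

test_that("forward and reverse runs of the same step cancel within
           statistics", {
  fx <- generateFepFixture("harmonic")
  sch <- lambdaSchedule(10, equilSweeps = 200, collectSweeps = 2000,
                        sampleEvery = 2)
  fwd <- vapply(1:4, function(s)
    runTransformation(fx$factory, sch, 1, 1, "forward",
                      seed = s)$deltaG, numeric(1))
  rev <- vapply(1:4, function(s)
    runTransformation(fx$factory, sch, 1, 1, "reverse",
                      seed = s + 50)$deltaG, numeric(1))
  ## raw (unnegated) values should sum to zero
  expect_lt(abs(mean(fwd) + mean(rev)),
            3 * sqrt(se(fwd)^2 + se(rev)^2) + 0.02)
})

test_that("a null transformation yields exactly zero free energy", {
  nullFactory <- function(transformation, step)
    particleSystem(rbind(c(0, 0, 0), c(4, 0, 0)), epsilon = 0.3, rmin = 4)
  sch <- lambdaSchedule(4, equilSweeps = 50, collectSweeps = 200,
                        sampleEvery = 2)
  res <- runTransformation(nullFactory, sch, 1, 1, "forward", seed = 1)
  expect_equal(res$deltaG, 0, tolerance = 1e-12)
  expect_equal(sum(res$perWindow), res$deltaG, tolerance = 1e-12)
})

test_that("a non-interacting cycle reduces to the correction terms alone", {
  nullFactory <- function(transformation, step)
    particleSystem(rbind(c(0, 0, 0), c(4, 0, 0)), epsilon = 0.3, rmin = 4)
  sch <- lambdaSchedule(4, equilSweeps = 50, collectSweeps = 200,
                        sampleEvery = 2)
  runsOf <- function(tr) lapply(1:2, function(s) {
    r1 <- runTransformation(nullFactory, sch, tr, 1, "forward", seed = s)
    r2 <- runTransformation(nullFactory, sch, tr, 2, "forward", seed = s)
    list(r1, r2)
  })
  t1 <- unlist(runsOf(1), recursive = FALSE)
  t2 <- unlist(runsOf(2), recursive = FALSE)
  corr <- standardStateCorrection(10)
  cyc <- combineCycle(t1, t2, corr)
  expect_equal(cyc$deltaGBind, corr, tolerance = 1e-10)
  expect_equal(cyc$se, 0, tolerance = 1e-10)
})

test_that("cycle bookkeeping: Kd round-trips and missing steps are
           reported", {
  kd <- deltaGtoKd(-9.8)
  expect_equal(kdToDeltaG(kd), -9.8, tolerance = 1e-12)
  fake <- function(tr, st, v) structure(list(transformation = tr, step = st,
    direction = "forward", seed = 1, perWindow = v, deltaG = sum(v),
    deltaGDecoupling = sum(v), acceptance = 0.5, temperature = 298.15),
    class = "TransformationResult")
  t1 <- list(fake(1, 1, 2), fake(1, 2, 1))
  t2 <- list(fake(2, 1, 0.5))
  expect_error(combineCycle(t1, t2, 0), "incomplete cycle")
})

test_that("hysteresis reporting computes replicate standard errors and
           flags divergent steps", {
  fake <- function(tr, st, dir, v) structure(list(transformation = tr,
    step = st, direction = dir, seed = 1, perWindow = v, deltaG = sum(v),
    deltaGDecoupling = if (dir == "forward") sum(v) else -sum(v),
    acceptance = 0.5, temperature = 298.15),
    class = "TransformationResult")
  ## identical forward and negated-reverse values: zero discrepancy
  runs <- c(lapply(1:3, function(i) fake(1, 1, "forward", 2)),
            lapply(1:3, function(i) fake(1, 1, "reverse", -2)))
  rep1 <- hysteresisReport(runs)
  expect_equal(rep1$discrepancy, 0)
  expect_false(rep1$flagged)
  ## known injected spread: se = sd / sqrt(n)
  set.seed(5)
  vals <- stats::rnorm(10, 2, 0.3)
  runs2 <- c(lapply(vals, function(v) fake(1, 1, "forward", v)),
             lapply(1:10, function(i) fake(1, 1, "reverse", -2)))
  rep2 <- hysteresisReport(runs2)
  expect_equal(rep2$seForward, stats::sd(vals) / sqrt(10),
               tolerance = 1e-10)
  ## a deliberately divergent step is flagged
  runs3 <- c(lapply(stats::rnorm(5, 2, 0.05),
                    function(v) fake(1, 2, "forward", v)),
             lapply(stats::rnorm(5, 3, 0.05),
                    function(v) fake(1, 2, "reverse", -v)))
  expect_true(hysteresisReport(runs3)$flagged)
  expect_error(hysteresisReport(runs[1:3]), "forward and one reverse")
})

test_that("the stated window/replicate protocol implies a 336 ns
           campaign", {
  expect_equal(fepCampaignTime(nWindows = 20, equilPs = 10,
                               collectPs = 190, preEquilPs = 200,
                               steps = 4, replicates = 10,
                               directions = 2), 336)
})
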