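RT298 <- thermalRT(298.15)

## the documented soft-core kernel, written out independently of the package
refSoftcore <- function(r, eps, rmin, lc, shift) {
  sw <- if (r <= 6) 1 else if (r >= 10) 0 else
    (100 - r^2)^2 * (100 + 2 * r^2 - 3 * 36) / (100 - 36)^3
  r2 <- r^2 + shift * (1 - lc)
  lc * eps * ((rmin^2 / r2)^6 - 2 * (rmin^2 / r2)^3) * sw
}

pairSystem <- function(r, eps = 1, rmin = 4.5, decouple = TRUE) {
  particleSystem(rbind(c(0, 0, 0), c(r, 0, 0)), epsilon = eps, rmin = rmin,
                 decoupleSet = if (decouple) 2L else integer(0))
}

test_that("fully coupled soft-core energy equals plain Lennard-Jones and
           full decoupling removes it", {
  for (r in c(3.5, 4.5, 7, 9.5)) {
    plain <- systemEnergy(pairSystem(r, decouple = FALSE))["vdw"]
    expect_equal(unname(systemEnergy(pairSystem(r), lam = 0)["vdw"]),
                 unname(plain), tolerance = 1e-12)
    expect_equal(unname(systemEnergy(pairSystem(r), lam = 1)["vdw"]), 0)
  }
})

test_that("soft-core pair energy matches the documented closed form", {
  ## decoupling progress 0.5 -> coupling strength 0.5; shift 8 A^2
  for (r in c(3.0, 4.0, 5.5, 7.0)) {
    for (lamd in c(0.2, 0.5, 0.8)) {
      lc <- 1 - lamd
      want <- refSoftcore(r, 1, 4.5, lc, 8)
      expect_equal(unname(systemEnergy(pairSystem(r), lam = lamd,
                                       shiftCoeff = 8)["vdw"]),
                   want, tolerance = 1e-12)
      expect_equal(softcorePairEnergy(r, 1, 4.5, lc, 8), want,
                   tolerance = 1e-12)
    }
  }
})

test_that("energy is continuous in lambda across [0, 1]", {
  lams <- seq(0, 1, by = 1e-4)
  sys <- pairSystem(4.0)
  u <- vapply(lams, function(l)
    unname(systemEnergy(sys, lam = l, shiftCoeff = 8)["total"]),
    numeric(1))
  ## no discontinuity anywhere, endpoints included: adjacent-grid jumps stay
  ## bounded by a smooth-kernel slope (O(eps) kcal/mol per unit lambda)
  expect_lt(max(abs(diff(u))), 20 * 1e-4)
  expect_false(any(!is.finite(u)))
})

test_that("interactions vanish beyond the 10 A cutoff and switch from 6 A", {
  expect_equal(unname(systemEnergy(pairSystem(10.5,
                                              decouple = FALSE))["vdw"]), 0)
  ## below the switch-on distance the plain kernel is unswitched
  e5 <- unname(systemEnergy(pairSystem(5, decouple = FALSE))["vdw"])
  expect_equal(e5, 1 * ((4.5 / 5)^12 - 2 * (4.5 / 5)^6), tolerance = 1e-12)
  ## between 6 and 10 the energy is scaled by the switching polynomial
  e8 <- unname(systemEnergy(pairSystem(8, decouple = FALSE))["vdw"])
  sw <- (100 - 64)^2 * (100 + 128 - 108) / (100 - 36)^3
  expect_equal(e8, 1 * ((4.5 / 8)^12 - 2 * (4.5 / 8)^6) * sw,
               tolerance = 1e-12)
})

test_that("unlike pairs use Lorentz-Berthelot mixing", {
  sys <- particleSystem(rbind(c(0, 0, 0), c(4, 0, 0)),
                        epsilon = c(0.5, 2), rmin = c(3, 5))
  want <- sqrt(0.5 * 2) * ((4 / 4)^12 - 2 * (4 / 4)^6)  # mixed rmin = 4
  expect_equal(unname(systemEnergy(sys)["vdw"]), want, tolerance = 1e-12)
})

test_that("energy breakdown components sum to the total", {
  sys <- particleSystem(rbind(c(0, 0, 0), c(4.2, 0, 0), c(0, 4.2, 0)),
                        epsilon = 0.4, rmin = 4,
                        bonds = data.frame(i = 1, j = 2, k = 5, r0 = 4),
                        restraints = list(harmonicRestraint(1, 3, 2, 3)))
  e <- systemEnergy(sys, lam = 0)
  expect_equal(unname(e["total"]),
               unname(e["vdw"] + e["bonded"] + e["restraint"]),
               tolerance = 1e-10)
})

test_that("sampling is deterministic given the seed", {
  sys <- pairSystem(4.5, decouple = FALSE)
  r1 <- mcSample(sys, nsweeps = 500, seed = 7)
  r2 <- mcSample(sys, nsweeps = 500, seed = 7)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$positions, r2$positions)
  r3 <- mcSample(sys, nsweeps = 500, seed = 8)
  expect_false(identical(r1$positions, r3$positions))
})

test_that("a harmonically restrained particle satisfies equipartition", {
  ## <r^2> = 3 RT / k for energy (k/2) r^2
  k <- 10
  sys <- particleSystem(rbind(c(0, 0, 0), c(0.3, 0, 0)), epsilon = 0,
                        rmin = 3, restraints = list(
                          harmonicRestraint(1, 2, k, 0)),
                        fixed = 1)
  run <- mcSample(sys, nsweeps = 40000, stepSize = 0.6, seed = 3,
                  sampleEvery = 4, trackPair = c(1, 2))
  r2 <- run$samples[, "dist"]^2
  want <- 3 * RT298 / k
  ## block the correlated samples for an honest standard error
  blocks <- tapply(r2, rep(seq_len(50), each = length(r2) / 50), mean)
  expect_lt(abs(mean(r2) - want), 3 * se(blocks))
})

test_that("a cold Lennard-Jones pair samples the potential minimum", {
  sys <- particleSystem(rbind(c(0, 0, 0), c(4.5, 0, 0)), epsilon = 1,
                        rmin = 4.5, fixed = 1, temperature = 60)
  run <- mcSample(sys, nsweeps = 30000, stepSize = 0.25, seed = 5,
                  sampleEvery = 3, trackPair = c(1, 2))
  d <- run$samples[, "dist"]
  h <- hist(d, breaks = seq(floor(min(d)), ceiling(max(d)), by = 0.1),
            plot = FALSE)
  peak <- h$mids[which.max(h$counts)]
  expect_lt(abs(peak - 4.5), 0.15)
})

test_that("double-well occupancies follow the Boltzmann-weighted
           quadrature oracle", {
  ## two fixed wells of different depth; occupancy ratio should match the
  ## ratio of their configurational integrals
  epsA <- 1.6; epsB <- 1.0; rmin <- 3.5
  sys <- particleSystem(rbind(c(6, 12, 12), c(18, 12, 12),
                              c(6, 12.5, 12.5)),
                        epsilon = c(epsA, epsB, 1), rmin = rmin,
                        fixed = 1:2, box = c(24, 24, 24),
                        temperature = 220)
  RTk <- thermalRT(220)
  uLJ <- function(r, eps) {
    sw <- ifelse(r <= 6, 1, ifelse(r >= 10, 0,
      (100 - r^2)^2 * (100 + 2 * r^2 - 3 * 36) / (100 - 36)^3))
    eps * ((rmin / r)^12 - 2 * (rmin / r)^6) * sw
  }
  ## occupancy of the two balls (r < 5.5 around each well) against the
  ## Boltzmann-weighted configurational integrals of the same regions
  Z <- function(eps) stats::integrate(function(r)
    4 * pi * r^2 * exp(-uLJ(r, sqrt(eps * 1)) / RTk), 0.5, 5.5)$value
  wantRatio <- Z(epsA) / Z(epsB)
  run <- mcSample(sys, nsweeps = 160000, stepSize = 1.6, seed = 17,
                  sampleEvery = 10, trackPair = c(1, 3),
                  trackPair2 = c(2, 3))
  dA <- run$samples[, "dist"]; dB <- run$samples[, "dist2"]
  nA <- sum(dA < 5.5); nB <- sum(dB < 5.5)
  expect_gt(nA, 50); expect_gt(nB, 50)
  expect_lt(abs(log(nA / nB) - log(wantRatio)), 0.5)
})

test_that("energies are invariant to lattice translations of a periodic
           system", {
  box <- c(22, 22, 22)
  set.seed(2)
  pos <- matrix(stats::runif(30, 0, 22), 10, 3)
  sys <- particleSystem(pos, epsilon = 0.3, rmin = 3.5, box = box)
  e0 <- systemEnergy(sys)["total"]
  pos2 <- pos; pos2[4, ] <- pos2[4, ] + box  # shift one particle by a cell
  e1 <- systemEnergy(particleSystem(pos2, epsilon = 0.3, rmin = 3.5,
                                    box = box))["total"]
  expect_equal(unname(e0), unname(e1), tolerance = 1e-9)
})

test_that("invalid sampler and system inputs are rejected", {
  sys <- pairSystem(4)
  expect_error(mcSample(sys, lam = 1.2), "lam")
  expect_error(mcSample(sys, nsweeps = 0), "nsweeps")
  expect_error(systemEnergy(sys, lam = -0.1), "lam")
  expect_error(particleSystem(matrix(numeric(0), 0, 3)), "at least one")
  expect_error(particleSystem(rbind(c(0, 0, 0), c(1, 0, 0)),
                              box = c(15, 25, 25)), "box edges")
})
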