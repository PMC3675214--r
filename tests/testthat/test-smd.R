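test_that("identical master seeds give bit-identical ensembles", {
  scn <- validationScenario(seed = 7)
  scn$params@M <- 4L
  a <- simulatePulling(scn$potential, scn$protocol, scn$params,
                       scn$pullDistance)
  b <- simulatePulling(scn$potential, scn$protocol, scn$params,
                       scn$pullDistance)
  for (i in seq_along(a)) expect_identical(a[[i]]@xi, b[[i]]@xi)
  scn2 <- validationScenario(seed = 8)
  scn2$params@M <- 4L
  c <- simulatePulling(scn2$potential, scn2$protocol, scn2$params,
                       scn2$pullDistance)
  expect_false(identical(a[[1]]@xi, c[[1]]@xi))
})

test_that("near-zero temperature on a flat potential gives the drag lag", {
  ## deterministic limit: xi tracks lambda with steady lag gamma v / k
  prot <- pullingProtocol(k = 10, v = 2, temperature = 1e-8)
  par <- langevinParams(gamma = 1, dt = 5e-4, temperature = 1e-8,
                        seed = 1, M = 2, init = "fixed")
  trs <- simulatePulling(potentialSpec("flat"), prot, par,
                         pullDistance = 6)
  lag <- trs[[1]]@lambda - trs[[1]]@xi
  n <- length(lag)
  expect_equal(lag[n], par@gamma * prot@v / prot@k, tolerance = 1e-3)
  ## transient: lag grows monotonically while relaxing (first 2.5 tau)
  expect_true(all(diff(lag[1:50]) > 0))
})

test_that("a stiff guide confines the particle to the thermal width", {
  prot <- pullingProtocol(k = 200, v = 1, temperature = 310)
  par <- langevinParams(gamma = 1, dt = 2e-4, temperature = 310,
                        seed = 3, M = 10)
  trs <- simulatePulling(potentialSpec("flat"), prot, par,
                         pullDistance = 2)
  beta <- thermoParams(310)@beta
  width <- sqrt(1 / (beta * prot@k))
  lagTerm <- par@gamma * prot@v / prot@k
  dev <- abs(unlist(lapply(trs, function(tr) tr@xi - tr@lambda)))
  ## bulk of the excursions within three thermal widths of the guide,
  ## extremes within the Gaussian tail expected at this sample count
  expect_gt(mean(dev < 3 * width + lagTerm), 0.99)
  expect_lt(max(dev), 6 * width + lagTerm)
})

test_that("the integrator refuses unstable time steps", {
  prot <- pullingProtocol(k = 50, v = 1)
  par <- langevinParams(gamma = 1, dt = 0.01, M = 2)
  expect_error(
    simulatePulling(potentialSpec("harmonic", a = 1, c = 0.5), prot, par),
    "reduce dt")
})

test_that("ground-truth profiles follow the specified potentials", {
  xi <- seq(0, 2, by = 0.05)
  expect_equal(groundTruthPMF(potentialSpec("flat"), xi)@phi,
               rep(0, length(xi)))
  gt <- groundTruthPMF(potentialSpec("harmonic", a = 2, c = 1), xi)
  expect_equal(gt@phi, (xi - 1)^2 - 1)
  ## double well: barrier height above the wells equals h by construction
  dw <- potentialSpec("double-well", h = 3, c = 1, w = 0.5)
  expect_equal(potentialEnergy(dw, 1) - potentialEnergy(dw, 0.5), 3)
  expect_equal(potentialEnergy(dw, c(0.5, 1.5)), c(0, 0))
  pl <- potentialSpec("piecewise-linear", x1 = 0, y1 = 0, x2 = 1, y2 = 2,
                      x3 = 2, y3 = 1)
  expect_equal(potentialEnergy(pl, c(0.5, 1.5)), c(1, 1.5))
  expect_equal(potentialGradient(pl, c(0.5, 1.5)), c(2, -1))
})

test_that("potential gradients match numerical differentiation", {
  xi <- seq(-1, 3, by = 0.1)
  h <- 1e-6
  for (pot in list(potentialSpec("harmonic", a = 1.5, c = 0.7),
                   potentialSpec("double-well", h = 2, c = 1, w = 0.8))) {
    num <- (potentialEnergy(pot, xi + h) - potentialEnergy(pot, xi - h)) /
      (2 * h)
    expect_equal(potentialGradient(pot, xi), num, tolerance = 1e-6)
  }
})

test_that("work distributions narrow as pulling slows", {
  ## variance of the endpoint work drops with v (less dissipation)
  pot <- potentialSpec("flat")
  endVar <- vapply(c(2, 1, 0.5), function(v) {
    scn <- validationScenario(seed = 11, v = v)
    trs <- simulatePulling(pot, scn$protocol, scn$params, scn$pullDistance)
    ens <- workEnsemble(trs)
    var(ens@work[, ncol(ens@work)])
  }, numeric(1))
  expect_true(all(diff(endVar) < 0))
})

test_that("the estimator pipeline recovers a known potential end to end", {
  scn <- validationScenario(seed = 21)
  trs <- simulatePulling(scn$potential, scn$protocol, scn$params,
                         scn$pullDistance)
  prof <- estimatePMF(trs)
  gt <- groundTruthPMF(scn$potential, prof@xi)
  expect_lt(max(abs(prof@phi - gt@phi)), 0.75)
  ## the cumulant estimator lands close to the exponential average here
  prof2 <- estimatePMF(trs, estimator = "cumulant2")
  expect_lt(max(abs(prof2@phi - gt@phi)), 0.75)
})
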