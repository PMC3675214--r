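## Unit-beta thermodynamics keeps hand algebra simple.
betaOne <- thermoParams(temperature = 1 / 0.0019872041)

test_that("a perfectly tracking particle accumulates no work", {
  prot <- pullingProtocol(k = 5, v = 2)
  t <- seq(0, 3, by = 0.01)
  tr <- pullingTrajectory(time = t, xi = prot@v * t, protocol = prot)
  expect_equal(computeWork(tr), rep(0, length(t)))
})

test_that("constant lag reproduces the closed-form work exactly", {
  ## xi = lambda - d gives constant force k d, so W(t) = k d v t; the
  ## trapezoid rule is exact for a constant integrand
  k <- 5; v <- 2; d <- 0.3
  prot <- pullingProtocol(k = k, v = v)
  t <- seq(0, 4, by = 0.05)
  tr <- pullingTrajectory(time = t, xi = v * t - d, protocol = prot)
  expect_lt(max(abs(computeWork(tr) - k * d * v * t)[-1] /
                (k * d * v * t)[-1]), 1e-10)
})

test_that("trapezoid error shrinks as the sampling stride refines", {
  ## quadratic lag: xi = lambda - c t^2; W(t) = k v c t^3 / 3 exactly
  k <- 5; v <- 1; cc <- 0.05
  prot <- pullingProtocol(k = k, v = v)
  err <- vapply(c(0.2, 0.1, 0.05, 0.025), function(h) {
    t <- seq(0, 2, by = h)
    tr <- pullingTrajectory(time = t, xi = v * t - cc * t^2,
                            protocol = prot, tol = 1)
    max(abs(computeWork(tr) - k * v * cc * t^3 / 3))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[4] / err[1], 1 / 16)  # second-order convergence
})

test_that("trajectory validation catches inconsistent inputs", {
  prot <- pullingProtocol(k = 5, v = 1)
  expect_error(pullingTrajectory(time = c(0, 1, 1), xi = c(0, 1, 1),
                                 protocol = prot), "increasing")
  expect_error(pullingTrajectory(time = 0:2, xi = c(0, 1, 2),
                                 lambda = c(0, 2, 4), protocol = prot),
               "schedule")
  expect_error(pullingTrajectory(time = 0:2, xi = c(0, 1, 2),
                                 force = c(1, 1, 1), protocol = prot),
               "inconsistent")
})

test_that("jarzynski estimate matches hand values and invariants", {
  th <- thermoParams()  # 310 K
  expect_equal(jarzynskiDeltaA(3.0, th), 3.0)
  expect_equal(jarzynskiDeltaA(rep(2.5, 20), th), 2.5)
  expect_error(jarzynskiDeltaA(numeric(), th), "empty")

  set.seed(4)
  for (i in 1:20) {
    w <- rnorm(50, mean = 5, sd = 2)
    dA <- jarzynskiDeltaA(w, th)
    ## Jensen bound and permutation invariance
    expect_lte(dA, mean(w) + 1e-12)
    expect_equal(jarzynskiDeltaA(sample(w), th), dA)
    ## shifting all works by c shifts the estimate by c
    expect_equal(jarzynskiDeltaA(w + 1.7, th), dA + 1.7)
  }
  ## shifted-exponential formulation survives very large beta W
  expect_equal(jarzynskiDeltaA(c(5000, 5001), th),
               5000 - log(mean(c(1, exp(-th@beta)))) / th@beta)
})

test_that("cumulant estimator matches hand algebra", {
  expect_equal(cumulant2DeltaA(c(2, 2), betaOne), 2.0)
  x <- 1.3
  ## unbiased variance of {0, x} is x^2/2, so the estimate is x/2 - x^2/4
  expect_equal(cumulant2DeltaA(c(0, x), betaOne), x / 2 - x^2 / 4)
  expect_error(cumulant2DeltaA(3, betaOne), "at least two")
})

test_that("both estimators agree with the Gaussian closed form", {
  ## for W ~ N(mu, sigma^2): deltaA = mu - beta sigma^2 / 2
  th <- thermoParams()
  mu <- 2; sigma <- 0.6
  truth <- mu - th@beta * sigma^2 / 2
  set.seed(12)
  w <- rnorm(4e4, mu, sigma)
  se <- sd(exp(-th@beta * (w - min(w)))) /
    (mean(exp(-th@beta * (w - min(w)))) * sqrt(length(w))) / th@beta
  expect_lt(abs(jarzynskiDeltaA(w, th) - truth), 3 * se)
  expect_lt(abs(cumulant2DeltaA(w, th) - truth), 0.05)
})

test_that("work ensembles interpolate onto a common guide grid", {
  prot <- pullingProtocol(k = 5, v = 1)
  d <- 0.2
  mk <- function(h) {
    t <- seq(0, 2, by = h)
    pullingTrajectory(time = t, xi = prot@v * t - d, protocol = prot)
  }
  ens <- workEnsemble(list(mk(0.01), mk(0.02)), lambdaGrid = seq(0, 2, 0.1))
  expect_identical(dim(ens@work), c(2L, 21L))
  expect_equal(ens@work[, 1], c(0, 0))
  ## both trajectories carry the same closed-form work at the same lambda
  expect_equal(ens@work[1, ], ens@work[2, ], tolerance = 1e-10)
  expect_equal(ens@work[1, 21], prot@k * d * 2, tolerance = 1e-8)
})

test_that("stiff-spring mapping anchors the profile", {
  prot <- pullingProtocol(k = 50, v = 1)
  lam <- seq(0, 2, 0.1)
  prof <- stiffSpringPMF(rep(0, length(lam)), lam, prot)
  expect_equal(prof@phi, rep(0, length(lam)))
  dA <- 3 + 0.5 * lam^2
  prof2 <- stiffSpringPMF(dA, lam, prot)
  expect_equal(prof2@phi[1], 0)
  expect_equal(prof2@phi, dA - dA[1])
  expect_identical(prof2@k, 50)
  expect_error(stiffSpringPMF(dA, rev(lam), prot), "increasing")
})

test_that("bootstrap intervals are seeded, nested and degenerate-safe", {
  prot <- pullingProtocol(k = 5, v = 1)
  t <- seq(0, 1, by = 0.05)
  same <- lapply(1:5, function(i)
    pullingTrajectory(time = t, xi = prot@v * t - 0.1, protocol = prot))
  ens <- workEnsemble(same)
  ci <- bootstrapUncertainty(ens, replicates = 50, seed = 9)
  expect_equal(ci$lower, ci$upper)  # identical trajectories: zero width

  set.seed(31)
  vary <- lapply(1:8, function(i)
    pullingTrajectory(time = t, xi = prot@v * t - 0.1 - rnorm(1, 0, 0.02),
                      protocol = prot, tol = 1))
  ens2 <- workEnsemble(vary)
  a <- bootstrapUncertainty(ens2, replicates = 100, seed = 5)
  b <- bootstrapUncertainty(ens2, replicates = 100, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$upper - a$lower >= 0))
  expect_error(bootstrapUncertainty(workEnsemble(same[1]), seed = 1),
               "two trajectories")
})

test_that("bootstrap width shrinks with ensemble size", {
  prot <- pullingProtocol(k = 5, v = 1)
  t <- seq(0, 1, by = 0.05)
  width <- vapply(c(5, 20, 80), function(M) {
    set.seed(M)
    trs <- lapply(seq_len(M), function(i)
      pullingTrajectory(time = t, xi = prot@v * t - 0.1 - rnorm(1, 0, 0.05),
                        protocol = prot, tol = 1))
    ci <- bootstrapUncertainty(workEnsemble(trs), replicates = 200, seed = 1)
    mean(ci$upper - ci$lower)
  }, numeric(1))
  expect_true(all(diff(width) < 0))
})

test_that("mirror-lag trajectories average to zero force", {
  prot <- pullingProtocol(k = 5, v = 1)
  t <- seq(0, 1, by = 0.05)
  plus <- pullingTrajectory(time = t, xi = prot@v * t - 0.2, protocol = prot)
  minus <- pullingTrajectory(time = t, xi = prot@v * t + 0.2, protocol = prot)
  fp <- averageForceProfile(list(plus, minus))
  expect_equal(fp$force, rep(0, nrow(fp)))
  single <- averageForceProfile(list(plus))
  expect_equal(single$force, rep(prot@k * 0.2, nrow(single)))
})
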