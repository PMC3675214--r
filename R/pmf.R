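#' Thermodynamic parameters
#'
#' @param temperature kelvin (default 310).
#' @param kB Boltzmann constant in kcal/(mol K).
#' @return A \code{\link{ThermoParams}} with beta = 1/(kB T).
#' @export
thermoParams <- function(temperature = 310, kB = 0.0019872041) {
  new("ThermoParams", temperature = temperature, kB = kB,
      beta = 1 / (kB * temperature))
}

#' Constant-velocity pulling protocol
#'
#' @param k guide spring constant, kcal/(mol A^2) (default 5, the SMD
#'   value used for peptide unbinding).
#' @param v pulling velocity, A/ns.
#' @param lambda0 guide origin, A.
#' @param temperature kelvin.
#' @return A \code{\link{PullingProtocol}}.
#' @export
pullingProtocol <- function(k = 5, v = 1, lambda0 = 0, temperature = 310) {
  new("PullingProtocol", k = k, v = v, lambda0 = lambda0,
      temperature = temperature)
}

#' Assemble a pulling trajectory
#'
#' Validates that time is strictly increasing, that the guide positions
#' follow the protocol schedule lambda(t) = lambda0 + v t, and that any
#' supplied force column equals k (lambda - xi). The force is derived
#' from the spring when absent.
#'
#' @param time sample times, ns.
#' @param xi reaction-coordinate samples, A.
#' @param protocol a \code{\link{PullingProtocol}}.
#' @param lambda guide positions (default: the protocol schedule).
#' @param force applied force (default: k (lambda - xi)).
#' @param tol consistency tolerance, A.
#' @param source provenance label.
#' @return A \code{\link{PullingTrajectory}}.
#' @export
pullingTrajectory <- function(time, xi, protocol, lambda = NULL,
                              force = NULL, tol = 1e-3,
                              source = NA_character_) {
  if (any(diff(time) <= 0))
    .stopInput("trajectory time must be strictly increasing")
  sched <- protocol@lambda0 + protocol@v * (time - time[1L])
  if (is.null(lambda)) lambda <- sched
  else if (max(abs(lambda - sched)) > tol)
    .stopInput("guide positions deviate from the protocol schedule by %g A",
               max(abs(lambda - sched)))
  spring <- protocol@k * (lambda - xi)
  if (is.null(force)) force <- spring
  else if (max(abs(force - spring)) > protocol@k * tol)
    .stopInput("force column inconsistent with k (lambda - xi) by %g",
               max(abs(force - spring)))
  new("PullingTrajectory", time = time, lambda = lambda, xi = xi,
      force = force, protocol = protocol, source = source)
}

#' @rdname computeWork
#' @export
setMethod("computeWork", "PullingTrajectory", function(trajectory) {
  ## W(t) = v * int k (lambda - xi) dt' ; trapezoid on the sample times
  .cumtrapz(trajectory@time, trajectory@protocol@v * trajectory@force)
})

#' Resample an ensemble of trajectories onto a common guide grid
#'
#' Computes each trajectory's accumulated work and linearly interpolates
#' it onto a common grid of guide positions, so work values at the same
#' lambda can be combined across trajectories.
#'
#' @param trajectories list of \code{\link{PullingTrajectory}}.
#' @param lambdaGrid common grid, A; default: the first trajectory's
#'   guide positions clipped to the range every trajectory covers.
#' @return A \code{\link{WorkEnsemble}}.
#' @export
workEnsemble <- function(trajectories, lambdaGrid = NULL) {
  if (!length(trajectories)) .stopInput("empty trajectory ensemble")
  if (is.null(lambdaGrid)) {
    lo <- max(vapply(trajectories, function(tr) min(tr@lambda), numeric(1)))
    hi <- min(vapply(trajectories, function(tr) max(tr@lambda), numeric(1)))
    g <- trajectories[[1L]]@lambda
    lambdaGrid <- g[g >= lo - 1e-12 & g <= hi + 1e-12]
  }
  work <- t(vapply(trajectories, function(tr)
    .interp(tr@lambda, computeWork(tr), lambdaGrid, "lambda grid"),
    numeric(length(lambdaGrid))))
  ## anchor: work is zero where the pull starts
  work <- work - work[, 1L]
  new("WorkEnsemble", lambda = lambdaGrid, work = work,
      protocol = trajectories[[1L]]@protocol)
}

#' Jarzynski free-energy estimate from work values at one guide position
#'
#' Evaluates deltaA = -(1/beta) log mean(exp(-beta W)) over the ensemble,
#' using a shifted exponential (the minimum work is subtracted before
#' exponentiation) so large beta W does not underflow.
#'
#' @param works numeric vector of work values, kcal/mol.
#' @param thermo a \code{\link{ThermoParams}}.
#' @return The free-energy estimate, kcal/mol.
#' @examples
#' jarzynskiDeltaA(c(3, 3, 3))   # 3
#' @export
jarzynskiDeltaA <- function(works, thermo = thermoParams()) {
  if (!length(works)) .stopInput("empty work ensemble")
  b <- thermo@beta
  m <- min(works)
  m - log(mean(exp(-b * (works - m)))) / b
}

#' Second-order cumulant free-energy estimate
#'
#' mean(W) - beta var(W)/2 with the unbiased variance: exact for Gaussian
#' work distributions and far less sample-hungry than the exponential
#' average when dissipation is large.
#'
#' @param works numeric vector of at least two work values, kcal/mol.
#' @param thermo a \code{\link{ThermoParams}}.
#' @return The free-energy estimate, kcal/mol.
#' @export
cumulant2DeltaA <- function(works, thermo = thermoParams()) {
  if (length(works) < 2L)
    .stopInput("cumulant estimator needs at least two work values")
  mean(works) - thermo@beta * stats::var(works) / 2
}

## Estimator dispatch shared by the profile functions.
.estimatorFun <- function(estimator) {
  switch(match.arg(estimator, c("jarzynski", "cumulant2")),
         jarzynski = jarzynskiDeltaA, cumulant2 = cumulant2DeltaA)
}

#' Free-energy profile along the guide coordinate
#'
#' Applies a free-energy estimator to each column of the work ensemble.
#'
#' @param ensemble a \code{\link{WorkEnsemble}}.
#' @param thermo a \code{\link{ThermoParams}}.
#' @param estimator \code{"jarzynski"} or \code{"cumulant2"}.
#' @return Numeric vector deltaA(lambda), kcal/mol.
#' @export
deltaAProfile <- function(ensemble, thermo = thermoParams(),
                          estimator = "jarzynski") {
  f <- .estimatorFun(estimator)
  apply(ensemble@work, 2L, f, thermo = thermo)
}

#' Potential of mean force under the stiff-spring approximation
#'
#' For a sufficiently stiff guide spring the reaction coordinate tracks
#' the guide closely and, to leading order, the PMF read at xi = lambda is
#' the anchored guide free-energy profile: Phi(xi = lambda) =
#' deltaA(lambda) - deltaA(lambda0). An optional second-order correction
#' subtracts (deltaA')^2 / (2 k) (finite-difference gradient); it is off
#' by default and only meaningful when the profile is well resolved.
#'
#' @param deltaA free-energy profile on \code{lambda}.
#' @param lambda guide grid, A, strictly increasing.
#' @param protocol the \code{\link{PullingProtocol}} (records k).
#' @param estimator label stored in the profile.
#' @param secondOrder apply the second-order stiffness correction.
#' @return A \code{\link{PMFProfile}} anchored to 0 at the grid start.
#' @export
stiffSpringPMF <- function(deltaA, lambda, protocol,
                           estimator = "jarzynski", secondOrder = FALSE) {
  if (any(diff(lambda) <= 0))
    .stopInput("lambda grid must be strictly increasing")
  if (length(deltaA) != length(lambda))
    .stopInput("deltaA and lambda must have equal length")
  phi <- deltaA - deltaA[1L]
  if (secondOrder && length(lambda) >= 3L) {
    grad <- c(diff(phi)[1L] / diff(lambda)[1L],
              (phi[-(1:2)] - phi[-c(length(phi) - 1L, length(phi))]) /
                (lambda[-(1:2)] - lambda[-c(length(lambda) - 1L, length(lambda))]),
              diff(phi)[length(phi) - 1L] / diff(lambda)[length(lambda) - 1L])
    phi <- phi - grad^2 / (2 * protocol@k)
    phi <- phi - phi[1L]
  }
  new("PMFProfile", xi = lambda, phi = phi, deltaA = deltaA,
      estimator = estimator, k = protocol@k)
}

#' Estimate a PMF from a trajectory ensemble
#'
#' Convenience wrapper: resamples work onto a common guide grid, applies
#' the chosen estimator per grid point, maps to the PMF by the
#' stiff-spring approximation, and optionally attaches bootstrap
#' uncertainty.
#'
#' @param trajectories list of \code{\link{PullingTrajectory}}, or a
#'   \code{\link{WorkEnsemble}}.
#' @param thermo a \code{\link{ThermoParams}}.
#' @param estimator \code{"jarzynski"} or \code{"cumulant2"}.
#' @param lambdaGrid optional common grid.
#' @param bootstrap number of bootstrap replicates (0 = none).
#' @param seed seed for the bootstrap resampling.
#' @param level interval level for the bootstrap (default 0.95).
#' @param secondOrder see \code{\link{stiffSpringPMF}}.
#' @return A \code{\link{PMFProfile}}.
#' @export
estimatePMF <- function(trajectories, thermo = thermoParams(),
                        estimator = "jarzynski", lambdaGrid = NULL,
                        bootstrap = 0, seed = 1, level = 0.95,
                        secondOrder = FALSE) {
  ens <- if (is(trajectories, "WorkEnsemble")) trajectories
         else workEnsemble(trajectories, lambdaGrid)
  dA <- deltaAProfile(ens, thermo, estimator)
  prof <- stiffSpringPMF(dA, ens@lambda, ens@protocol, estimator,
                         secondOrder = secondOrder)
  if (bootstrap > 0) {
    ci <- bootstrapUncertainty(ens, thermo, replicates = bootstrap,
                               seed = seed, estimator = estimator,
                               level = level)
    prof@lower <- ci$lower
    prof@upper <- ci$upper
  }
  prof
}

#' Bootstrap uncertainty of the free-energy profile
#'
#' Resamples trajectories with replacement, recomputes the anchored
#' profile per replicate, and returns pointwise percentile intervals.
#' Seeded and reproducible.
#'
#' @param ensemble a \code{\link{WorkEnsemble}} with at least two
#'   trajectories.
#' @param thermo a \code{\link{ThermoParams}}.
#' @param replicates number of bootstrap replicates.
#' @param seed integer seed.
#' @param estimator \code{"jarzynski"} or \code{"cumulant2"}.
#' @param level interval level (default 0.95).
#' @return List with numeric vectors \code{lower} and \code{upper}, one
#'   value per grid point.
#' @export
bootstrapUncertainty <- function(ensemble, thermo = thermoParams(),
                                 replicates = 200, seed = 1,
                                 estimator = "jarzynski", level = 0.95) {
  M <- nrow(ensemble@work)
  if (M < 2L) .stopInput("bootstrap needs at least two trajectories")
  if (replicates < 1L) .stopInput("replicates must be >= 1")
  f <- .estimatorFun(estimator)
  reps <- .withSeed(seed, {
    idx <- matrix(sample.int(M, M * replicates, replace = TRUE),
                  nrow = replicates)
    t(apply(idx, 1L, function(rows) {
      dA <- apply(ensemble@work[rows, , drop = FALSE], 2L, f,
                  thermo = thermo)
      dA - dA[1L]
    }))
  })
  a <- (1 - level) / 2
  list(lower = apply(reps, 2L, stats::quantile, probs = a, names = FALSE),
       upper = apply(reps, 2L, stats::quantile, probs = 1 - a,
                     names = FALSE))
}

#' Ensemble-average force profile
#'
#' Pointwise mean of the applied force k (lambda - xi) across
#' trajectories on a common guide grid.
#'
#' @param trajectories list of \code{\link{PullingTrajectory}}.
#' @param lambdaGrid common grid (default as in
#'   \code{\link{workEnsemble}}).
#' @return data.frame with columns \code{lambda} and \code{force}.
#' @export
averageForceProfile <- function(trajectories, lambdaGrid = NULL) {
  if (!length(trajectories)) .stopInput("empty trajectory ensemble")
  if (is.null(lambdaGrid)) {
    lo <- max(vapply(trajectories, function(tr) min(tr@lambda), numeric(1)))
    hi <- min(vapply(trajectories, function(tr) max(tr@lambda), numeric(1)))
    g <- trajectories[[1L]]@lambda
    lambdaGrid <- g[g >= lo - 1e-12 & g <= hi + 1e-12]
  }
  f <- vapply(trajectories, function(tr)
    .interp(tr@lambda, tr@force, lambdaGrid, "lambda grid"),
    numeric(length(lambdaGrid)))
  data.frame(lambda = lambdaGrid,
             force = rowMeans(matrix(f, nrow = length(lambdaGrid))))
}

#' @describeIn PMFProfile-class display method
#' @param object a \code{PMFProfile}.
#' @export
setMethod("show", "PMFProfile", function(object) {
  cat(sprintf(
    "PMFProfile (%s): %d points, xi in [%.3g, %.3g] A, Phi range [%.3g, %.3g] kcal/mol, k = %g\n",
    object@estimator, length(object@xi), min(object@xi), max(object@xi),
    min(object@phi), max(object@phi), object@k))
  if (length(object@lower))
    cat(sprintf("  bootstrap interval attached (mean width %.3g kcal/mol)\n",
                mean(object@upper - object@lower)))
})

#' Coerce a PMF profile to a data.frame
#'
#' @param x a \code{\link{PMFProfile}}.
#' @param ... ignored.
#' @return data.frame with \code{xi}, \code{phi}, \code{deltaA} and, when
#'   present, \code{lower}/\code{upper}.
#' @export
as.data.frame.PMFProfile <- function(x, ...) {
  out <- data.frame(xi = x@xi, phi = x@phi, deltaA = x@deltaA)
  if (length(x@lower)) { out$lower <- x@lower; out$upper <- x@upper }
  out
}
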