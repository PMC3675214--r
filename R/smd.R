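#' Specify a one-dimensional test potential
#'
#' Ground-truth potentials for validating the free-energy estimators:
#' \describe{
#'   \item{flat}{U = 0 everywhere; no parameters.}
#'   \item{harmonic}{U = a/2 (xi - c)^2; parameters \code{a}
#'     (kcal/(mol A^2)) and \code{c} (A).}
#'   \item{double-well}{U = h ((xi - c)^2 - w^2)^2 / w^4; parameters
#'     \code{h} (barrier height, kcal/mol), \code{c} (barrier position,
#'     A) and \code{w} (half well separation, A).}
#'   \item{piecewise-linear}{linear interpolation through knots; parameters
#'     alternate \code{x1, y1, x2, y2, ...}.}
#' }
#'
#' @param form potential form.
#' @param ... named parameters, see above.
#' @return A \code{\link{PotentialSpec}}.
#' @examples
#' potentialSpec("harmonic", a = 1, c = 0.5)
#' @export
potentialSpec <- function(form = c("flat", "harmonic", "double-well",
                                   "piecewise-linear"), ...) {
  form <- match.arg(form)
  p <- unlist(list(...))
  need <- switch(form, flat = character(),
                 harmonic = c("a", "c"),
                 `double-well` = c("h", "c", "w"),
                 `piecewise-linear` = character())
  if (!all(need %in% names(p)))
    .stopInput("potential '%s' needs parameters: %s", form,
               paste(need, collapse = ", "))
  if (form == "piecewise-linear" &&
      (length(p) < 4L || length(p) %% 2L != 0L))
    .stopInput("piecewise-linear potential needs x1,y1,x2,y2,... knots")
  new("PotentialSpec", form = form,
      parameters = if (length(p)) p else numeric())
}

#' Evaluate a test potential
#'
#' @param potential a \code{\link{PotentialSpec}}.
#' @param xi positions, A.
#' @return U(xi), kcal/mol.
#' @export
potentialEnergy <- function(potential, xi) {
  p <- potential@parameters
  switch(potential@form,
    flat = rep(0, length(xi)),
    harmonic = p[["a"]] / 2 * (xi - p[["c"]])^2,
    `double-well` = p[["h"]] * ((xi - p[["c"]])^2 - p[["w"]]^2)^2 /
      p[["w"]]^4,
    `piecewise-linear` = {
      kx <- p[seq(1L, length(p), 2L)]; ky <- p[seq(2L, length(p), 2L)]
      .interp(kx, ky, pmin(pmax(xi, min(kx)), max(kx)), "position")
    })
}

#' Gradient of a test potential
#'
#' @param potential a \code{\link{PotentialSpec}}.
#' @param xi positions, A.
#' @return dU/dxi, kcal/(mol A).
#' @export
potentialGradient <- function(potential, xi) {
  p <- potential@parameters
  switch(potential@form,
    flat = rep(0, length(xi)),
    harmonic = p[["a"]] * (xi - p[["c"]]),
    `double-well` = 4 * p[["h"]] * ((xi - p[["c"]])^2 - p[["w"]]^2) *
      (xi - p[["c"]]) / p[["w"]]^4,
    `piecewise-linear` = {
      kx <- p[seq(1L, length(p), 2L)]; ky <- p[seq(2L, length(p), 2L)]
      slopes <- diff(ky) / diff(kx)
      i <- pmin(pmax(findInterval(xi, kx), 1L), length(slopes))
      unname(slopes[i])
    })
}

## Largest curvature of the potential over a range (for the dt guard).
.maxCurvature <- function(potential, lo, hi) {
  p <- potential@parameters
  switch(potential@form,
    flat = 0,
    harmonic = abs(p[["a"]]),
    `piecewise-linear` = 0,
    {
      xi <- seq(lo, hi, length.out = 512L)
      g <- potentialGradient(potential, xi)
      max(abs(diff(g) / diff(xi)))
    })
}

#' Integrator settings for the synthetic pulling simulator
#'
#' @param gamma friction, kcal ns/(mol A^2) (default 1).
#' @param dt time step, ns (default 0.001).
#' @param temperature kelvin (default 310).
#' @param seed master seed; per-trajectory seeds are split from it by a
#'   fixed rule so each trajectory is independently reproducible.
#' @param M number of trajectories (default 50).
#' @param init initial reaction-coordinate distribution:
#'   \code{"equilibrium-in-guide"} (Boltzmann in the combined potential at
#'   the guide origin) or \code{"fixed"} (exactly at the guide origin).
#' @param stride record every \code{stride}-th step (default 10).
#' @return A \code{\link{LangevinParams}}.
#' @export
langevinParams <- function(gamma = 1, dt = 0.001, temperature = 310,
                           seed = 42, M = 50, init = "equilibrium-in-guide",
                           stride = 10) {
  new("LangevinParams", gamma = gamma, dt = dt, temperature = temperature,
      seed = as.numeric(seed), M = as.integer(M), init = init,
      stride = as.integer(stride))
}

## Boltzmann sampling of the combined potential on a fine grid
## (inverse-CDF over grid cells plus uniform jitter within a cell).
.sampleEquilibrium <- function(potential, protocol, beta, n) {
  width <- sqrt(1 / (beta * protocol@k))
  grid <- seq(protocol@lambda0 - 8 * width, protocol@lambda0 + 8 * width,
              length.out = 2048L)
  u <- potentialEnergy(potential, grid) +
    protocol@k / 2 * (grid - protocol@lambda0)^2
  w <- exp(-beta * (u - min(u)))
  cell <- sample.int(length(grid), n, replace = TRUE, prob = w)
  grid[cell] + stats::runif(n, -0.5, 0.5) * (grid[2L] - grid[1L])
}

#' Simulate a constant-velocity pulling ensemble
#'
#' Integrates an overdamped Langevin particle in the chosen potential,
#' dragged by the harmonic guide of the protocol, with the
#' Euler-Maruyama scheme
#' d xi = [-U'(xi) - k (xi - lambda(t))] dt / gamma
#'        + sqrt(2 dt / (beta gamma)) eta.
#' A stability guard requires dt (k + max U'') / gamma < 0.1.
#'
#' @param potential a \code{\link{PotentialSpec}}.
#' @param protocol a \code{\link{PullingProtocol}}.
#' @param params a \code{\link{LangevinParams}}.
#' @param pullDistance how far the guide travels, A.
#' @return List of \code{M} seeded, reproducible
#'   \code{\link{PullingTrajectory}} objects.
#' @examples
#' pot <- potentialSpec("harmonic", a = 1, c = 0.5)
#' trajs <- simulatePulling(pot, pullingProtocol(k = 50, v = 1),
#'                          langevinParams(M = 5), pullDistance = 1)
#' @export
simulatePulling <- function(potential, protocol, params = langevinParams(),
                            pullDistance = 1) {
  beta <- thermoParams(params@temperature)@beta
  lo <- protocol@lambda0
  hi <- lo + pullDistance
  curv <- .maxCurvature(potential, lo - 2, hi + 2)
  guard <- params@dt * (protocol@k + curv) / params@gamma
  if (guard >= 0.1)
    stop(sprintf(paste0("integration unstable: dt (k + max U'')/gamma = %.3g",
                        " >= 0.1; reduce dt below %.3g ns"),
                 guard, 0.1 * params@gamma / (protocol@k + curv)),
         call. = FALSE)
  nst <- ceiling(pullDistance / (protocol@v * params@dt))
  M <- params@M
  seeds <- .splitSeed(params@seed, M + 1L)
  ## per-trajectory noise streams and initial positions, then a vectorized
  ## lockstep time loop over the whole ensemble
  noise <- matrix(0, M, nst)
  for (i in seq_len(M))
    noise[i, ] <- .withSeed(seeds[i], stats::rnorm(nst))
  xi <- if (params@init == "fixed") rep(lo, M)
        else .withSeed(seeds[M + 1L],
                       .sampleEquilibrium(potential, protocol, beta, M))
  sigma <- sqrt(2 * params@dt / (beta * params@gamma))
  keep <- seq(0L, nst, by = params@stride)
  if (keep[length(keep)] != nst) keep <- c(keep, nst)
  xiRec <- matrix(0, M, length(keep))
  xiRec[, 1L] <- xi
  lam <- lo
  j <- 1L
  for (s in seq_len(nst)) {
    drift <- (-potentialGradient(potential, xi) -
                protocol@k * (xi - lam)) * params@dt / params@gamma
    xi <- xi + drift + sigma * noise[, s]
    lam <- lo + protocol@v * s * params@dt
    if (s == keep[j + 1L]) { j <- j + 1L; xiRec[, j] <- xi }
  }
  tRec <- keep * params@dt
  lamRec <- lo + protocol@v * tRec
  lapply(seq_len(M), function(i)
    pullingTrajectory(time = tRec, xi = xiRec[i, ], protocol = protocol,
                      lambda = lamRec,
                      source = sprintf("sim:seed=%d", as.integer(seeds[i]))))
}

#' Analytic ground-truth PMF of a test potential
#'
#' @param potential a \code{\link{PotentialSpec}}.
#' @param xi grid of reaction-coordinate values, A.
#' @return A \code{\link{PMFProfile}} holding U(xi) - U(xi[1]).
#' @export
groundTruthPMF <- function(potential, xi) {
  u <- potentialEnergy(potential, xi)
  new("PMFProfile", xi = xi, phi = u - u[1L], deltaA = u - u[1L],
      estimator = "analytic", k = NA_real_)
}

#' The default estimator-validation scenario
#'
#' A harmonic well (a = 1 kcal/(mol A^2)) centred halfway along a 1 A
#' pull, a stiff guide (k = 50 kcal/(mol A^2)) moving at 1 A/ns, friction
#' gamma = 1 kcal ns/(mol A^2), T = 310 K and M = 50 trajectories. The
#' short pull keeps the dissipated work (about gamma v times the pulled
#' distance, roughly 1 kcal/mol here) small enough that the Jarzynski
#' exponential average converges at this ensemble size, so the stiff-
#' spring, quasi-static analysis demonstrably holds; see the package
#' vignette for the sizing analysis.
#'
#' @param seed master seed (default 42).
#' @param v pulling velocity, A/ns (default 1).
#' @return List with elements \code{potential}, \code{protocol},
#'   \code{params} and \code{pullDistance}, ready to pass to
#'   \code{\link{simulatePulling}}.
#' @export
validationScenario <- function(seed = 42, v = 1) {
  list(potential = potentialSpec("harmonic", a = 1, c = 0.5),
       protocol = pullingProtocol(k = 50, v = v, lambda0 = 0,
                                  temperature = 310),
       params = langevinParams(gamma = 1, dt = 0.001, temperature = 310,
                               seed = seed, M = 50),
       pullDistance = 1)
}
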