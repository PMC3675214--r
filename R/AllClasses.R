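#' @import methods
NULL

## ---- mutation space ---------------------------------------------------

#' MutationRules: the chemical restriction on substitutions
#'
#' Substitutions are confined to the residue's chemical group, minus an
#' explicit exclusion list, with a cap on the number of simultaneous
#' mutations per peptide. Defaults encode the glycine-to-methionine
#' exclusion and a cap of four mutations.
#'
#' @slot exclusions character vector of directional exclusions in
#'   \code{"from>to"} form (default \code{"G>M"}).
#' @slot maxMutations integer cap on mutations per peptide (default 4).
#' @exportClass MutationRules
setClass("MutationRules",
         representation(exclusions = "character", maxMutations = "integer"),
         prototype(exclusions = "G>M", maxMutations = 4L),
         validity = function(object) {
           if (length(object@maxMutations) != 1L || is.na(object@maxMutations) ||
               object@maxMutations < 1L)
             return("maxMutations must be a positive integer")
           if (length(object@exclusions) &&
               !all(grepl("^[A-Z]>[A-Z]$", object@exclusions)))
             return("exclusions must look like \"G>M\"")
           TRUE
         })

#' CandidatePeptide: a sequence plus its mutation set and scores
#'
#' @slot sequence amino-acid string.
#' @slot mutations character vector in \code{"<from><pos><to>"} notation
#'   (e.g. \code{"G2V"}); empty for the reference peptide.
#' @slot level integer, number of mutations.
#' @slot scores named numeric vector of per-scorer scores.
#' @exportClass CandidatePeptide
setClass("CandidatePeptide",
         representation(sequence = "character", mutations = "character",
                        level = "integer", scores = "numeric"),
         prototype(mutations = character(), level = 0L, scores = numeric()),
         validity = function(object) {
           if (length(object@sequence) != 1L || !nzchar(object@sequence))
             return("sequence must be a single non-empty string")
           if (object@level != length(object@mutations))
             return("level must equal the number of mutations")
           TRUE
         })

## ---- scoring ----------------------------------------------------------

#' Scorer: the contract the search engine consumes
#'
#' A scorer is a pure function from a peptide sequence to a real number,
#' together with a name and a polarity stating which direction is
#' favorable. Docking-like scores are higher-is-better; free-energy-like
#' scores (e.g. rescoring in kJ/mol) are lower-is-better.
#'
#' @slot name scorer name.
#' @slot polarity \code{"higher"} or \code{"lower"} (is better).
#' @slot fun function taking a sequence string, returning a numeric score.
#' @exportClass Scorer
setClass("Scorer",
         representation(name = "character", polarity = "character",
                        fun = "function"),
         validity = function(object) {
           if (!object@polarity %in% c("higher", "lower"))
             return("polarity must be \"higher\" or \"lower\"")
           TRUE
         })

#' ScoreTable: externally computed scores keyed by sequence
#'
#' Adapter for score tables produced by an external program (e.g. docking
#' scores). Serialized as two-column TSV with a header line carrying the
#' scorer name and polarity.
#'
#' @slot scores named numeric vector (names are uppercase sequences).
#' @slot name scorer name.
#' @slot polarity \code{"higher"} or \code{"lower"}.
#' @exportClass ScoreTable
setClass("ScoreTable",
         representation(scores = "numeric", name = "character",
                        polarity = "character"),
         validity = function(object) {
           if (anyDuplicated(names(object@scores)))
             return("duplicate sequences in score table")
           if (length(object@scores) && !all(grepl("^[A-Z]+$", names(object@scores))))
             return("sequences must be uppercase one-letter strings")
           if (!object@polarity %in% c("higher", "lower"))
             return("polarity must be \"higher\" or \"lower\"")
           TRUE
         })

## ---- search -----------------------------------------------------------

#' SearchConfig: limits for the combine-score-accept search
#'
#' @slot maxLevel integer, highest mutation level admitted (default 4).
#' @slot maxCycles integer, number of combination cycles (default 2).
#' @slot targetSize optional integer; stop once the library reaches it
#'   (\code{NA} = no target).
#' @exportClass SearchConfig
setClass("SearchConfig",
         representation(maxLevel = "integer", maxCycles = "integer",
                        targetSize = "integer"),
         prototype(maxLevel = 4L, maxCycles = 2L, targetSize = NA_integer_),
         validity = function(object) {
           if (object@maxLevel < 1L) return("maxLevel must be >= 1")
           if (object@maxCycles < 0L) return("maxCycles must be >= 0")
           TRUE
         })

#' CandidateLibrary: the growing inhibitor candidate library (ICL)
#'
#' Holds the reference peptide with its score, the accepted members with
#' provenance, a cache of scored-and-rejected sequences, and a per-cycle
#' log. Members are unique by sequence and every member strictly improves
#' on the reference under the primary scorer.
#'
#' @slot reference reference peptide sequence.
#' @slot referenceScore its primary score.
#' @slot scorerName name of the primary scorer.
#' @slot polarity polarity of the primary scorer.
#' @slot members data.frame with columns \code{sequence}, \code{mutations}
#'   (\code{"+"}-joined notation), \code{level}, \code{cycle},
#'   \code{score}, \code{secondary}, \code{parents}.
#' @slot rejected named numeric vector of scored-but-rejected sequences.
#' @slot log data.frame of per-cycle counts.
#' @exportClass CandidateLibrary
setClass("CandidateLibrary",
         representation(reference = "character", referenceScore = "numeric",
                        scorerName = "character", polarity = "character",
                        members = "data.frame", rejected = "numeric",
                        log = "data.frame"),
         validity = function(object) {
           m <- object@members
           need <- c("sequence", "mutations", "level", "cycle", "score",
                     "secondary", "parents")
           if (!all(need %in% names(m)))
             return(paste("members must have columns:",
                          paste(need, collapse = ", ")))
           if (anyDuplicated(m$sequence)) return("duplicate member sequences")
           if (any(m$sequence == object@reference))
             return("the reference cannot be a member")
           ok <- if (object@polarity == "higher")
             m$score > object@referenceScore else m$score < object@referenceScore
           if (length(ok) && !all(ok))
             return("every member must strictly improve on the reference")
           TRUE
         })

## ---- pulling / PMF ----------------------------------------------------

#' ThermoParams: temperature and inverse temperature
#'
#' @slot temperature kelvin.
#' @slot kB Boltzmann constant, kcal/(mol K).
#' @slot beta 1/(kB T), mol/kcal.
#' @exportClass ThermoParams
setClass("ThermoParams",
         representation(temperature = "numeric", kB = "numeric",
                        beta = "numeric"),
         validity = function(object) {
           if (object@temperature <= 0) return("temperature must be > 0")
           if (abs(object@beta * object@kB * object@temperature - 1) > 1e-12)
             return("beta inconsistent with kB and temperature")
           TRUE
         })

#' PullingProtocol: the constant-velocity guide schedule
#'
#' The guide (dummy-atom) position moves as lambda(t) = lambda0 + v t and
#' is coupled to the reaction coordinate by a harmonic spring.
#'
#' @slot k spring constant, kcal/(mol A^2).
#' @slot v pulling velocity, A/ns.
#' @slot lambda0 guide origin, A.
#' @slot temperature kelvin.
#' @exportClass PullingProtocol
setClass("PullingProtocol",
         representation(k = "numeric", v = "numeric", lambda0 = "numeric",
                        temperature = "numeric"),
         prototype(k = 5, v = 1, lambda0 = 0, temperature = 310),
         validity = function(object) {
           if (object@k <= 0) return("spring constant k must be > 0")
           if (object@v <= 0) return("pulling velocity v must be > 0")
           TRUE
         })

#' PullingTrajectory: one constant-velocity pulling run
#'
#' @slot time sampling times, ns, strictly increasing.
#' @slot lambda guide positions, A (must match the protocol schedule).
#' @slot xi reaction-coordinate values, A.
#' @slot force applied force k(lambda - xi), kcal/(mol A).
#' @slot protocol the \code{PullingProtocol}.
#' @slot source provenance string (file name or simulator seed).
#' @exportClass PullingTrajectory
setClass("PullingTrajectory",
         representation(time = "numeric", lambda = "numeric", xi = "numeric",
                        force = "numeric", protocol = "PullingProtocol",
                        source = "character"),
         prototype(source = NA_character_),
         validity = function(object) {
           n <- length(object@time)
           if (n < 2L) return("a trajectory needs at least two samples")
           if (length(object@lambda) != n || length(object@xi) != n ||
               length(object@force) != n)
             return("time, lambda, xi, force must have equal length")
           if (any(diff(object@time) <= 0))
             return("time must be strictly increasing")
           TRUE
         })

#' WorkEnsemble: per-trajectory work resampled onto a common guide grid
#'
#' @slot lambda common guide-position grid, A.
#' @slot work M x G matrix of accumulated work, kcal/mol; one row per
#'   trajectory, zero at the grid start.
#' @slot protocol the shared \code{PullingProtocol}.
#' @exportClass WorkEnsemble
setClass("WorkEnsemble",
         representation(lambda = "numeric", work = "matrix",
                        protocol = "PullingProtocol"),
         validity = function(object) {
           if (ncol(object@work) != length(object@lambda))
             return("work must have one column per grid point")
           if (any(diff(object@lambda) <= 0))
             return("lambda grid must be strictly increasing")
           TRUE
         })

#' PMFProfile: free-energy profile along the reaction coordinate
#'
#' @slot xi reaction-coordinate grid, A.
#' @slot phi potential of mean force, kcal/mol, anchored to 0 at the
#'   grid start.
#' @slot deltaA intermediate free-energy profile along the guide, kcal/mol.
#' @slot estimator \code{"jarzynski"} or \code{"cumulant2"}.
#' @slot lower,upper bootstrap interval bounds (empty when not computed).
#' @slot k guide spring constant, recorded so stiffness validity can be
#'   assessed downstream.
#' @exportClass PMFProfile
setClass("PMFProfile",
         representation(xi = "numeric", phi = "numeric", deltaA = "numeric",
                        estimator = "character", lower = "numeric",
                        upper = "numeric", k = "numeric"),
         prototype(lower = numeric(), upper = numeric()),
         validity = function(object) {
           if (length(object@phi) != length(object@xi))
             return("phi and xi must have equal length")
           if (length(object@lower) &&
               any(object@upper - object@lower < -1e-12))
             return("interval bounds must satisfy lower <= upper")
           TRUE
         })

## ---- synthetic pulling ------------------------------------------------

#' PotentialSpec: a one-dimensional test potential
#'
#' @slot form one of \code{"flat"}, \code{"harmonic"}, \code{"double-well"},
#'   \code{"piecewise-linear"}.
#' @slot parameters named numeric vector; see \code{\link{potentialSpec}}.
#' @exportClass PotentialSpec
setClass("PotentialSpec",
         representation(form = "character", parameters = "numeric"),
         validity = function(object) {
           if (!object@form %in% c("flat", "harmonic", "double-well",
                                   "piecewise-linear"))
             return("unknown potential form")
           TRUE
         })

#' LangevinParams: integrator settings for the synthetic pulling simulator
#'
#' @slot gamma friction, kcal ns/(mol A^2).
#' @slot dt time step, ns.
#' @slot temperature kelvin.
#' @slot seed master seed; per-trajectory seeds are split from it.
#' @slot M number of trajectories.
#' @slot init \code{"equilibrium-in-guide"} or \code{"fixed"}.
#' @slot stride record every \code{stride}-th step.
#' @exportClass LangevinParams
setClass("LangevinParams",
         representation(gamma = "numeric", dt = "numeric",
                        temperature = "numeric", seed = "numeric",
                        M = "integer", init = "character", stride = "integer"),
         prototype(gamma = 1, dt = 0.001, temperature = 310, seed = 42,
                   M = 50L, init = "equilibrium-in-guide", stride = 10L),
         validity = function(object) {
           if (object@gamma <= 0) return("gamma must be > 0")
           if (object@dt <= 0) return("dt must be > 0")
           if (object@M < 1L) return("M must be >= 1")
           if (!object@init %in% c("equilibrium-in-guide", "fixed"))
             return("init must be \"equilibrium-in-guide\" or \"fixed\"")
           TRUE
         })
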