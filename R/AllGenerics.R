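#' Score a peptide sequence with a scorer
#'
#' @param scorer a \code{\link{Scorer}}.
#' @param sequence a peptide sequence string or a
#'   \code{\link{CandidatePeptide}}.
#' @return Numeric score.
#' @export
setGeneric("scoreSequence", function(scorer, sequence)
  standardGeneric("scoreSequence"))

#' Accumulated external work of a pulling run
#'
#' Evaluates W(t) = v * integral of k (lambda - xi) dt by trapezoidal
#' quadrature on the recorded sample times; W at the first sample is 0.
#'
#' @param trajectory a \code{\link{PullingTrajectory}}.
#' @return Numeric vector of accumulated work, kcal/mol, one value per
#'   sample.
#' @export
setGeneric("computeWork", function(trajectory)
  standardGeneric("computeWork"))

#' Number of members of a candidate library
#' @param x a \code{\link{CandidateLibrary}}.
#' @return Integer count.
#' @export
setGeneric("libSize", function(x) standardGeneric("libSize"))

#' Per-level member counts (n1..nLmax) of a candidate library
#' @param x a \code{\link{CandidateLibrary}}.
#' @return Named integer vector \code{c(n1 = ..., n2 = ..., ...)}.
#' @export
setGeneric("levelCounts", function(x) standardGeneric("levelCounts"))
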