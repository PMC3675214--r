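#' Construct a scorer from a score function
#'
#' @param name scorer name.
#' @param polarity \code{"higher"} or \code{"lower"} (is better).
#' @param fun function mapping a sequence string to a numeric score.
#'   Scorers must be pure: the same sequence always scores the same.
#' @return A \code{\link{Scorer}}.
#' @export
scorer <- function(name, polarity, fun) {
  new("Scorer", name = name, polarity = match.arg(polarity,
      c("higher", "lower")), fun = fun)
}

#' @rdname scoreSequence
#' @export
setMethod("scoreSequence", signature("Scorer", "character"),
          function(scorer, sequence) {
  val <- scorer@fun(sequence)
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
    .stopInput("scorer '%s' failed on sequence %s", scorer@name, sequence)
  as.numeric(val)
})

#' @rdname scoreSequence
#' @export
setMethod("scoreSequence", signature("Scorer", "CandidatePeptide"),
          function(scorer, sequence)
  scoreSequence(scorer, sequence@sequence))

#' Is a candidate score a strict improvement over the reference?
#'
#' Acceptance into the candidate library demands a strict improvement in
#' the scorer's favorable direction; ties are rejected.
#'
#' @param candidateScore,referenceScore numeric scores from the same
#'   scorer.
#' @param polarity \code{"higher"} or \code{"lower"} (is better).
#' @return Logical.
#' @examples
#' isImprovement(67.56, 49.12, "higher")   # TRUE
#' isImprovement(-15.01, -7.13, "lower")   # TRUE
#' isImprovement(49.12, 49.12, "higher")   # FALSE (tie)
#' @export
isImprovement <- function(candidateScore, referenceScore,
                          polarity = c("higher", "lower")) {
  polarity <- match.arg(polarity)
  if (polarity == "higher") candidateScore > referenceScore
  else candidateScore < referenceScore
}

## ---- score tables -----------------------------------------------------

#' Construct a score table
#'
#' @param scores named numeric vector; names are peptide sequences.
#' @param name scorer name.
#' @param polarity \code{"higher"} or \code{"lower"}.
#' @return A \code{\link{ScoreTable}}.
#' @export
scoreTable <- function(scores, name = "table",
                       polarity = c("higher", "lower")) {
  names(scores) <- toupper(names(scores))
  new("ScoreTable", scores = scores, name = name,
      polarity = match.arg(polarity))
}

#' Look up a peptide's score in a score table
#'
#' @param peptide a sequence string or \code{\link{CandidatePeptide}}.
#' @param table a \code{\link{ScoreTable}}.
#' @return The stored score, unchanged.
#' @export
scoreFromTable <- function(peptide, table) {
  seqc <- if (is(peptide, "CandidatePeptide")) peptide@sequence else peptide
  if (!seqc %in% names(table@scores))
    .stopInput("sequence %s not present in score table '%s'",
               seqc, table@name)
  unname(table@scores[[seqc]])
}

#' Wrap a score table as a scorer
#'
#' @param table a \code{\link{ScoreTable}}.
#' @return A \code{\link{Scorer}} that looks sequences up in the table and
#'   errors, naming the sequence, on a miss.
#' @export
tableScorer <- function(table) {
  scorer(table@name, table@polarity,
         function(s) scoreFromTable(s, table))
}

#' Read a score table from TSV
#'
#' Expects two tab-separated columns \code{sequence} and \code{score} and
#' a header line \code{# scorer=<name> polarity=<higher|lower>}.
#'
#' @param path file path.
#' @return A \code{\link{ScoreTable}}.
#' @export
readScoreTable <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- c(scorer = "table", polarity = "higher")
  if (length(hdr)) {
    kv <- regmatches(hdr[1L],
                     gregexpr("[A-Za-z_]+=[^ \t]+", hdr[1L]))[[1L]]
    for (x in kv) {
      key <- sub("=.*", "", x)
      meta[key] <- sub(".*=", "", x)
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body))
    return(scoreTable(stats::setNames(numeric(), character()),
                      meta[["scorer"]], meta[["polarity"]]))
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    .stopInput("malformed score table line: %s",
               body[which(lengths(parts) < 2L)[1L]])
  scores <- as.numeric(vapply(parts, `[`, "", 2L))
  names(scores) <- vapply(parts, `[`, "", 1L)
  if (anyNA(scores)) .stopInput("non-numeric score in %s", path)
  scoreTable(scores, meta[["scorer"]], meta[["polarity"]])
}

#' Write a score table to TSV
#'
#' Scores are written with six fractional digits, so decimal inputs with
#' at most six fractional digits round-trip bit-identically.
#'
#' @param table a \code{\link{ScoreTable}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeScoreTable <- function(table, path) {
  lines <- c(sprintf("# scorer=%s polarity=%s", table@name, table@polarity),
             sprintf("%s\t%s", names(table@scores),
                     sprintf("%.6f", table@scores)))
  writeLines(lines, path)
  invisible(path)
}

## ---- surrogate groove scorer -----------------------------------------

#' Parameters of the surrogate groove-complementarity scorer
#'
#' A groove-binding peptide of the xGxFxGxF type presents alternating
#' faces: the even positions pack against the fibril groove while the odd
#' positions face the solvent and carry solubility. The surrogate scorer
#' rewards hydrophobic contact-face residues and hydrophilic solvent-face
#' residues. It exists so the full pipeline runs without proprietary
#' docking software; it is deliberately simple, non-physical, and makes no
#' claim to reproduce docking-score rankings.
#'
#' @param contact 1-based contact-face positions (default \code{c(2,4,6,8)}).
#' @param solvent 1-based solvent-face positions (default \code{c(1,3,5,7)}).
#' @param wc,ws face weights (defaults 1).
#' @return A list of class \code{"SurrogateParams"}.
#' @export
surrogateParams <- function(contact = c(2, 4, 6, 8),
                            solvent = c(1, 3, 5, 7),
                            wc = 1, ws = 1) {
  if (length(intersect(contact, solvent)))
    .stopInput("contact and solvent faces must be disjoint")
  structure(list(contact = as.integer(contact),
                 solvent = as.integer(solvent), wc = wc, ws = ws),
            class = "SurrogateParams")
}

#' Surrogate groove-complementarity score
#'
#' Computes \code{wc * sum(h[contact]) - ws * sum(h[solvent])} where h is
#' the Kyte-Doolittle hydropathy. Higher is better. The score is additive
#' over positions: a single substitution changes it by exactly the
#' hydropathy delta times the face weight.
#'
#' @param peptide a sequence string or \code{\link{CandidatePeptide}}.
#' @param params a \code{\link{surrogateParams}} object.
#' @return Numeric score.
#' @examples
#' surrogateGrooveScore("RGTFEGKF")   # 17.4
#' @export
surrogateGrooveScore <- function(peptide, params = surrogateParams()) {
  seqc <- if (is(peptide, "CandidatePeptide")) peptide@sequence else peptide
  aa <- .checkSequence(seqc, "peptide")
  idx <- c(params$contact, params$solvent)
  if (any(idx < 1L | idx > length(aa)))
    .stopInput("face position out of range for a %d-mer", length(aa))
  if (!setequal(idx, seq_along(aa)))
    .stopInput("faces must cover every position of a %d-mer exactly once",
               length(aa))
  h <- hydropathy(aa)
  params$wc * sum(h[params$contact]) - params$ws * sum(h[params$solvent])
}

#' Surrogate scorer object
#'
#' @param params a \code{\link{surrogateParams}} object.
#' @return A \code{\link{Scorer}} with polarity higher-is-better.
#' @export
surrogateScorer <- function(params = surrogateParams()) {
  scorer("surrogate", "higher",
         function(s) surrogateGrooveScore(s, params))
}

## ---- mock scorer ------------------------------------------------------

#' Seedable additive mock scorer for tests and demonstrations
#'
#' Assigns the reference a base score and every allowed single mutation a
#' gain drawn from a seeded normal distribution; an arbitrary peptide's
#' score is the base plus the gains of its mutations plus optional
#' pairwise interaction terms. Deterministic for a given seed, so search
#' behaviour is exactly reproducible.
#'
#' @param reference reference peptide sequence.
#' @param seed integer seed.
#' @param rules a \code{\link{MutationRules}} (determines the allowed
#'   mutations that receive gains).
#' @param base reference score.
#' @param gainSd standard deviation of per-mutation gains.
#' @param interactionSd standard deviation of pairwise interaction terms
#'   (0 disables them).
#' @return A \code{\link{Scorer}} with polarity higher-is-better.
#' @export
mockScorer <- function(reference, seed, rules = mutationRules(),
                       base = 0, gainSd = 1, interactionSd = 0) {
  .checkSequence(reference, "reference")
  singles <- enumerateSingleMutations(reference, rules)
  pairs <- if (length(singles) >= 2L) utils::combn(singles, 2L) else
    matrix(character(), 2L, 0L)
  gains <- .withSeed(seed, {
    g <- stats::setNames(stats::rnorm(length(singles), sd = gainSd), singles)
    w <- if (interactionSd > 0 && ncol(pairs))
      stats::setNames(stats::rnorm(ncol(pairs), sd = interactionSd),
                      paste(pairs[1L, ], pairs[2L, ], sep = "&"))
      else stats::setNames(numeric(), character())
    list(g = g, w = w)
  })
  scorer(sprintf("mock:%d", as.integer(seed)), "higher", function(s) {
    muts <- .sortMutations(diffMutations(reference, s))
    if (!all(muts %in% names(gains$g)))
      .stopInput("sequence %s is outside the mock scorer's mutation space", s)
    val <- base + sum(gains$g[muts])
    if (length(gains$w) && length(muts) >= 2L) {
      pp <- utils::combn(muts, 2L)
      keys <- paste(pp[1L, ], pp[2L, ], sep = "&")
      val <- val + sum(gains$w[intersect(keys, names(gains$w))])
    }
    val
  })
}

#' @describeIn Scorer-class display method
#' @param object a \code{Scorer}.
#' @export
setMethod("show", "Scorer", function(object)
  cat(sprintf("Scorer '%s' (%s-is-better)\n", object@name, object@polarity)))

#' @describeIn ScoreTable-class display method
#' @param object a \code{ScoreTable}.
#' @export
setMethod("show", "ScoreTable", function(object)
  cat(sprintf("ScoreTable '%s' (%s-is-better), %d sequences\n",
              object@name, object@polarity, length(object@scores))))
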