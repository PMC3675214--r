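#' Construct search limits
#'
#' @param maxLevel highest mutation level admitted into the library
#'   (default 4).
#' @param maxCycles number of combination cycles to run (default 2).
#' @param targetSize optional library-size target; the search stops after
#'   the cycle in which it is reached.
#' @return A \code{\link{SearchConfig}}.
#' @export
searchConfig <- function(maxLevel = 4, maxCycles = 2, targetSize = NA) {
  new("SearchConfig", maxLevel = as.integer(maxLevel),
      maxCycles = as.integer(maxCycles), targetSize = as.integer(targetSize))
}

.emptyMembers <- function() {
  data.frame(sequence = character(), mutations = character(),
             level = integer(), cycle = integer(), score = numeric(),
             secondary = numeric(), parents = character(),
             stringsAsFactors = FALSE)
}

#' Initialize the inhibitor candidate library (ICL)
#'
#' Scores the reference and every allowed single mutant; the mutants whose
#' primary score strictly improves on the reference become the initial
#' library (their count is n1).
#'
#' @param reference reference peptide sequence.
#' @param scorer the primary \code{\link{Scorer}}.
#' @param rules a \code{\link{MutationRules}}.
#' @param veto optional keep-predicate applied to improving candidates,
#'   see \code{\link{combinationCycle}}.
#' @return A \code{\link{CandidateLibrary}}.
#' @export
initializeLibrary <- function(reference, scorer, rules = mutationRules(),
                              veto = NULL) {
  refScore <- scoreSequence(scorer, reference)
  singles <- enumerateSingleMutations(reference, rules)
  members <- .emptyMembers()
  rejected <- numeric()
  nVeto <- 0L
  for (mut in singles) {
    pep <- applyMutations(reference, mut)
    sc <- scoreSequence(scorer, pep)
    if (!isImprovement(sc, refScore, scorer@polarity)) {
      rejected[pep@sequence] <- sc
    } else if (!is.null(veto) && !isTRUE(veto(pep))) {
      rejected[pep@sequence] <- sc
      nVeto <- nVeto + 1L
    } else {
      members[nrow(members) + 1L, ] <-
        list(pep@sequence, mut, 1L, 0L, sc, NA_real_, "")
    }
  }
  log <- data.frame(cycle = 0L, tried = length(singles),
                    accepted = nrow(members),
                    rej_score = length(rejected) - nVeto, rej_conflict = 0L,
                    rej_cap = 0L, rej_nonew = 0L, rej_duplicate = 0L,
                    rej_veto = nVeto)
  new("CandidateLibrary", reference = reference, referenceScore = refScore,
      scorerName = scorer@name, polarity = scorer@polarity,
      members = members, rejected = rejected, log = log)
}

#' Assemble a candidate library from externally scored sequences
#'
#' Builds a \code{\link{CandidateLibrary}} directly from a set of member
#' sequences and a primary scorer (typically a score table from an
#' external docking program). Mutation sets and levels are reconstructed
#' by diffing against the reference; every member must strictly improve
#' on the reference.
#'
#' @param reference reference peptide sequence.
#' @param sequences member sequences.
#' @param scorer the primary \code{\link{Scorer}}.
#' @return A \code{\link{CandidateLibrary}}.
#' @export
candidateLibrary <- function(reference, sequences, scorer) {
  refScore <- scoreSequence(scorer, reference)
  members <- .emptyMembers()
  for (s in sequences) {
    muts <- .sortMutations(diffMutations(reference, s))
    sc <- scoreSequence(scorer, s)
    if (!isImprovement(sc, refScore, scorer@polarity))
      .stopInput("sequence %s (%.4g) does not improve on the reference (%.4g)",
                 s, sc, refScore)
    members[nrow(members) + 1L, ] <-
      list(toupper(s), paste(muts, collapse = "+"),
           length(muts), 0L, sc, NA_real_, "")
  }
  log <- data.frame(cycle = 0L, tried = length(sequences),
                    accepted = nrow(members), rej_score = 0L,
                    rej_conflict = 0L, rej_cap = 0L, rej_nonew = 0L,
                    rej_duplicate = 0L, rej_veto = 0L)
  new("CandidateLibrary", reference = reference, referenceScore = refScore,
      scorerName = scorer@name, polarity = scorer@polarity,
      members = members, rejected = numeric(), log = log)
}

## Split a "+"-joined mutation string back into a set.
.mutSet <- function(x) {
  if (nzchar(x)) strsplit(x, "+", fixed = TRUE)[[1L]] else character()
}

#' Run one combination cycle over the current library
#'
#' Forms the pairwise unions of the mutation sets of the members present
#' at cycle start and scores the new sequences. Only pairs involving a
#' member added in the previous cycle are formed; pairs of longer standing
#' were exhausted in an earlier cycle (so cycle 1 combines the accepted
#' singles, cycle 2 the 1+2 and 2+2 combinations, and so on). Newly
#' accepted members do not pair within the cycle that accepts them.
#' Improvements over the reference are appended; the input library is not
#' modified.
#'
#' @param library a \code{\link{CandidateLibrary}}.
#' @param scorer the primary \code{\link{Scorer}} (must match the one the
#'   library was built with).
#' @param rules a \code{\link{MutationRules}}.
#' @param maxLevel level cap for this cycle (default: the rules cap).
#' @param veto optional predicate taking a \code{CandidatePeptide} and
#'   returning \code{TRUE} to keep it; models discarding candidates whose
#'   poses do not fit the groove. Default keeps everything.
#' @return A new \code{\link{CandidateLibrary}}.
#' @export
combinationCycle <- function(library, scorer, rules = mutationRules(),
                             maxLevel = rules@maxMutations, veto = NULL) {
  if (scorer@name != library@scorerName)
    .stopInput("scorer '%s' does not match the library's primary scorer '%s'",
               scorer@name, library@scorerName)
  cycle <- max(library@log$cycle) + 1L
  m <- library@members
  members <- m
  rejected <- library@rejected
  cap <- min(rules@maxMutations, maxLevel)
  capRules <- new("MutationRules", exclusions = rules@exclusions,
                  maxMutations = as.integer(cap))
  counts <- c(tried = 0L, accepted = 0L, rej_score = 0L, rej_conflict = 0L,
              rej_cap = 0L, rej_nonew = 0L, rej_duplicate = 0L, rej_veto = 0L)
  n <- nrow(m)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    ## pairs fully enumerated in an earlier cycle are skipped
    if (max(m$cycle[i], m$cycle[j]) != cycle - 1L) next
    counts["tried"] <- counts["tried"] + 1L
    comb <- combineMutationSets(.mutSet(m$mutations[i]),
                                .mutSet(m$mutations[j]), capRules)
    if (!comb$accepted) {
      key <- paste0("rej_", c(`position-conflict` = "conflict",
                              `over-cap` = "cap",
                              `no-new-mutation` = "nonew")[comb$reason])
      counts[key] <- counts[key] + 1L
      next
    }
    pep <- applyMutations(library@reference, comb$mutations)
    prov <- paste(m$mutations[i], m$mutations[j], sep = "|")
    hit <- match(pep@sequence, members$sequence)
    if (!is.na(hit)) {
      ## reachable via several parent pairs: record provenance, add nothing
      if (!grepl(prov, members$parents[hit], fixed = TRUE))
        members$parents[hit] <- paste(members$parents[hit], prov, sep = ";")
      counts["rej_duplicate"] <- counts["rej_duplicate"] + 1L
      next
    }
    if (pep@sequence %in% names(rejected)) {
      counts["rej_duplicate"] <- counts["rej_duplicate"] + 1L
      next
    }
    sc <- scoreSequence(scorer, pep)
    if (!isImprovement(sc, library@referenceScore, library@polarity)) {
      rejected[pep@sequence] <- sc
      counts["rej_score"] <- counts["rej_score"] + 1L
      next
    }
    if (!is.null(veto) && !isTRUE(veto(pep))) {
      rejected[pep@sequence] <- sc
      counts["rej_veto"] <- counts["rej_veto"] + 1L
      next
    }
    members[nrow(members) + 1L, ] <-
      list(pep@sequence, paste(comb$mutations, collapse = "+"),
           pep@level, cycle, sc, NA_real_, prov)
    counts["accepted"] <- counts["accepted"] + 1L
  }
  log <- rbind(library@log,
               data.frame(cycle = cycle, tried = counts[["tried"]],
                          accepted = counts[["accepted"]],
                          rej_score = counts[["rej_score"]],
                          rej_conflict = counts[["rej_conflict"]],
                          rej_cap = counts[["rej_cap"]],
                          rej_nonew = counts[["rej_nonew"]],
                          rej_duplicate = counts[["rej_duplicate"]],
                          rej_veto = counts[["rej_veto"]]))
  initialize(library, members = members, rejected = rejected, log = log)
}

#' Run the full combine-score-accept search
#'
#' Initializes the library with the accepted single mutants, then runs
#' combination cycles until the cycle budget is spent, a cycle adds no
#' member, or the size target is reached.
#'
#' @param reference reference peptide sequence.
#' @param scorer the primary \code{\link{Scorer}}.
#' @param rules a \code{\link{MutationRules}}.
#' @param config a \code{\link{SearchConfig}}.
#' @param veto optional keep-predicate, see \code{\link{combinationCycle}}.
#' @return A \code{\link{CandidateLibrary}} with full provenance and a
#'   per-cycle log.
#' @examples
#' sc <- mockScorer("RGTF", seed = 1)
#' lib <- runSearch("RGTF", sc)
#' levelCounts(lib)
#' @export
runSearch <- function(reference, scorer, rules = mutationRules(),
                      config = searchConfig(), veto = NULL) {
  lib <- initializeLibrary(reference, scorer, rules, veto = veto)
  for (cyc in seq_len(config@maxCycles)) {
    if (!is.na(config@targetSize) && libSize(lib) >= config@targetSize) break
    before <- libSize(lib)
    lib <- combinationCycle(lib, scorer, rules,
                            maxLevel = config@maxLevel, veto = veto)
    if (libSize(lib) == before) break
  }
  lib
}

#' Rescore the library with a second scorer and filter
#'
#' Scores the reference and every member with the second scorer; members
#' that strictly improve on the reference survive, sorted best-first in
#' the second scorer's favorable direction.
#'
#' @param library a \code{\link{CandidateLibrary}}.
#' @param secondScorer a \code{\link{Scorer}}.
#' @return A data.frame with columns \code{sequence}, \code{mutations},
#'   \code{level}, \code{primary} and \code{secondary}, ranked by the
#'   secondary score.
#' @export
rescoreAndFilter <- function(library, secondScorer) {
  refSecond <- scoreSequence(secondScorer, library@reference)
  m <- library@members
  second <- vapply(m$sequence, function(s) scoreSequence(secondScorer, s),
                   numeric(1))
  keep <- isImprovement(second, refSecond, secondScorer@polarity)
  out <- data.frame(sequence = m$sequence[keep],
                    mutations = m$mutations[keep],
                    level = m$level[keep],
                    primary = m$score[keep],
                    secondary = unname(second[keep]),
                    stringsAsFactors = FALSE)
  ord <- order(out$secondary,
               decreasing = (secondScorer@polarity == "higher"))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "referenceSecondary") <- refSecond
  out
}

## ---- accessors --------------------------------------------------------

#' @rdname libSize
#' @export
setMethod("libSize", "CandidateLibrary", function(x) nrow(x@members))

#' @rdname levelCounts
#' @export
setMethod("levelCounts", "CandidateLibrary", function(x) {
  lmax <- max(4L, if (nrow(x@members)) max(x@members$level) else 0L)
  counts <- vapply(seq_len(lmax), function(l) sum(x@members$level == l),
                   integer(1))
  stats::setNames(counts, paste0("n", seq_len(lmax)))
})

#' Members of a candidate library
#' @param x a \code{\link{CandidateLibrary}}.
#' @return data.frame of members with provenance.
#' @export
libraryMembers <- function(x) x@members

#' Per-cycle log of a search
#' @param x a \code{\link{CandidateLibrary}}.
#' @return data.frame with per-cycle acceptance and rejection counts.
#' @export
searchLog <- function(x) x@log

#' Reference peptide of a library, with its primary score
#' @param x a \code{\link{CandidateLibrary}}.
#' @return A \code{\link{CandidatePeptide}}.
#' @export
referencePeptide <- function(x) {
  new("CandidatePeptide", sequence = x@reference, mutations = character(),
      level = 0L,
      scores = stats::setNames(x@referenceScore, x@scorerName))
}

#' @describeIn CandidateLibrary-class display method
#' @param object a \code{CandidateLibrary}.
#' @export
setMethod("show", "CandidateLibrary", function(object) {
  lc <- levelCounts(object)
  cat(sprintf("CandidateLibrary: reference %s (%s = %.4g, %s-is-better)\n",
              object@reference, object@scorerName, object@referenceScore,
              object@polarity))
  cat(sprintf("  N = %d members (%s); %d sequences scored and rejected\n",
              libSize(object),
              paste(sprintf("%s=%d", names(lc), lc), collapse = ", "),
              length(object@rejected)))
})
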