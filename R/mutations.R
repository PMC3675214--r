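#' Construct mutation rules
#'
#' @param exclusions character vector of forbidden substitutions in
#'   \code{"from>to"} form. Exclusions are directional: the default
#'   \code{"G>M"} forbids glycine-to-methionine but not the reverse.
#' @param maxMutations cap on simultaneous mutations per peptide.
#' @return A \code{\link{MutationRules}} object.
#' @examples
#' mutationRules()                      # defaults: G>M excluded, cap 4
#' mutationRules(exclusions = character(), maxMutations = 2)
#' @export
mutationRules <- function(exclusions = "G>M", maxMutations = 4) {
  new("MutationRules", exclusions = as.character(exclusions),
      maxMutations = as.integer(maxMutations))
}

#' Parse mutation notation
#'
#' Parses \code{"<from><position><to>"} strings such as \code{"G2V"} into a
#' data.frame. Positions are 1-based.
#'
#' @param notation character vector of mutation strings.
#' @return data.frame with columns \code{pos}, \code{from}, \code{to}.
#' @examples
#' parseMutations(c("G2V", "F4W"))
#' @export
parseMutations <- function(notation) {
  if (!length(notation))
    return(data.frame(pos = integer(), from = character(),
                      to = character(), stringsAsFactors = FALSE))
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", notation)
  if (!all(ok))
    .stopInput("malformed mutation notation: %s",
               paste(notation[!ok], collapse = ", "))
  data.frame(
    pos = as.integer(gsub("[A-Z]", "", notation)),
    from = substr(notation, 1L, 1L),
    to = substring(notation, nchar(notation)),
    stringsAsFactors = FALSE)
}

#' Format mutations as notation strings
#'
#' @param pos 1-based positions.
#' @param from,to one-letter residue codes.
#' @return Character vector like \code{"G2V"}.
#' @export
formatMutations <- function(pos, from, to) {
  if (!length(pos)) return(character())
  sprintf("%s%d%s", from, as.integer(pos), to)
}

## Sort a mutation set canonically: by position, then target residue.
.sortMutations <- function(notation) {
  m <- parseMutations(notation)
  notation[order(m$pos, m$to)]
}

## Allowed target residues for one reference residue under the rules.
.allowedTargets <- function(from, rules) {
  grp <- residueGroup(from)
  targets <- setdiff(.AA_GROUPS[[grp]], from)
  excl <- sub(">.*", "", rules@exclusions) == from
  targets <- setdiff(targets, sub(".*>", "", rules@exclusions[excl]))
  sort(targets)
}

#' Enumerate all allowed single-residue mutations
#'
#' Every substitution of one reference residue by another member of its
#' chemical group, minus the exclusion list. The order is deterministic:
#' by position, then alphabetical target residue.
#'
#' @param reference reference peptide sequence (one-letter codes).
#' @param rules a \code{\link{MutationRules}} object.
#' @return Character vector of mutations in \code{"G2V"} notation.
#' @examples
#' length(enumerateSingleMutations("RGTFEGKF"))  # 23
#' enumerateSingleMutations("E")                 # "E1D"
#' @export
enumerateSingleMutations <- function(reference, rules = mutationRules()) {
  aa <- .checkSequence(reference, "reference")
  out <- lapply(seq_along(aa), function(i) {
    formatMutations(rep(i, length(.allowedTargets(aa[i], rules))),
                    aa[i], .allowedTargets(aa[i], rules))
  })
  unlist(out)
}

#' Apply a mutation set to the reference peptide
#'
#' @param reference reference peptide sequence.
#' @param mutations character vector in \code{"G2V"} notation (may be
#'   empty, giving the reference itself at level 0).
#' @return A \code{\link{CandidatePeptide}}.
#' @examples
#' applyMutations("RGTFEGKF", c("G2V", "F4W"))  # RVTWEGKF, level 2
#' @export
applyMutations <- function(reference, mutations = character()) {
  aa <- .checkSequence(reference, "reference")
  m <- parseMutations(mutations)
  if (anyDuplicated(m$pos))
    .stopInput("conflicting mutations at position %d",
               m$pos[duplicated(m$pos)][1L])
  if (any(m$pos < 1L | m$pos > length(aa)))
    .stopInput("mutation position out of range for a %d-mer", length(aa))
  bad <- m$from != aa[m$pos]
  if (any(bad))
    .stopInput("mutation %s does not match reference residue '%s' at position %d",
               formatMutations(m$pos, m$from, m$to)[bad][1L],
               aa[m$pos][bad][1L], m$pos[bad][1L])
  aa[m$pos] <- m$to
  new("CandidatePeptide", sequence = paste(aa, collapse = ""),
      mutations = .sortMutations(mutations),
      level = length(mutations))
}

#' Diff a peptide against the reference to recover its mutation set
#'
#' @param reference reference peptide sequence.
#' @param sequence mutated sequence of the same length.
#' @return Character vector of mutations in notation form.
#' @export
diffMutations <- function(reference, sequence) {
  a <- .checkSequence(reference, "reference")
  b <- .checkSequence(sequence, "sequence")
  if (length(a) != length(b))
    .stopInput("sequence length %d does not match reference length %d",
               length(b), length(a))
  i <- which(a != b)
  formatMutations(i, a[i], b[i])
}

#' Combine two mutation sets
#'
#' Forms the union of two mutation sets when their positions are pairwise
#' distinct, the union stays within the mutation cap, and the union is
#' strictly larger than both inputs. Otherwise returns a typed rejection.
#'
#' @param a,b character vectors of mutations in notation form.
#' @param rules a \code{\link{MutationRules}} object.
#' @return A list with elements \code{accepted} (logical),
#'   \code{mutations} (the union, when accepted) and \code{reason}
#'   (\code{NA}, \code{"position-conflict"}, \code{"over-cap"} or
#'   \code{"no-new-mutation"}).
#' @examples
#' combineMutationSets("G2V", "F4W")          # accepted
#' combineMutationSets("G2V", "G2I")          # position-conflict
#' @export
combineMutationSets <- function(a, b, rules = mutationRules()) {
  u <- union(a, b)
  reject <- function(reason)
    list(accepted = FALSE, mutations = character(), reason = reason)
  if (length(u) <= max(length(a), length(b)))
    return(reject("no-new-mutation"))
  pos <- parseMutations(u)$pos
  if (anyDuplicated(pos)) return(reject("position-conflict"))
  if (length(u) > rules@maxMutations) return(reject("over-cap"))
  list(accepted = TRUE, mutations = .sortMutations(u), reason = NA_character_)
}

#' Size of the unrestricted sequence space
#'
#' The number of sequences of a given length over an alphabet, computed
#' exactly. An 8-mer over the 20 standard residues has 20^8 = 2.56e10
#' sequences; restricting mutations to chemical groups is what makes the
#' search tractable.
#'
#' @param length peptide length (>= 1).
#' @param alphabetSize alphabet size (default 20).
#' @return The exact count as a double (errors if the exact integer
#'   exceeds 2^53, beyond which doubles cannot represent it exactly).
#' @examples
#' sequenceSpaceSize(8)        # 25,600,000,000
#' sequenceSpaceSize(3, 4)     # 64
#' @export
sequenceSpaceSize <- function(length, alphabetSize = 20) {
  if (length < 1 || alphabetSize < 1 ||
      length != round(length) || alphabetSize != round(alphabetSize))
    .stopInput("length and alphabetSize must be positive integers")
  out <- as.numeric(alphabetSize)^as.numeric(length)
  if (out > 2^53)
    .stopInput("result exceeds 2^53 and cannot be represented exactly")
  out
}

#' @describeIn CandidatePeptide-class display method
#' @param object a \code{CandidatePeptide}.
#' @export
setMethod("show", "CandidatePeptide", function(object) {
  muts <- if (object@level) paste(object@mutations, collapse = "+")
          else "(reference)"
  cat(sprintf("CandidatePeptide %s  level %d  %s\n",
              object@sequence, object@level, muts))
  if (length(object@scores))
    cat("  scores:", paste(sprintf("%s=%.4g", names(object@scores),
                                   object@scores), collapse = "  "), "\n")
})

#' Sequence of a candidate peptide
#' @param x a \code{CandidatePeptide}.
#' @return Character sequence.
#' @export
peptideSequence <- function(x) x@sequence

#' Mutation set of a candidate peptide
#' @param x a \code{CandidatePeptide}.
#' @return Character vector of mutations in notation form.
#' @export
peptideMutations <- function(x) x@mutations

#' Mutation level (number of mutations) of a candidate peptide
#' @param x a \code{CandidatePeptide}.
#' @return Integer level.
#' @export
peptideLevel <- function(x) x@level
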