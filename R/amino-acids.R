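## The chemical grouping and Kyte-Doolittle hydropathy table that restricts
## the mutation space. Groups follow side-chain chemistry; each residue
## belongs to exactly one group.

.AA_GROUPS <- list(
  `nonpolar-aliphatic`  = c("G", "A", "V", "P", "L", "I", "M"),
  `aromatic`            = c("F", "Y", "W"),
  `polar-uncharged`     = c("S", "T", "C", "N", "Q"),
  `negatively-charged`  = c("D", "E"),
  `positively-charged`  = c("K", "H", "R")
)

.AA_HYDROPATHY <- c(
  G = -0.4, A = 1.8, V = 4.2, P = 1.6, L = 3.8, I = 4.5, M = 1.9,
  F = 2.8, Y = -1.3, W = -0.9,
  S = -0.8, T = -0.7, C = 2.5, N = -3.5, Q = -3.5,
  D = -3.5, E = -3.5,
  K = -3.9, H = -3.2, R = -4.5
)

#' Amino-acid grouping and hydropathy table
#'
#' Returns the 20 standard residues with their chemical group (nonpolar
#' aliphatic, aromatic, polar uncharged, negatively charged, positively
#' charged) and Kyte-Doolittle hydropathy index. Mutation enumeration is
#' restricted to substitutions within a group; the surrogate groove scorer
#' uses the hydropathy column.
#'
#' @return A \code{data.frame} with columns \code{residue}, \code{group}
#'   and \code{hydropathy}, one row per standard amino acid.
#' @examples
#' tab <- aminoAcidTable()
#' tab[tab$residue == "G", ]
#' @export
aminoAcidTable <- function() {
  res <- unlist(.AA_GROUPS, use.names = FALSE)
  grp <- rep(names(.AA_GROUPS), lengths(.AA_GROUPS))
  data.frame(residue = res, group = grp,
             hydropathy = unname(.AA_HYDROPATHY[res]),
             stringsAsFactors = FALSE)
}

#' Chemical group of one or more residues
#'
#' @param residue Character vector of one-letter residue codes.
#' @return Character vector of group names.
#' @examples
#' residueGroup(c("G", "F", "K"))
#' @export
residueGroup <- function(residue) {
  map <- rep(names(.AA_GROUPS), lengths(.AA_GROUPS))
  names(map) <- unlist(.AA_GROUPS, use.names = FALSE)
  bad <- setdiff(residue, names(map))
  if (length(bad))
    .stopInput("unknown residue letter(s): %s", paste(bad, collapse = ", "))
  unname(map[residue])
}

#' Kyte-Doolittle hydropathy of one or more residues
#'
#' @param residue Character vector of one-letter residue codes.
#' @return Numeric vector of hydropathy indices.
#' @examples
#' hydropathy(c("R", "G", "F"))
#' @export
hydropathy <- function(residue) {
  bad <- setdiff(residue, names(.AA_HYDROPATHY))
  if (length(bad))
    .stopInput("unknown residue letter(s): %s", paste(bad, collapse = ", "))
  unname(.AA_HYDROPATHY[residue])
}

## Validate a peptide string, naming the first offending position.
.checkSequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    .stopInput("%s must be a single non-empty string", what)
  aa <- strsplit(sequence, "")[[1L]]
  bad <- which(!aa %in% names(.AA_HYDROPATHY))
  if (length(bad))
    .stopInput("%s contains non-standard residue '%s' at position %d",
               what, aa[bad[1L]], bad[1L])
  aa
}
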