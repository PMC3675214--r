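## Independent oracles, deliberately coded without reusing the package's
## internals: brute-force mutation enumeration, a stand-alone search
## recursion, and closed-form work/free-energy references.

## All 19 substitutions per position, filtered against the group rules.
oracleSingles <- function(reference, exclusions = "G>M") {
  tab <- aminoAcidTable()
  aa <- strsplit(reference, "")[[1L]]
  out <- character()
  for (i in seq_along(aa)) {
    for (to in setdiff(tab$residue, aa[i])) {
      sameGroup <- tab$group[tab$residue == to] ==
        tab$group[tab$residue == aa[i]]
      if (sameGroup && !(paste0(aa[i], ">", to) %in% exclusions))
        out <- c(out, paste0(aa[i], i, to))
    }
  }
  out
}

## Stand-alone combine-score-accept recursion. Members pair only when at
## least one of them was accepted in the previous cycle; a sequence is
## scored at most once.
oracleSearch <- function(reference, scoreFun, polarity = "higher",
                         exclusions = "G>M", cap = 4, maxLevel = 4,
                         maxCycles = 2) {
  better <- function(a, b) if (polarity == "higher") a > b else a < b
  applySet <- function(muts) {
    aa <- strsplit(reference, "")[[1L]]
    for (m in muts)
      aa[as.integer(gsub("[A-Z]", "", m))] <- substring(m, nchar(m))
    paste(aa, collapse = "")
  }
  refS <- scoreFun(reference)
  mem <- list()
  rejectedSeqs <- character()
  for (m in oracleSingles(reference, exclusions)) {
    s <- applySet(m)
    sc <- scoreFun(s)
    if (better(sc, refS))
      mem[[length(mem) + 1L]] <- list(muts = m, seq = s, cycle = 0L,
                                      score = sc)
    else rejectedSeqs <- c(rejectedSeqs, s)
  }
  lvlCap <- min(cap, maxLevel)
  for (cyc in seq_len(maxCycles)) {
    snap <- mem
    added <- 0L
    if (length(snap) >= 2L)
      for (i in seq_len(length(snap) - 1L)) for (j in seq(i + 1L, length(snap))) {
        if (max(snap[[i]]$cycle, snap[[j]]$cycle) != cyc - 1L) next
        u <- sort(union(snap[[i]]$muts, snap[[j]]$muts))
        if (length(u) <= max(length(snap[[i]]$muts), length(snap[[j]]$muts)))
          next
        if (anyDuplicated(as.integer(gsub("[A-Z]", "", u)))) next
        if (length(u) > lvlCap) next
        s <- applySet(u)
        if (s %in% c(vapply(mem, `[[`, "", "seq"), rejectedSeqs)) next
        sc <- scoreFun(s)
        if (better(sc, refS)) {
          mem[[length(mem) + 1L]] <- list(muts = u, seq = s, cycle = cyc,
                                          score = sc)
          added <- added + 1L
        } else rejectedSeqs <- c(rejectedSeqs, s)
      }
    if (added == 0L) break
  }
  df <- if (length(mem))
    data.frame(sequence = vapply(mem, `[[`, "", "seq"),
               level = vapply(mem, function(x) length(x$muts), integer(1)),
               cycle = vapply(mem, `[[`, integer(1), "cycle"),
               score = vapply(mem, `[[`, numeric(1), "score"),
               stringsAsFactors = FALSE)
  else data.frame(sequence = character(), level = integer(),
                  cycle = integer(), score = numeric())
  list(refScore = refS, members = df[order(df$sequence), , drop = FALSE])
}

## Library members in the oracle's comparison shape.
memberTable <- function(library) {
  m <- libraryMembers(library)
  df <- data.frame(sequence = m$sequence, level = m$level,
                   cycle = m$cycle, score = m$score,
                   stringsAsFactors = FALSE)
  df <- df[order(df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Short random references over the full alphabet.
randomReference <- function(len) {
  paste(sample(aminoAcidTable()$residue, len, replace = TRUE),
        collapse = "")
}

table2Path <- function(which)
  system.file("extdata", sprintf("table2_%s.tsv", which),
              package = "pepdesign")
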