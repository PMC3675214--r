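## Readers and writers for the on-disk formats: FASTA peptide libraries,
## library TSV, pulling-trace TSV, NAMD-SMD-style logs and run configs.

#' Read a peptide library from FASTA
#'
#' Record ids carry the mutation notation joined by \code{"+"} (e.g.
#' \code{">G2V+F4W"}); the reference record is named \code{"reference"}.
#' Ids that are not mutation notation are reconstructed by diffing
#' against \code{reference} when one is supplied.
#'
#' @param path FASTA file.
#' @param reference optional reference sequence used to reconstruct
#'   mutation sets from sequences with uninformative ids.
#' @return List of \code{\link{CandidatePeptide}}.
#' @export
readFastaLibrary <- function(path, reference = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) return(list())
  lapply(seq_along(set), function(i) {
    id <- sub("\\s.*", "", names(set)[i])
    seqc <- toupper(as.character(set[[i]]))
    .checkSequence(seqc, sprintf("record %d (%s)", i, id))
    muts <- if (identical(id, "reference")) character()
      else if (grepl("^[A-Z][0-9]+[A-Z](\\+[A-Z][0-9]+[A-Z])*$", id))
        strsplit(id, "+", fixed = TRUE)[[1L]]
      else if (!is.null(reference)) diffMutations(reference, seqc)
      else .stopInput("record %d id '%s' is not mutation notation and no reference was supplied",
                      i, id)
    if (!is.null(reference) && length(muts)) {
      rebuilt <- applyMutations(reference, muts)@sequence
      if (rebuilt != seqc)
        .stopInput("record %d: id '%s' does not reproduce sequence %s",
                   i, id, seqc)
    }
    new("CandidatePeptide", sequence = seqc,
        mutations = .sortMutations(muts), level = length(muts))
  })
}

#' Write a peptide library to FASTA
#'
#' @param peptides list of \code{\link{CandidatePeptide}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFastaLibrary <- function(peptides, path) {
  ids <- vapply(peptides, function(p)
    if (p@level) paste(p@mutations, collapse = "+") else "reference", "")
  seqs <- vapply(peptides, function(p) p@sequence, "")
  set <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a candidate library to TSV
#'
#' Header lines carry the reference, its score and the scorer; columns
#' are \code{sequence}, \code{mutations}, \code{level}, \code{cycle},
#' \code{primary_score}, \code{secondary_score}, \code{parents}.
#'
#' @param library a \code{\link{CandidateLibrary}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCandidateLibrary <- function(library, path) {
  m <- library@members
  hdr <- sprintf("# reference=%s reference_score=%.10g scorer=%s polarity=%s",
                 library@reference, library@referenceScore,
                 library@scorerName, library@polarity)
  rows <- sprintf("%s\t%s\t%d\t%d\t%.10g\t%s\t%s",
                  m$sequence, m$mutations, m$level, m$cycle, m$score,
                  ifelse(is.na(m$secondary), "NA",
                         sprintf("%.10g", m$secondary)),
                  m$parents)
  writeLines(c(hdr,
               "sequence\tmutations\tlevel\tcycle\tprimary_score\tsecondary_score\tparents",
               rows), path)
  invisible(path)
}

#' Read a candidate library from TSV
#'
#' @param path file written by \code{\link{writeCandidateLibrary}}.
#' @return A \code{\link{CandidateLibrary}} (the per-cycle log is
#'   reduced to the member counts recoverable from the file).
#' @export
readCandidateLibrary <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)[1L]
  if (is.na(hdr)) .stopInput("missing '# reference=...' header in %s", path)
  kv <- regmatches(hdr, gregexpr("[A-Za-z_]+=[^ \t]+", hdr))[[1L]]
  meta <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  body <- body[-1L]  # column header
  members <- .emptyMembers()
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    ## a trailing empty parents field is dropped by strsplit; restore it
    parts <- lapply(parts, function(p)
      c(p, rep("", max(0L, 7L - length(p)))))
    if (any(lengths(parts) != 7L))
      .stopInput("malformed library row in %s", path)
    g <- function(i) vapply(parts, `[`, "", i)
    members <- data.frame(sequence = g(1L), mutations = g(2L),
                          level = as.integer(g(3L)),
                          cycle = as.integer(g(4L)),
                          score = as.numeric(g(5L)),
                          secondary = suppressWarnings(as.numeric(g(6L))),
                          parents = g(7L), stringsAsFactors = FALSE)
  }
  cyc <- sort(unique(c(0L, members$cycle)))
  log <- data.frame(cycle = cyc, tried = NA_integer_,
                    accepted = vapply(cyc, function(ci)
                      sum(members$cycle == ci), integer(1)),
                    rej_score = NA_integer_, rej_conflict = NA_integer_,
                    rej_cap = NA_integer_, rej_nonew = NA_integer_,
                    rej_duplicate = NA_integer_, rej_veto = NA_integer_)
  new("CandidateLibrary", reference = meta[["reference"]],
      referenceScore = as.numeric(meta[["reference_score"]]),
      scorerName = meta[["scorer"]], polarity = meta[["polarity"]],
      members = members, rejected = numeric(), log = log)
}

## ---- pulling traces ---------------------------------------------------

#' Write a pulling trace to TSV
#'
#' Format: a \code{# protocol: k=... v=... lambda0=... T=...} header, an
#' optional \code{# source:} line, a column-header line and tab-separated
#' \code{t lambda xi force} samples.
#'
#' @param trajectory a \code{\link{PullingTrajectory}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePullingTrace <- function(trajectory, path) {
  p <- trajectory@protocol
  hdr <- sprintf("# protocol: k=%.10g v=%.10g lambda0=%.10g T=%.10g",
                 p@k, p@v, p@lambda0, p@temperature)
  src <- if (!is.na(trajectory@source))
    sprintf("# source: %s", trajectory@source) else character()
  rows <- sprintf("%.10g\t%.10g\t%.10g\t%.10g", trajectory@time,
                  trajectory@lambda, trajectory@xi, trajectory@force)
  writeLines(c(hdr, src, "t\tlambda\txi\tforce", rows), path)
  invisible(path)
}

.parseProtocolHeader <- function(line) {
  kv <- regmatches(line, gregexpr("[A-Za-z0-9_]+=[-0-9.eE+]+", line))[[1L]]
  vals <- stats::setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  pullingProtocol(k = vals[["k"]], v = vals[["v"]],
                  lambda0 = vals[["lambda0"]],
                  temperature = if ("T" %in% names(vals)) vals[["T"]] else 310)
}

.readTraceTSV <- function(path, protocol = NULL, energyUnits = "kcal") {
  lines <- readLines(path)
  hdr <- grep("^# protocol:", lines, value = TRUE)
  if (is.null(protocol)) {
    if (!length(hdr))
      .stopInput("%s has no '# protocol:' header and no protocol was supplied",
                 path)
    protocol <- .parseProtocolHeader(hdr[1L])
  }
  src <- grep("^# source:", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  body <- body[!grepl("^t\t", body)]  # column header
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L))
    .stopInput("malformed trace line in %s", path)
  g <- function(i) as.numeric(vapply(parts, `[`, "", i))
  force <- if (all(lengths(parts) >= 4L)) g(4L) else NULL
  scale <- if (energyUnits == "kJ") 0.239006 else 1
  if (!is.null(force)) force <- force * scale
  pullingTrajectory(time = g(1L), xi = g(3L), protocol = protocol,
                    lambda = g(2L), force = force,
                    source = if (length(src))
                      sub("^# source: *", "", src[1L]) else basename(path))
}

.readTraceNAMD <- function(path, protocol, columnMap, timestepNs,
                           energyUnits = "kcal") {
  if (is.null(protocol))
    .stopInput("the namd-smd-log dialect needs an explicit protocol")
  lines <- grep("^SMD\\b", readLines(path), value = TRUE)
  if (!length(lines)) .stopInput("no 'SMD' lines found in %s", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  g <- function(i) as.numeric(vapply(parts, `[`, "", i))
  step <- g(columnMap$step)
  tns <- step * timestepNs
  xi <- g(columnMap$xi)
  scale <- if (energyUnits == "kJ") 0.239006 else 1
  force <- if (!is.null(columnMap$force)) g(columnMap$force) * scale
           else NULL
  pullingTrajectory(time = tns, xi = xi, protocol = protocol,
                    force = force, source = basename(path))
}

#' Read constant-velocity pulling traces
#'
#' Reads one file or every file in a directory, in either the native TSV
#' dialect (with a \code{# protocol:} header) or a NAMD-SMD-style log
#' dialect whose \code{SMD}-prefixed lines are mapped to fields via
#' \code{columnMap}. All traces in a directory must agree on the
#' protocol.
#'
#' @param path file or directory.
#' @param dialect \code{"tsv"} or \code{"namd-smd-log"}.
#' @param protocol a \code{\link{PullingProtocol}}; required for the log
#'   dialect, optional for TSV (overrides the file headers).
#' @param columnMap for the log dialect: list with 1-based token indices
#'   \code{step}, \code{xi} and optionally \code{force} (token 1 is the
#'   \code{SMD} tag itself).
#' @param timestepNs for the log dialect: MD timestep in ns.
#' @param energyUnits \code{"kcal"} (default) or \code{"kJ"}; forces in
#'   kJ/(mol A) are converted by 0.239006.
#' @param pattern filename filter when \code{path} is a directory.
#' @return List of \code{\link{PullingTrajectory}}.
#' @export
readPullingTraces <- function(path, dialect = c("tsv", "namd-smd-log"),
                              protocol = NULL,
                              columnMap = list(step = 2, xi = 3, force = 4),
                              timestepNs = 1e-6, energyUnits = "kcal",
                              pattern = NULL) {
  dialect <- match.arg(dialect)
  files <- if (dir.exists(path))
    list.files(path, pattern = pattern, full.names = TRUE) else path
  if (!length(files)) .stopInput("no trace files found under %s", path)
  trajs <- lapply(files, function(f)
    if (dialect == "tsv") .readTraceTSV(f, protocol, energyUnits)
    else .readTraceNAMD(f, protocol, columnMap, timestepNs, energyUnits))
  protos <- vapply(trajs, function(tr)
    sprintf("k=%g v=%g lambda0=%g", tr@protocol@k, tr@protocol@v,
            tr@protocol@lambda0), "")
  if (length(unique(protos)) > 1L) {
    off <- basename(files)[protos != protos[1L]]
    .stopInput("inconsistent protocol headers across traces: %s",
               paste(off, collapse = ", "))
  }
  trajs
}

## ---- run configuration ------------------------------------------------

#' Read a run configuration
#'
#' YAML mirror of the search and PMF options (reference, rules, scorer
#' specs, search limits, grid/estimator options, seeds, output paths).
#' Round-trips losslessly through \code{\link{writeRunConfig}}.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' Write a run configuration
#'
#' @param config named list.
#' @param path output YAML file.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
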