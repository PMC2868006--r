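# File formats and run manifests: FASTA sequences, TSV interaction/pair/
# feature/score tables, JSON manifests and reports.  Every writer has a
# reader that round-trips exactly.

#' Read protein sequences from FASTA
#'
#' Identifiers are the header up to the first whitespace; sequences are
#' upper-cased.  Empty files, duplicate identifiers and malformed headers
#' are distinct errors.
#'
#' @param path FASTA file.
#' @return An [Biostrings::AAStringSet] named by identifier.
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) .stopf("no such file: %s", path)
    x <- Biostrings::readAAStringSet(path)
    if (length(x) == 0L) .stopf("empty FASTA file: %s", path)
    ids <- sub("\\s.*$", "", names(x))
    if (any(!nzchar(ids))) .stopf("malformed FASTA header (empty identifier)")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) {
        .stopf("duplicate FASTA identifier(s): %s",
               paste(utils::head(dup, 5L), collapse = ", "))
    }
    names(x) <- ids
    Biostrings::AAStringSet(toupper(as.character(x)))
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector or `AAStringSet`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(sequences, path) {
    if (!methods::is(sequences, "XStringSet")) {
        sequences <- Biostrings::AAStringSet(sequences)
    }
    Biostrings::writeXStringSet(sequences, path)
    invisible(path)
}

#' Read an interaction table
#'
#' Tab-separated columns `idA`, `idB` and optionally `detection`
#' (`in_vivo` / `in_vitro` / `other`) and `arity`.  Blank lines are
#' skipped (with a message when present).  Pairs are returned as given —
#' canonicalisation happens in [filterInteractions()] / [canonicalPairs()].
#'
#' @param path TSV file with a header line.
#' @return Data frame of interaction records.
#' @export
readInteractions <- function(path) {
    if (!file.exists(path)) .stopf("no such file: %s", path)
    lines <- readLines(path)
    blank <- !nzchar(trimws(lines))
    if (any(blank)) {
        message(sum(blank), " blank line(s) skipped in ", path)
    }
    d <- utils::read.delim(text = lines[!blank], stringsAsFactors = FALSE,
                           colClasses = NA)
    if (!all(c("idA", "idB") %in% names(d))) {
        .stopf("interaction table needs columns idA, idB (got: %s)",
               paste(names(d), collapse = ", "))
    }
    d$idA <- as.character(d$idA)
    d$idB <- as.character(d$idB)
    d
}

#' Read a pair table with optional id validation
#'
#' @param path TSV with columns `idA`, `idB` (extra columns preserved).
#' @param fastaIndex Optional vector of known protein ids (e.g.
#'   `names(readFasta(f))`); pairs referencing unknown ids are then
#'   rejected or dropped per `unknownIds`.
#' @param unknownIds `"error"` (default) or `"drop"`.
#' @return Data frame of canonical pairs (annotations preserved).
#' @export
readPairs <- function(path, fastaIndex = NULL,
                      unknownIds = c("error", "drop")) {
    unknownIds <- match.arg(unknownIds)
    d <- readInteractions(path)
    if (!is.null(fastaIndex)) {
        bad <- !(d$idA %in% fastaIndex) | !(d$idB %in% fastaIndex)
        if (any(bad)) {
            if (unknownIds == "error") {
                ids <- setdiff(unique(c(d$idA, d$idB)), fastaIndex)
                .stopf("unknown protein id(s): %s",
                       paste(utils::head(ids, 5L), collapse = ", "))
            }
            message(sum(bad), " pair(s) with unknown ids dropped")
            d <- d[!bad, , drop = FALSE]
        }
    }
    swap <- d$idB < d$idA
    tmp <- d$idA[swap]
    d$idA[swap] <- d$idB[swap]
    d$idB[swap] <- tmp
    rownames(d) <- NULL
    d
}

#' Write a pair table
#'
#' @param pairs Data frame with at least `idA`, `idB`.
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
writePairs <- function(pairs, path) {
    utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write / read a feature matrix
#'
#' TSV with an `id` column and one column per triad label (per-protein,
#' 343 columns) or per pair-vector position (686 columns).
#'
#' @param features Numeric matrix with row names.
#' @param path TSV file.
#' @return `writeFeatures` invisibly returns `path`; `readFeatures`
#'   returns the matrix.
#' @export
writeFeatures <- function(features, path) {
    d <- data.frame(id = rownames(features), features, check.names = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d$id
    m
}

#' Build a run manifest
#'
#' Records what produced a set of artifacts: command name, package
#' version, configuration snapshot, seeds, md5 checksums of the input
#' files and the output inventory.  No wall-clock timestamp is included
#' unless requested, so identical runs produce byte-identical manifests.
#'
#' @param command Character, the operation performed.
#' @param seeds Named list or vector of seeds in play.
#' @param config Configuration snapshot (any jsonlite-serialisable list).
#' @param inputs,outputs Character vectors of file paths; existing files
#'   are checksummed.
#' @param timestamp Include the current time (default `FALSE`).
#' @return List suitable for [writeManifest()].
#' @export
runManifest <- function(command, seeds = list(), config = list(),
                        inputs = character(0), outputs = character(0),
                        timestamp = FALSE) {
    checksum <- function(paths) {
        ok <- file.exists(paths)
        sums <- rep(NA_character_, length(paths))
        sums[ok] <- unname(tools::md5sum(paths[ok]))
        stats::setNames(as.list(sums), basename(paths))
    }
    m <- list(tool = "triadKDE",
              version = as.character(utils::packageVersion("triadKDE")),
              command = command,
              seeds = seeds,
              config = config,
              inputs = checksum(inputs),
              outputs = checksum(outputs))
    if (timestamp) m$created <- format(Sys.time(), tz = "UTC")
    m
}

#' Write / read a JSON manifest or report
#'
#' @param x List to serialise.
#' @param path JSON file.
#' @return `writeManifest` invisibly returns `path`; `readManifest`
#'   returns the list.
#' @export
writeManifest <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE)
}
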