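#' @importFrom stats median setNames runif
#' @importFrom utils read.delim write.table head tail
NULL

# Sequences are plain character scalars over {A,C,G,T,N}; collections are
# named character vectors (names = unique ids). All internal coordinates are
# 0-based half-open; GFF3 conversion happens in exactly one place
# (write_gff3/read_gff3).

#' Create a half-open interval
#'
#' Intervals are 0-based, start-inclusive, end-exclusive. They carry every
#' positional coordinate used by the detector, the promoter annotator and the
#' synthetic-genome truth records.
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @return A list of class `interval` with fields `start` and `end`.
#' @export
interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid interval: need 0 <= start < end, got [", start, ",", end, ")")
  }
  structure(list(start = start, end = end), class = "interval")
}

#' Interval length
#' @param iv An `interval`.
#' @return `end - start`.
#' @export
iv_length <- function(iv) iv$end - iv$start

#' Extract the residues covered by an interval
#' @param seq A DNA string.
#' @param iv An `interval` in `seq` coordinates.
#' @return The substring `seq[start, end)`.
#' @export
iv_seq <- function(seq, iv) substr(seq, iv$start + 1L, iv$end)

#' Validate and normalise a DNA string
#'
#' Folds lowercase to uppercase and rejects residues outside {A,C,G,T,N}.
#'
#' @param x Character scalar.
#' @param what Label used in error messages.
#' @return The uppercase string.
#' @export
clean_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x)) stop(what, " must be a single string")
  if (nchar(x) == 0L) stop(what, " is empty")
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    bad <- regmatches(x, regexpr("[^ACGTN]", x))
    stop(what, " contains invalid residue '", bad, "'")
  }
  x
}

#' Hamming distance between equal-length strings
#'
#' @param a,b DNA strings of identical length.
#' @return Number of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("length mismatch: ", nchar(a), " vs ", nchar(b))
  }
  sum(charToRaw(a) != charToRaw(b))
}

#' Alignment scoring parameters
#'
#' Defaults mirror the search scoring used for the original screen
#' (match +1, mismatch -2, gap cost 2 to open and 2 to extend).
#'
#' @param match,mismatch,gap_open,gap_extend Scores; gap penalties negative.
#' @return A list of class `aln_scoring`.
#' @export
aln_scoring <- function(match = 1, mismatch = -2, gap_open = -2,
                        gap_extend = -2) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "aln_scoring")
}

.subst_matrix <- function(scoring) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  # N never counts as a match (identity handles this too, but keep the
  # optimiser from rewarding N runs)
  m["N", ] <- scoring$mismatch
  m[, "N"] <- scoring$mismatch
  m
}

#' Percent identity of two gapped alignment rows
#'
#' Identity = 100 x matched columns / columns where at least one row has a
#' residue, with terminal-overhang columns (leading/trailing gap runs of
#' either row) excluded. Internal gap columns count in the denominator; N
#' never counts as a match.
#'
#' @param aligned_a,aligned_b Equal-length gapped strings (`-` = gap).
#' @return Percent identity in [0, 100].
#' @export
identity_from_alignment <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    stop("aligned rows differ in length")
  }
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  res_a <- a != "-"
  res_b <- b != "-"
  # terminal overhangs: columns before the first / after the last position
  # where BOTH rows carry a residue
  both <- which(res_a & res_b)
  if (length(both) == 0L) return(0)
  keep <- seq(both[1L], both[length(both)])
  a <- a[keep]; b <- b[keep]
  denom <- sum(a != "-" | b != "-")
  matches <- sum(a == b & a != "-" & a != "N")
  100 * matches / denom
}

.aln_result <- function(aln, a, b) {
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  list(
    aligned_a = pa,
    aligned_b = pb,
    score = Biostrings::score(aln),
    identity_pct = identity_from_alignment(pa, pb),
    span_a = interval(Biostrings::start(Biostrings::pattern(aln)) - 1L,
                      Biostrings::end(Biostrings::pattern(aln))),
    span_b = interval(Biostrings::start(Biostrings::subject(aln)) - 1L,
                      Biostrings::end(Biostrings::subject(aln)))
  )
}

#' Optimal global alignment and percent identity
#'
#' Needleman-Wunsch alignment under the configured scoring; the identity
#' statistic follows [identity_from_alignment()].
#'
#' @param a,b DNA strings.
#' @param scoring An [aln_scoring()].
#' @return A list: `aligned_a`, `aligned_b`, `score`, `identity_pct`,
#'   `span_a`, `span_b`.
#' @export
global_identity <- function(a, b, scoring = aln_scoring()) {
  a <- clean_dna(a, "sequence a"); b <- clean_dna(b, "sequence b")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = .subst_matrix(scoring),
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  .aln_result(aln, a, b)
}

#' Best local alignment (Smith-Waterman)
#'
#' @param query,target DNA strings.
#' @param scoring An [aln_scoring()].
#' @param min_score Minimum alignment score; below it `NULL` is returned.
#' @return An alignment result as in [global_identity()], or `NULL`.
#' @export
local_align <- function(query, target, scoring = aln_scoring(),
                        min_score = -Inf) {
  query <- clean_dna(query, "query"); target <- clean_dna(target, "target")
  aln <- Biostrings::pairwiseAlignment(
    query, target, type = "local",
    substitutionMatrix = .subst_matrix(scoring),
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  if (Biostrings::score(aln) < min_score) return(NULL)
  .aln_result(aln, query, target)
}

# ---- file formats ----------------------------------------------------------

.check_fasta_lines <- function(path) {
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("FASTA parse error at line 1: empty file")
  if (!startsWith(lines[nonblank[1L]], ">")) {
    stop("FASTA parse error at line ", nonblank[1L],
         ": expected '>' header, got '",
         substr(lines[nonblank[1L]], 1, 20), "'")
  }
  for (i in nonblank) {
    ln <- lines[i]
    if (startsWith(ln, ">")) next
    if (grepl("[^ACGTNacgtn]", ln)) {
      stop("FASTA parse error at line ", i, ": invalid residue in '",
           substr(ln, 1, 20), "'")
    }
  }
  invisible(TRUE)
}

#' Read a multi-record FASTA file
#'
#' Lowercase residues are folded to uppercase; duplicate ids are an error.
#' Malformed records raise a parse error naming the offending line.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase DNA strings.
#' @export
read_fasta <- function(path) {
  .check_fasta_lines(path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (qualities ignored)
#'
#' @param path FASTQ file.
#' @return Named character vector of uppercase DNA strings.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write features to GFF3
#'
#' The single conversion point from internal 0-based half-open coordinates to
#' the 1-based inclusive GFF3 convention. Feature types are Sequence Ontology
#' terms (`LTR_retrotransposon`, `long_terminal_repeat`,
#' `primer_binding_site`, `RR_tract`, `region`, ...).
#'
#' @param features Data frame with columns `contig_id`, `type`, `start`,
#'   `end` (0-based half-open), optional `strand`, `source`, `score`,
#'   `attributes`.
#' @param path Output file.
#' @export
write_gff3 <- function(features, path) {
  stopifnot(all(c("contig_id", "type", "start", "end") %in% names(features)))
  n <- nrow(features)
  get <- function(col, default) {
    if (col %in% names(features)) features[[col]] else rep(default, n)
  }
  lines <- "##gff-version 3"
  if (n > 0L) {
    stopifnot(all(features$start >= 0), all(features$end > features$start))
    rows <- paste(features$contig_id, get("source", "cassandra"),
                  features$type, features$start + 1L, features$end,
                  get("score", "."), get("strand", "+"), ".",
                  get("attributes", "."), sep = "\t")
    lines <- c(lines, rows)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file into internal coordinates
#'
#' @param path GFF3 file.
#' @return Data frame with 0-based half-open `start`/`end` plus `contig_id`,
#'   `source`, `type`, `score`, `strand`, `attributes`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(contig_id = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = character(), strand = character(),
                      attributes = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad)) stop("GFF3 parse error: expected 9 columns at record ",
                        bad[1L])
  m <- do.call(rbind, parts)
  data.frame(contig_id = m[, 1], source = m[, 2], type = m[, 3],
             start = as.integer(m[, 4]) - 1L, end = as.integer(m[, 5]),
             score = m[, 6], strand = m[, 7], attributes = m[, 9],
             stringsAsFactors = FALSE)
}

#' Write a tab-separated report table
#' @param df Data frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated report table
#' @param path File written by [write_tsv()].
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
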