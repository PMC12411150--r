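#' Microbial reference sequence
#'
#' @param label reference label, e.g. `"EBV"` or `"H_pylori"`.
#' @param sequence nucleotide string over `A/C/G/T/N`.
#' @param source_id free-text provenance (accession or similar).
#' @return A list of class `"microbial_reference"`.
#' @export
microbial_reference <- function(label, sequence, source_id = NA_character_) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("reference sequence is empty")
  if (grepl("[^ACGTN]", sequence))
    stop("reference sequence must use the A/C/G/T/N alphabet")
  structure(list(label = label, sequence = sequence, source_id = source_id),
            class = "microbial_reference")
}

#' Load a microbial reference from FASTA
#'
#' Reads the first record of a FASTA file (via Biostrings) as the
#' reference sequence.
#'
#' @param path path to a FASTA file.
#' @param label reference label; defaults to the FASTA record name.
#' @return A [microbial_reference()].
#' @export
read_reference_fasta <- function(path, label = NULL) {
  s <- Biostrings::readDNAStringSet(path)
  if (length(s) == 0L) stop("no sequences in ", path)
  if (is.null(label)) label <- names(s)[1]
  microbial_reference(label, as.character(s[[1]]), source_id = names(s)[1])
}

#' Screening parameters
#'
#' @param max_mismatches maximum substitutions tolerated per read
#'   placement (default 1).
#' @param min_reads_exclusive a sample is positive when its matched read
#'   count strictly exceeds this (default 4: five matching reads flag
#'   the sample).
#' @return A list of class `"screen_params"`.
#' @export
screen_params <- function(max_mismatches = 1L, min_reads_exclusive = 4L) {
  if (max_mismatches < 0) stop("max_mismatches must be >= 0")
  if (min_reads_exclusive < 0) stop("min_reads_exclusive must be >= 0")
  structure(list(max_mismatches = as.integer(max_mismatches),
                 min_reads_exclusive = as.integer(min_reads_exclusive)),
            class = "screen_params")
}

#' Does a read match the reference within a mismatch budget?
#'
#' True when some ungapped placement of the read on the reference, on
#' the forward strand or as its reverse complement, has Hamming distance
#' at most `max_mismatches`. `N` (in read or reference) never matches.
#'
#' @param read nucleotide string, no longer than the reference.
#' @param reference a [microbial_reference()] or nucleotide string.
#' @param max_mismatches mismatch budget (default 1).
#' @return Logical scalar.
#' @export
read_matches <- function(read, reference, max_mismatches = 1L) {
  seqc <- if (inherits(reference, "microbial_reference"))
    reference$sequence else toupper(as.character(reference))
  read <- toupper(as.character(read))
  if (nchar(read) == 0L) stop("empty read")
  if (nchar(read) > nchar(seqc)) stop("read longer than reference")
  cpp_read_matches(read, seqc, as.integer(max_mismatches))
}

#' Screen a read set against a microbial reference
#'
#' Counts reads matching the reference within the mismatch budget and
#' labels the sample positive when the count strictly exceeds
#' `min_reads_exclusive`.
#'
#' @param reads character vector of read sequences, or a path to a
#'   FASTA/FASTQ file (read via Biostrings).
#' @param reference a [microbial_reference()].
#' @param params a [screen_params()] object.
#' @return A list of class `"screen_result"`: `label`,
#'   `matched_read_count`, `positive`, `n_reads`, `params`.
#' @export
screen_sample <- function(reads, reference, params = screen_params()) {
  stopifnot(inherits(params, "screen_params"))
  if (!inherits(reference, "microbial_reference"))
    reference <- microbial_reference("reference", reference)
  if (length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fa|fasta|fq|fastq)$", reads, ignore.case = TRUE)) {
    fmt <- if (grepl("\\.(fq|fastq)$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  reads <- toupper(as.character(reads))
  count <- if (length(reads) == 0L) 0L else
    cpp_count_matches(reads, reference$sequence, params$max_mismatches)
  structure(list(label = reference$label, matched_read_count = count,
                 positive = count > params$min_reads_exclusive,
                 n_reads = length(reads), params = params),
            class = "screen_result")
}

#' Write reads as FASTQ with constant quality
#'
#' @param reads character vector of read sequences.
#' @param path output path.
#' @param quality_char quality character repeated per base (default
#'   `"I"`, Phred 40).
#' @return Invisibly, the path.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  lines <- unlist(lapply(seq_along(reads), function(i) {
    c(sprintf("@read_%d", i), reads[i], "+",
      strrep(quality_char, nchar(reads[i])))
  }))
  writeLines(lines, path)
  invisible(path)
}
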