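# FASTA/FASTQ input/output and Phred quality arithmetic.
#
# FASTQ is fixed to the strict 4-line dialect with Phred+33 qualities; FASTA
# may be multi-line on input and is wrapped at 80 columns on output.

#' Construct a raw read record
#'
#' A raw read is one basecalled concatemer read: an identifier, an uppercase
#' DNA sequence over A/C/G/T/N, and one integer Phred quality per base.
#'
#' @param read_id character identifier.
#' @param sequence DNA string; lowercase input is uppercased.
#' @param qualities integer Phred scores in \[0, 93\], one per base.
#' @return an object of class `raw_read`.
#' @export
raw_read <- function(read_id, sequence, qualities) {
  sequence <- toupper(sequence)
  qualities <- as.integer(qualities)
  if (nchar(sequence) != length(qualities))
    stop(condition_error("malformed_record", sprintf(
      "record '%s': sequence length %d != quality length %d",
      read_id, nchar(sequence), length(qualities))))
  if (length(qualities) && (min(qualities) < 0L || max(qualities) > 93L))
    stop(condition_error("malformed_record", sprintf(
      "record '%s': quality values outside [0, 93]", read_id)))
  structure(list(read_id = read_id, sequence = sequence,
                 qualities = qualities),
            class = "raw_read")
}

#' @export
print.raw_read <- function(x, ...) {
  cat(sprintf("<raw_read %s: %d bases, mean Q %.1f>\n",
              x$read_id, nchar(x$sequence),
              if (length(x$qualities)) mean_read_q(x$qualities)$mean_q else NA))
  invisible(x)
}

phred_offset <- 33L

qual_string_to_int <- function(q) {
  if (!nchar(q)) return(integer(0))
  utf8ToInt(q) - phred_offset
}

int_to_qual_string <- function(q) {
  if (!length(q)) return("")
  intToUtf8(as.integer(q) + phred_offset)
}

#' Read a 4-line FASTQ file
#'
#' @param path path to an uncompressed FASTQ file (Phred+33).
#' @return a list of [raw_read] records in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) return(list())
  if (length(lines) %% 4L != 0L)
    stop(condition_error("malformed_record",
                         sprintf("FASTQ '%s': line count %d is not a multiple of 4",
                                 path, length(lines))))
  n <- length(lines) %/% 4L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    hdr <- lines[4L * i - 3L]
    if (!startsWith(hdr, "@"))
      stop(condition_error("malformed_record",
                           sprintf("FASTQ record %d: header does not start with '@'", i)))
    id <- sub("\\s.*$", "", substring(hdr, 2L))
    out[[i]] <- raw_read(id, lines[4L * i - 2L],
                         qual_string_to_int(lines[4L * i]))
  }
  out
}

#' Write reads as 4-line FASTQ
#'
#' @param reads a list of [raw_read] records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * length(reads))
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    lines[4L * i - 3L] <- paste0("@", r$read_id)
    lines[4L * i - 2L] <- r$sequence
    lines[4L * i - 1L] <- "+"
    lines[4L * i] <- int_to_qual_string(r$qualities)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path path to an uncompressed FASTA file.
#' @return a named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA (80-column wrap)
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Summarize per-base qualities in probability space
#'
#' The mean error probability over bases is `mean(10^(-q/10))`; the summary Q
#' is that mean converted back to the Phred scale, `-10*log10(p)`. Averaging
#' in probability space (rather than averaging Q values directly) matches the
#' "estimated error rate" semantics of the Phred scale.
#'
#' @param qualities integer Phred scores (non-empty).
#' @return a list with `mean_error_prob` and `mean_q`.
#' @export
mean_read_q <- function(qualities) {
  if (!length(qualities)) stop("mean_read_q: empty quality vector")
  p <- mean(10^(-as.numeric(qualities) / 10))
  structure(list(mean_error_prob = p, mean_q = -10 * log10(p)),
            class = "quality_summary")
}

# Consensus FASTA headers carry coverage and quality so downstream ranking
# needs no sidecar file: `<read_id>_<subread_count>_<mean_q two decimals>`.
format_consensus_header <- function(read_id, subread_count, mean_q) {
  sprintf("%s_%d_%.2f", read_id, as.integer(subread_count), mean_q)
}

parse_consensus_header <- function(header) {
  m <- regmatches(header,
                  regexec("^(.*)_([0-9]+)_([0-9]+\\.?[0-9]*)$", header))[[1]]
  if (length(m) != 4L)
    stop("not a consensus-read header: ", header)
  list(read_id = m[2], subread_count = as.integer(m[3]),
       mean_q = as.numeric(m[4]))
}
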