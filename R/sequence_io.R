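# Sequence input/output and the long-reference splitting accessory.
#
# Sequence records are plain data frames with columns id, description and
# residues; coordinates everywhere in the package are 0-based half-open and
# only the tabular writer converts to the 1-based inclusive BLAST convention.

#' Construct sequence records
#'
#' The in-memory representation used throughout the package: a data frame
#' with one row per sequence and columns `id`, `description`, `residues`
#' (uppercased).
#'
#' @param id character vector of unique ids.
#' @param residues nucleotide strings.
#' @param description optional descriptions (recycled).
#' @export
sequence_records <- function(id, residues, description = "") {
  data.frame(id = as.character(id),
             description = rep_len(as.character(description), length(id)),
             residues = toupper(as.character(residues)),
             stringsAsFactors = FALSE)
}

.check_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate %s id(s): %s", what,
                 paste(head(dup, 3L), collapse = ", ")), call. = FALSE)
}

.as_input_file <- function(path, text) {
  if (!is.null(text)) {
    tf <- tempfile(fileext = ".txt")
    writeLines(sub("\n$", "", paste(text, collapse = "")), tf)
    return(tf)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  path
}

#' Read a FASTA file
#'
#' Reads (optionally gzip-compressed) FASTA into a sequence-record data
#' frame. Residues are uppercased; soft-masking is ignored. The record id is
#' the first whitespace-delimited token of the header, the remainder becomes
#' the description. Duplicate ids and headerless sequence lines are format
#' errors; an empty file yields an empty record set.
#'
#' @param path path to a FASTA file (gzip accepted).
#' @param text literal FASTA text, as an alternative to `path`.
#' @return data frame with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path = NULL, text = NULL) {
  f <- .as_input_file(path, text)
  con <- gzfile(f, "r")
  on.exit(close(con))
  repeat {
    first <- readLines(con, n = 1L)
    if (length(first) == 0L)
      return(sequence_records(character(0), character(0)))
    if (nzchar(trimws(first))) break
  }
  if (!startsWith(first, ">"))
    stop("FASTA format error: sequence data before any header", call. = FALSE)
  set <- Biostrings::readDNAStringSet(f, format = "fasta")
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  .check_unique_ids(id, "FASTA")
  sequence_records(id, as.character(set), desc)
}

#' Read a FASTQ file
#'
#' Reads 4-line-per-record FASTQ (optionally gzip-compressed). Quality
#' strings are length-checked against the sequence and then discarded; the
#' search consumes sequence only. Truncated records and sequence/quality
#' length mismatches are format errors.
#'
#' @inheritParams read_fasta
#' @return data frame with columns `id`, `description`, `residues`.
#' @export
read_fastq <- function(path = NULL, text = NULL) {
  f <- .as_input_file(path, text)
  con <- gzfile(f, "r")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L)
    return(sequence_records(character(0), character(0)))
  if (length(lines) %% 4L != 0L)
    stop("FASTQ format error: truncated record", call. = FALSE)
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (!all(startsWith(hdr, "@")) || !all(startsWith(plus, "+")))
    stop("FASTQ format error: malformed record structure", call. = FALSE)
  if (any(nchar(seqs) != nchar(qual)))
    stop("FASTQ format error: sequence/quality length mismatch", call. = FALSE)
  hdr <- substring(hdr, 2L)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  .check_unique_ids(id, "FASTQ")
  sequence_records(id, seqs, desc)
}

#' Write sequence records as FASTA
#'
#' @param records sequence-record data frame.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read query sequences (FASTA or FASTQ)
#'
#' Format is sniffed from the first character (`>` FASTA, `@` FASTQ), after
#' transparent gzip decompression.
#'
#' @inheritParams read_fasta
#' @export
read_sequences <- function(path) {
  con <- gzfile(path, "r")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) return(sequence_records(character(0), character(0)))
  if (startsWith(first, "@")) read_fastq(path) else read_fasta(path)
}

#' Split long references into overlapping fragments
#'
#' References longer than the limit `L` are split into fragments of length
#' `L` starting at offsets `0, L - overlap, 2(L - overlap), ...`; consecutive
#' fragments of one parent overlap by exactly `overlap` bases (the last
#' fragment may be shorter). Concatenating the fragments with overlaps
#' removed reconstructs the parent exactly. References of length `<= L`
#' yield a single fragment at offset 0.
#'
#' @param records sequence-record data frame (one row per reference).
#' @param L maximum fragment length (default 64 Mb).
#' @param overlap overlap between consecutive fragments; must be `< L`.
#' @return data frame with columns `parent_id`, `fragment_index` (0-based),
#'   `parent_offset` (0-based), `residues`, `n_fragments`.
#' @export
split_reference <- function(records, L = 64000000L, overlap = 0L) {
  if (!(L >= 1)) stop("L must be >= 1", call. = FALSE)
  if (!(overlap >= 0)) stop("overlap must be >= 0", call. = FALSE)
  if (L <= overlap) stop("L must be greater than overlap", call. = FALSE)
  out <- lapply(seq_len(nrow(records)), function(i) {
    len <- nchar(records$residues[i])
    starts <- 0L
    while (utils::tail(starts, 1L) + L < len)
      starts <- c(starts, utils::tail(starts, 1L) + (L - overlap))
    data.frame(parent_id = records$id[i],
               fragment_index = seq_along(starts) - 1L,
               parent_offset = as.integer(starts),
               residues = substring(records$residues[i], starts + 1L,
                                    pmin(starts + L, len)),
               n_fragments = length(starts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Reverse complement
#'
#' Vectorized reverse complement over the IUPAC nucleotide alphabet
#' (`N` maps to `N`, ambiguity letters to their IUPAC complements).
#' Non-IUPAC characters are an error.
#'
#' @param residues character vector of nucleotide strings.
#' @export
reverse_complement <- function(residues) {
  cpp_revcomp(toupper(as.character(residues)))
}
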