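#' Construct a set of sequencing reads
#'
#' The container that flows through the whole pipeline: parallel vectors of
#' read identifiers, nucleotide sequences (over A, C, G, T, N) and per-base
#' Phred quality scores.
#'
#' @param id Character vector of unique, non-empty read identifiers.
#' @param seq Character vector of nucleotide sequences.
#' @param qual List of integer vectors of per-base Phred scores, one per read,
#'   each the same length as its sequence.
#' @return An object of class `read_set`.
#' @export
#' @examples
#' rs <- read_set("r1", "ACGT", list(c(30L, 30L, 30L, 30L)))
#' length(rs)
read_set <- function(id = character(), seq = character(), qual = list()) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  qual <- lapply(qual, as.integer)
  if (length(id) != length(seq) || length(id) != length(qual)) {
    stop("id, seq and qual must have equal length")
  }
  if (anyDuplicated(id)) stop("read ids must be unique")
  if (any(!nzchar(id))) stop("read ids must be non-empty")
  bad <- which(nchar(seq) != lengths(qual))
  if (length(bad)) {
    stop(sprintf("sequence/quality length mismatch for read '%s'", id[bad[1]]))
  }
  if (any(unlist(qual, use.names = FALSE) < 0L)) stop("Phred scores must be >= 0")
  structure(list(id = id, seq = seq, qual = qual), class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

#' @export
`[.read_set` <- function(x, i) {
  structure(list(id = x$id[i], seq = x$seq[i], qual = x$qual[i]),
            class = "read_set")
}

#' @export
c.read_set <- function(...) {
  parts <- list(...)
  read_set(
    id = unlist(lapply(parts, `[[`, "id"), use.names = FALSE),
    seq = unlist(lapply(parts, `[[`, "seq"), use.names = FALSE),
    qual = do.call(c, lapply(parts, `[[`, "qual"))
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set with %d read(s)\n", length(x)))
  if (length(x)) {
    n <- min(length(x), 5L)
    for (i in seq_len(n)) {
      cat(sprintf("  %s  %d nt  meanQ %.1f\n", x$id[i], nchar(x$seq[i]),
                  mean(x$qual[[i]])))
    }
    if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  }
  invisible(x)
}

#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records with Sanger (Phred+33) quality encoding.
#' Malformed records abort with an error naming the failing record.
#'
#' @param path Path to a FASTQ file.
#' @return A [read_set].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (!length(lines)) return(read_set())
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record %d in %s", length(lines) %/% 4L + 1L, path))
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qstr <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) stop(sprintf("malformed 4-line FASTQ record %d", bad[1]))
  bad <- which(nchar(seq) != nchar(qstr))
  if (length(bad)) {
    stop(sprintf("sequence/quality length mismatch in FASTQ record %d", bad[1]))
  }
  id <- sub("\\s.*$", "", substring(hdr, 2L))
  qual <- lapply(qstr, function(s) {
    if (!nzchar(s)) integer() else utf8ToInt(s) - 33L
  })
  read_set(id = id, seq = seq, qual = qual)
}

#' Write a FASTQ file
#'
#' @param reads A [read_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  qstr <- vapply(reads$qual, function(q) {
    if (!length(q)) "" else intToUtf8(q + 33L)
  }, character(1))
  out <- character(4L * length(reads))
  if (length(reads)) {
    out[seq(1L, by = 4L, length.out = length(reads))] <- paste0("@", reads$id)
    out[seq(2L, by = 4L, length.out = length(reads))] <- reads$seq
    out[seq(3L, by = 4L, length.out = length(reads))] <- "+"
    out[seq(4L, by = 4L, length.out = length(reads))] <- qstr
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences (names are the headers) or
#'   an unnamed vector together with `id`.
#' @param path Output path.
#' @param id Optional character vector of record identifiers.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, id = names(seqs)) {
  if (length(seqs) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (is.null(id)) stop("record ids are required")
  if (anyDuplicated(id)) stop("duplicate FASTA ids")
  x <- Biostrings::BStringSet(as.character(seqs))
  names(x) <- id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Construct a taxonomy-annotated reference set
#'
#' A reference set is a data frame with columns `accession`, `marker`,
#' `family`, `genus`, `species` and `sequence`; lineage labels are ordered
#' family -> genus -> species and must all be present.
#'
#' @param accession,marker,family,genus,species,sequence Parallel character
#'   vectors describing the reference barcodes.
#' @return A data frame of class `reference_set`.
#' @export
reference_set <- function(accession, marker, family, genus, species, sequence) {
  df <- data.frame(
    accession = as.character(accession), marker = as.character(marker),
    family = as.character(family), genus = as.character(genus),
    species = as.character(species), sequence = toupper(as.character(sequence)),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(df$family) | !nzchar(df$genus) | !nzchar(df$species))) {
    stop("every reference needs family, genus and species labels")
  }
  class(df) <- c("reference_set", "data.frame")
  df
}

#' Read a taxonomy-annotated reference FASTA
#'
#' Headers follow the dialect `accession|marker|family|genus|species`.
#'
#' @param path Path to the reference FASTA file.
#' @return A [reference_set].
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  hdr <- names(x)
  fields <- strsplit(hdr, "|", fixed = TRUE)
  bad <- which(lengths(fields) != 5L)
  if (length(bad)) {
    stop(sprintf("reference header '%s' does not have 5 pipe-separated fields",
                 hdr[bad[1]]))
  }
  m <- do.call(rbind, fields)
  reference_set(accession = m[, 1], marker = m[, 2], family = m[, 3],
                genus = m[, 4], species = m[, 5],
                sequence = as.character(x))
}

#' Write a taxonomy-annotated reference FASTA
#'
#' @param refs A [reference_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  stopifnot(inherits(refs, "reference_set"))
  hdr <- paste(refs$accession, refs$marker, refs$family, refs$genus,
               refs$species, sep = "|")
  write_fasta(refs$sequence, path, id = hdr)
}
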