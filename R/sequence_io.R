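#' Protein sequence record
#'
#' A named protein sequence plus the provenance of any cleaning applied to
#' it. Residue coordinates throughout the package are 1-based inclusive and,
#' after cleaning, always refer to the cleaned sequence.
#'
#' @param name free-text identifier (the full FASTA header after `>`).
#' @param residues character scalar of amino-acid letters (uppercased).
#' @param removed_positions data frame with columns `position` (original
#'   1-based coordinate) and `char` (removed character); empty unless
#'   [clean_sequence()] was applied.
#'
#' @return An object of class `nols_record`.
#' @export
sequence_record <- function(name, residues,
                            removed_positions = data.frame(position = integer(),
                                                           char = character())) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("record name must be a non-empty string")
  }
  stopifnot(is.character(residues), length(residues) == 1L)
  structure(list(name = name,
                 residues = toupper(residues),
                 removed_positions = removed_positions),
            class = "nols_record")
}

#' @export
print.nols_record <- function(x, ...) {
  cat(">", x$name, "\n")
  cat("  ", nchar(x$residues), " residues",
      if (nrow(x$removed_positions))
        paste0(" (", nrow(x$removed_positions), " removed by cleaning)"),
      "\n", sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Accepts single- or multi-record FASTA. Headers are taken as the full text
#' after `>` up to end of line (no tokenization). Sequence letters are
#' uppercased; no cleaning is applied — ambiguous characters are preserved
#' until [clean_sequence()] is called explicitly.
#'
#' @param source a file path, a connection, or a character vector of FASTA
#'   text (recognised when it contains a newline or starts with `>`).
#' @return A list of [sequence_record()] objects, in file order; empty input
#'   yields an empty list.
#' @export
#' @examples
#' recs <- read_fasta(">NOL12\nMGRNKKKKRDGDDRRPRLVL")
#' recs[[1]]$name
read_fasta <- function(source) {
  if (inherits(source, "connection")) {
    lines <- readLines(source, warn = FALSE)
  } else if (is.character(source) && length(source) == 1L && nzchar(source) &&
             !grepl("\n", source, fixed = TRUE) && !startsWith(source, ">")) {
    if (!file.exists(source)) stop("FASTA file not found: ", source)
    lines <- readLines(source, warn = FALSE)
  } else if (is.character(source)) {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    stop("source must be a path, connection or FASTA text")
  }
  # spec'd malformed-input diagnostics before delegating to Biostrings
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(list())
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence data before any '>' header at line ", first)
  }
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  set <- Biostrings::readBStringSet(tf)
  empty <- which(Biostrings::width(set) == 0L)
  if (length(empty)) {
    stop("empty sequence in record '", names(set)[empty[1]], "'")
  }
  res <- as.character(set)
  mapply(function(nm, sq) sequence_record(nm, sq),
         names(set), res, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Strip ambiguous characters from a sequence record
#'
#' Removes every character outside the 20 standard one-letter amino-acid
#' codes (B, J, O, U, X, Z, stop `*`, gaps, whitespace, digits, ...). Each
#' removal is logged with its original 1-based coordinate; positions in the
#' returned record refer to the cleaned sequence. Idempotent.
#'
#' @param record a [sequence_record()].
#' @return The cleaned `nols_record`.
#' @export
clean_sequence <- function(record) {
  stopifnot(inherits(record, "nols_record"))
  chars <- strsplit(record$residues, "")[[1]]
  keep <- chars %in% AA_STANDARD
  if (all(keep)) return(record)
  removed <- data.frame(position = which(!keep), char = chars[!keep])
  cleaned <- paste(chars[keep], collapse = "")
  if (!nzchar(cleaned)) {
    stop("record '", record$name, "' is empty after cleaning")
  }
  prior <- record$removed_positions
  if (nrow(prior)) removed <- rbind(prior, removed)
  sequence_record(record$name, cleaned, removed)
}

#' Write sequence records as FASTA
#'
#' Standard FASTA output with sequence lines wrapped at 60 columns.
#'
#' @param records a list of [sequence_record()] objects (a single record is
#'   accepted).
#' @param sink output file path or connection.
#' @return `sink`, invisibly.
#' @export
write_fasta <- function(records, sink) {
  if (inherits(records, "nols_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "nols_record")))
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "residues"))
  names(set) <- vapply(records, `[[`, character(1), "name")
  Biostrings::writeXStringSet(set, sink, width = 60L)
  invisible(sink)
}
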