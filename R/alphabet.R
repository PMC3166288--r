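#' @keywords internal
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a reduced amino-acid alphabet
#'
#' A reduced alphabet partitions the 20 standard amino acids into exactly 12
#' disjoint, non-empty groups. Window encoding replaces every residue by the
#' index of its group before one-hot encoding, shrinking the feature space
#' from 20 to 12 symbols per window position.
#'
#' @param groups named list (or character vector) of 12 residue strings, e.g.
#'   `c(basic = "KR", acidic = "DE", ...)`. Groups must be disjoint and
#'   jointly cover all 20 standard residues.
#' @param name identifier of the grouping scheme.
#'
#' @return An object of class `reduced_alphabet` with elements `name`,
#'   `groups` (named list of character vectors) and `index` (named integer
#'   vector mapping each residue to its group, 1-based).
#' @seealso [default_alphabet()], [read_alphabet()], [write_alphabet()]
#' @export
#' @examples
#' ab <- default_alphabet()
#' ab$index[["K"]] == ab$index[["R"]]
reduced_alphabet <- function(groups, name = "custom") {
  if (is.character(groups)) {
    nm <- names(groups)
    groups <- lapply(groups, function(g) strsplit(g, "")[[1]])
    names(groups) <- nm
  }
  if (length(groups) != 12L) {
    stop("a reduced alphabet must have exactly 12 groups, got ", length(groups))
  }
  if (is.null(names(groups)) || anyDuplicated(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must have unique non-empty names")
  }
  groups <- lapply(groups, function(g) sort(toupper(g)))
  all_res <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_res)) {
    stop("groups overlap: ", paste(all_res[duplicated(all_res)], collapse = ", "))
  }
  missing <- setdiff(AA_STANDARD, all_res)
  extra <- setdiff(all_res, AA_STANDARD)
  if (length(missing)) stop("residues not covered by any group: ", paste(missing, collapse = ", "))
  if (length(extra)) stop("non-standard residues in groups: ", paste(extra, collapse = ", "))
  index <- integer(0)
  for (g in seq_along(groups)) {
    idx <- rep.int(g, length(groups[[g]]))
    names(idx) <- groups[[g]]
    index <- c(index, idx)
  }
  index <- index[AA_STANDARD]
  structure(list(name = name, groups = groups, index = index),
            class = "reduced_alphabet")
}

#' Default 12-group reduced alphabet
#'
#' The grouping keeps the basic residues K/R — the dominant NoLS signal — as
#' a group of their own and merges standard physicochemical classes to reach
#' exactly 12 groups. Any alternative 12-group scheme can be supplied via
#' [reduced_alphabet()] or an alphabet config file; the alphabet is embedded
#' in every saved model so predictions stay reproducible.
#'
#' @return A `reduced_alphabet`.
#' @export
default_alphabet <- function() {
  reduced_alphabet(
    c(basic = "KR", acidic = "DE", hydroxyl = "ST", amide = "NQ",
      aliphatic = "ILV", aromatic = "FY", alanine = "A", glycine = "G",
      proline = "P", cysteine = "C", methionine = "M", bulky = "HW"),
    name = "default12"
  )
}

#' Read / write an alphabet config file
#'
#' Plain-text key-value format, one group per line: `name: RESIDUES`.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param name scheme identifier recorded in the alphabet (read only).
#' @return `read_alphabet()` returns a `reduced_alphabet`;
#'   `write_alphabet()` returns `path` invisibly.
#' @export
read_alphabet <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- regmatches(lines, regexec("^([^:]+):\\s*([A-Za-z]+)$", lines))
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop("malformed alphabet line: '", lines[bad[1]], "'")
  groups <- vapply(parts, `[`, character(1), 3L)
  names(groups) <- trimws(vapply(parts, `[`, character(1), 2L))
  reduced_alphabet(groups, name = name)
}

#' @rdname read_alphabet
#' @param alphabet a `reduced_alphabet`.
#' @export
write_alphabet <- function(alphabet, path) {
  stopifnot(inherits(alphabet, "reduced_alphabet"))
  lines <- vapply(seq_along(alphabet$groups), function(i) {
    paste0(names(alphabet$groups)[i], ": ",
           paste(alphabet$groups[[i]], collapse = ""))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.reduced_alphabet <- function(x, ...) {
  cat("Reduced amino-acid alphabet '", x$name, "' (", length(x$groups),
      " groups)\n", sep = "")
  for (i in seq_along(x$groups)) {
    cat(sprintf("  %2d %-11s %s\n", i, names(x$groups)[i],
                paste(x$groups[[i]], collapse = "")))
  }
  invisible(x)
}

# stable fingerprint used to detect model/alphabet mismatch on load
alphabet_fingerprint <- function(alphabet) {
  key <- paste(vapply(alphabet$groups, paste, character(1), collapse = ""),
               collapse = "|")
  codes <- utf8ToInt(key)
  # order-sensitive polynomial checksum, deterministic across platforms
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  sprintf("%s-%d", key, h)
}
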