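# Sequence containers and FASTA IO.
#
# A `seq_set` is an ordered collection of sequence records (ids, residue
# strings, one molecule type); an `alignment` additionally requires >= 2
# records of identical length. Residues are stored upper-case; the legal
# alphabet is the molecule's states plus '-' (gap) and 'X'/'N' (ambiguity).

AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
DNA_STATES <- c("A", "C", "G", "T")

mol_states <- function(molecule) {
  switch(molecule, protein = AA_STATES, dna = DNA_STATES,
         stop("unknown molecule type: ", molecule))
}

mol_ambiguity <- function(molecule) switch(molecule, protein = "X", dna = "N")

#' Create a sequence set
#'
#' @param ids character vector of unique, non-empty record ids.
#' @param seqs character vector of residue strings (same length as `ids`).
#' @param molecule `"protein"` or `"dna"`.
#' @return An object of class `seq_set` with elements `ids`, `seqs`
#'   (upper-cased), and `molecule`.
#' @export
seq_set <- function(ids, seqs, molecule = c("protein", "dna")) {
  molecule <- match.arg(molecule)
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (any(!nzchar(ids))) stop("record ids must be non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  allowed <- c(mol_states(molecule), "-", mol_ambiguity(molecule))
  bad <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    any(!ch %in% allowed)
  }, logical(1))
  if (any(bad)) {
    stop("illegal ", molecule, " character(s) in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  structure(list(ids = ids, seqs = seqs, molecule = molecule), class = "seq_set")
}

#' Assemble an alignment from sequence records
#'
#' Validates the alignment invariants: at least two records, all residue
#' strings the same length, one molecule type.
#'
#' @param x a `seq_set`, or character vector of ids when `seqs` is given.
#' @param seqs,molecule used when `x` is not already a `seq_set`.
#' @return An object of class `c("alignment", "seq_set")` with an extra
#'   `length` element (number of columns).
#' @export
alignment <- function(x, seqs = NULL, molecule = c("protein", "dna")) {
  if (!inherits(x, "seq_set")) x <- seq_set(x, seqs, molecule)
  if (length(x$ids) < 2) stop("an alignment needs >= 2 records")
  lens <- nchar(x$seqs)
  if (length(unique(lens)) != 1) {
    stop("unequal sequence lengths: ",
         paste(paste0(x$ids, "=", lens), collapse = ", "))
  }
  x$length <- lens[[1]]
  class(x) <- c("alignment", "seq_set")
  x
}

#' @export
print.seq_set <- function(x, ...) {
  kind <- if (inherits(x, "alignment")) "alignment" else "sequence set"
  cat(sprintf("%s: %d %s record(s)", kind, length(x$ids), x$molecule))
  if (inherits(x, "alignment")) cat(sprintf(", %d columns", x$length))
  cat("\n")
  invisible(x)
}

# residues as a records x columns character matrix
aln_char_matrix <- function(x) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

# TRUE where the residue is a state character (not gap, not ambiguity)
aln_state_mask <- function(x) {
  m <- aln_char_matrix(x)
  m != "-" & m != mol_ambiguity(x$molecule)
}

aln_subset_columns <- function(x, cols) {
  m <- aln_char_matrix(x)[, cols, drop = FALSE]
  out <- list(ids = x$ids,
              seqs = apply(m, 1, paste, collapse = ""),
              molecule = x$molecule,
              length = length(cols))
  class(out) <- class(x)
  out
}

#' Read a FASTA file or string
#'
#' Strict parser: rejects duplicate ids, empty sequences, and characters
#' outside the declared alphabet (reported with the offending line number).
#' Gaps (`-`) are retained, record order is preserved, residues are stored
#' upper-case.
#'
#' @param source path to a FASTA file, or FASTA text itself.
#' @param molecule `"protein"` or `"dna"`.
#' @return a [seq_set()].
#' @export
read_fasta <- function(source, molecule = c("protein", "dna")) {
  molecule <- match.arg(molecule)
  lines <- read_source_lines(source, starter = ">")
  allowed <- c(mol_states(molecule), "-", mol_ambiguity(molecule))
  ids <- character()
  seqs <- character()
  cur_id <- NULL
  cur_seq <- character()
  flush <- function() {
    if (is.null(cur_id)) return()
    if (length(cur_seq) == 0 || !nzchar(paste(cur_seq, collapse = ""))) {
      stop("empty sequence for record '", cur_id, "'")
    }
    ids[[length(ids) + 1L]] <<- cur_id
    seqs[[length(seqs) + 1L]] <<- paste(cur_seq, collapse = "")
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush()
      cur_id <- strsplit(sub("^>", "", line), "[ \t]")[[1]][[1]]
      if (is.na(cur_id) || !nzchar(cur_id)) {
        stop("empty FASTA header at line ", i)
      }
      if (cur_id %in% ids) stop("duplicate record id '", cur_id, "' at line ", i)
      cur_seq <- character()
    } else {
      if (is.null(cur_id)) stop("sequence data before any header at line ", i)
      chunk <- toupper(gsub("[ \t]", "", line))
      ch <- strsplit(chunk, "", fixed = TRUE)[[1]]
      bad <- which(!ch %in% allowed)
      if (length(bad)) {
        stop("illegal ", molecule, " character '", ch[bad[[1]]],
             "' at line ", i, " (record '", cur_id, "')")
      }
      cur_seq[[length(cur_seq) + 1L]] <- chunk
    }
  }
  flush()
  seq_set(ids, seqs, molecule)
}

#' Write FASTA text
#'
#' Deterministic, byte-identical output for identical input.
#'
#' @param x a `seq_set` (or `alignment`).
#' @param path optional output file; when `NULL` the text is returned only.
#' @param width residues per line (default 60).
#' @return the FASTA text, invisibly when `path` is given.
#' @export
write_fasta <- function(x, path = NULL, width = 60) {
  stopifnot(inherits(x, "seq_set"), width >= 1)
  out <- character()
  for (i in seq_along(x$ids)) {
    s <- x$seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, paste0(">", x$ids[[i]]),
             substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  txt <- if (length(out)) paste0(paste(out, collapse = "\n"), "\n") else ""
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

# Shared helper: `source` is file path unless it looks like literal content.
read_source_lines <- function(source, starter) {
  stopifnot(is.character(source), length(source) == 1)
  looks_literal <- grepl("\n", source, fixed = TRUE) ||
    startsWith(trimws(source), starter)
  if (!looks_literal && file.exists(source)) return(readLines(source, warn = FALSE))
  strsplit(source, "\n", fixed = TRUE)[[1]]
}
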