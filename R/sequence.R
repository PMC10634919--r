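#' @useDynLib ewsphase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef fft lm median nls optim quantile rnorm runif sd
#'   setNames var vcov acf approx
#' @importFrom utils head read.table write.table tail
NULL

AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a protein sequence object
#'
#' A lightweight container for a one-letter amino-acid string together with a
#' residue-numbering offset, used throughout the package for composition,
#' motif, mutant and topology-building operations. Residue numbers are
#' `start_index + position - 1`, so cloning scars or truncated constructs can
#' keep the numbering of the parent protein.
#'
#' @param residues character scalar over the 20 canonical one-letter codes
#'   (case-insensitive).
#' @param name text label for the sequence.
#' @param start_index residue number of the first residue (default 1).
#' @return An object of class `protein_sequence` with fields `name`,
#'   `residues` (uppercase string) and `start_index`.
#' @examples
#' seq <- protein_sequence("SGYGQS", name = "toy")
#' nchar(seq$residues)
#' @export
protein_sequence <- function(residues, name = "seq", start_index = 1L) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L) {
    stop("sequence must contain at least one residue")
  }
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), AA_CODES)
  if (length(bad) > 0L) {
    stop("non-canonical residue code(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(name = name, residues = residues,
         start_index = as.integer(start_index)),
    class = "protein_sequence"
  )
}

#' @export
print.protein_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("protein_sequence '%s': %d residues (numbered %d-%d)\n",
              x$name, n, x$start_index, x$start_index + n - 1L))
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) nchar(x$residues)

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

#' Amino-acid composition profile
#'
#' Percent abundance of each of the 20 canonical amino acids, including
#' explicit zero rows for residue types absent from the sequence.
#'
#' @param seq a [protein_sequence()].
#' @return data.frame with columns `aa`, `count`, `percent`; percentages sum
#'   to 100.
#' @export
composition_profile <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  chars <- seq_chars(seq)
  counts <- vapply(AA_CODES, function(a) sum(chars == a), integer(1))
  data.frame(aa = AA_CODES, count = unname(counts),
             percent = unname(100 * counts / length(chars)),
             stringsAsFactors = FALSE)
}

#' Positions of selected residue types
#'
#' Residue numbers (respecting `start_index`) at which each requested residue
#' type occurs, as used for amino-acid distribution plots along the chain.
#'
#' @param seq a [protein_sequence()].
#' @param residue_types character vector of one-letter codes.
#' @return named list, one sorted integer vector of residue numbers per type.
#' @export
residue_positions <- function(seq, residue_types) {
  stopifnot(inherits(seq, "protein_sequence"))
  residue_types <- toupper(residue_types)
  bad <- setdiff(residue_types, AA_CODES)
  if (length(bad) > 0L) {
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  }
  chars <- seq_chars(seq)
  out <- lapply(residue_types, function(a) {
    which(chars == a) + seq$start_index - 1L
  })
  names(out) <- residue_types
  out
}

#' Scan a sequence for tyrosine YxY / YxxY motifs
#'
#' Enumerates all tyrosine pairs spaced by one intervening residue (YxY) or
#' two (YxxY); tyrosines participating in neither pairing are reported as
#' isolated. A tyrosine may belong to several motifs: counts enumerate motif
#' pairs, not tyrosines, so a run like "YAYAAY" yields one YxY and one YxxY
#' sharing the middle tyrosine.
#'
#' @param seq a [protein_sequence()].
#' @return data.frame with columns `kind` ("YxY", "YxxY" or "isolated"),
#'   `first_position`, `second_position` (NA for isolated hits), in residue
#'   numbers.
#' @export
find_tyrosine_motifs <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  chars <- seq_chars(seq)
  ypos <- which(chars == "Y")
  hits <- data.frame(kind = character(0), first_position = integer(0),
                     second_position = integer(0), stringsAsFactors = FALSE)
  paired <- integer(0)
  for (i in ypos) {
    if ((i + 2L) <= length(chars) && chars[i + 2L] == "Y") {
      hits <- rbind(hits, data.frame(kind = "YxY", first_position = i,
                                     second_position = i + 2L))
      paired <- c(paired, i, i + 2L)
    }
    if ((i + 3L) <= length(chars) && chars[i + 3L] == "Y") {
      hits <- rbind(hits, data.frame(kind = "YxxY", first_position = i,
                                     second_position = i + 3L))
      paired <- c(paired, i, i + 3L)
    }
  }
  isolated <- setdiff(ypos, unique(paired))
  if (length(isolated) > 0L) {
    hits <- rbind(hits, data.frame(kind = "isolated",
                                   first_position = isolated,
                                   second_position = NA_integer_))
  }
  if (nrow(hits) > 0L) {
    off <- seq$start_index - 1L
    hits$first_position <- hits$first_position + off
    hits$second_position <- hits$second_position + off
    hits <- hits[order(match(hits$kind, c("YxY", "YxxY", "isolated")),
                       hits$first_position), , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

#' Construct a mutation set
#'
#' A labelled list of point substitutions, given either as parallel vectors or
#' as compact strings like `"Y170S"`. Positions are residue numbers in the
#' numbering convention of the target sequence.
#'
#' @param spec character vector of compact mutation strings ("Y170S"), or NULL
#'   when `position`/`from_aa`/`to_aa` are given.
#' @param position,from_aa,to_aa parallel vectors describing the substitutions.
#' @param label text label for the set (e.g. "7YS").
#' @return object of class `mutation_set`: data.frame of `position`,
#'   `from_aa`, `to_aa` plus a `label` attribute.
#' @export
mutation_set <- function(spec = NULL, position = NULL, from_aa = NULL,
                         to_aa = NULL, label = "mutant") {
  if (!is.null(spec)) {
    m <- regmatches(spec, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", spec))
    if (any(vapply(m, length, integer(1)) != 4L)) {
      stop("malformed mutation string; expected e.g. 'Y170S'")
    }
    from_aa <- toupper(vapply(m, `[`, character(1), 2L))
    position <- as.integer(vapply(m, `[`, character(1), 3L))
    to_aa <- toupper(vapply(m, `[`, character(1), 4L))
  }
  stopifnot(length(position) == length(from_aa),
            length(position) == length(to_aa))
  if (anyDuplicated(position)) stop("mutation positions must be unique")
  bad <- setdiff(unique(c(from_aa, to_aa)), AA_CODES)
  if (length(bad) > 0L) stop("unknown residue code(s): ",
                             paste(bad, collapse = ", "))
  out <- data.frame(position = as.integer(position), from_aa = from_aa,
                    to_aa = to_aa, stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("mutation_set", "data.frame")
  out
}

#' Read a mutation set from delimited text
#'
#' Accepts either a headered table with columns `position,from,to` or a file
#' of compact strings (one "Y170S" per line).
#'
#' @param path file path.
#' @param label label for the returned set (defaults to the file name).
#' @return a [mutation_set()].
#' @export
read_mutation_set <- function(path, label = basename(path)) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first)) {
    tab <- read.table(path, sep = ",", header = grepl("[A-Za-z]{2,}", first),
                      stringsAsFactors = FALSE)
    names(tab)[1:3] <- c("position", "from", "to")
    mutation_set(position = tab$position, from_aa = tab$from, to_aa = tab$to,
                 label = label)
  } else {
    lines <- readLines(path)
    lines <- trimws(lines[nzchar(trimws(lines))])
    mutation_set(spec = lines, label = label)
  }
}

#' Apply point mutations to a sequence
#'
#' Validates that each `from_aa` matches the sequence at its position (a
#' mismatch usually signals a numbering-convention error) and returns the
#' mutated sequence with the set's label appended to the name.
#'
#' @param seq a [protein_sequence()].
#' @param muts a [mutation_set()].
#' @return a new [protein_sequence()] of the same length and numbering.
#' @export
apply_mutations <- function(seq, muts) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(muts, "mutation_set"))
  chars <- seq_chars(seq)
  if (nrow(muts) == 0L) return(seq)
  idx <- muts$position - seq$start_index + 1L
  if (any(idx < 1L | idx > length(chars))) {
    stop("mutation position out of range")
  }
  mism <- chars[idx] != muts$from_aa
  if (any(mism)) {
    stop("from_aa mismatch at position(s) ",
         paste(muts$position[mism], collapse = ", "),
         " (sequence has ", paste(chars[idx][mism], collapse = ", "), ")")
  }
  chars[idx] <- muts$to_aa
  protein_sequence(paste(chars, collapse = ""),
                   name = paste0(seq$name, ",", attr(muts, "label")),
                   start_index = seq$start_index)
}

#' Invert a mutation set
#'
#' @param muts a [mutation_set()].
#' @return the set with `from_aa`/`to_aa` swapped; applying it undoes the
#'   original mutations.
#' @export
invert_mutations <- function(muts) {
  stopifnot(inherits(muts, "mutation_set"))
  mutation_set(position = muts$position, from_aa = muts$to_aa,
               to_aa = muts$from_aa,
               label = paste0("rev-", attr(muts, "label")))
}

#' Read protein sequences from FASTA
#'
#' Minimal single/multi-record FASTA reader returning
#' [protein_sequence()] objects. Blank lines are skipped; sequence lines are
#' concatenated and upper-cased.
#'
#' @param path FASTA file path.
#' @param start_index numbering of the first residue of every record.
#' @return named list of [protein_sequence()] objects.
#' @export
read_fasta_sequences <- function(path, start_index = 1L) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  grp <- cumsum(hdr)
  out <- lapply(split(lines, grp), function(block) {
    name <- sub("^>\\s*", "", block[1])
    name <- strsplit(name, "\\s+")[[1]][1]
    protein_sequence(paste(block[-1], collapse = ""), name = name,
                     start_index = start_index)
  })
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs a [protein_sequence()] or list of them.
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$name), con)
    n <- nchar(s$residues)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s$residues, starts, pmin(starts + width - 1L, n)),
               con)
  }
  invisible(path)
}
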