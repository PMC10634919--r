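#' Write an analysis table to delimited text or JSON
#'
#' Dispatches on the file extension: ".csv"/".tsv" delimited text with header,
#' ".json" via jsonlite. Used by the analysis drivers to export profiles,
#' contact tables and binodals.
#'
#' @param x data.frame (or coercible).
#' @param path output path ending in .csv, .tsv or .json.
#' @return `path`, invisibly.
#' @export
write_analysis_table <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  x <- as.data.frame(x)
  if (ext == "csv") {
    write.table(x, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else if (ext == "tsv") {
    write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, dataframe = "columns", digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    stop("unsupported extension: ", ext)
  }
  invisible(path)
}

#' Read a peak-intensity table from delimited text
#'
#' Expects a header and the long format `residue, delay_s, intensity` (or
#' `residue, condition, intensity` for heteronuclear NOE pairs) and reshapes
#' it into a [peak_table()].
#'
#' @param path delimited text file (comma or tab separated).
#' @param kind experiment kind, see [peak_table()].
#' @return a [peak_table()].
#' @export
read_peak_table <- function(path, kind = c("T1", "T1rho", "two_point_T2",
                                           "hetNOE_pair")) {
  kind <- match.arg(kind)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("residue", "delay", "intensity")
  residues <- sort(unique(tab$residue))
  delays <- unique(tab$delay)
  mat <- matrix(NA_real_, length(residues), length(delays))
  for (i in seq_len(nrow(tab))) {
    mat[match(tab$residue[i], residues), match(tab$delay[i], delays)] <-
      tab$intensity[i]
  }
  peak_table(kind = kind, residues = residues, delays = delays,
             intensities = mat)
}
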