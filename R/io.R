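#' Read a Ct table from TSV/CSV
#'
#' Reads a long-format qPCR table with header columns exactly `gene`,
#' `colony`, `zt`, `replicate`, `ct` (UTF-8, '.' decimal point). The
#' delimiter is taken from the file extension (`.csv` is comma-separated,
#' anything else tab-separated). Malformed rows and duplicate
#' (gene, colony, zt, replicate) keys are rejected.
#'
#' @param path Path to the file.
#' @return Validated Ct tibble.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  data <- suppressWarnings(reader(
    path,
    col_types = readr::cols(
      gene = readr::col_character(),
      colony = readr::col_character(),
      zt = readr::col_double(),
      replicate = readr::col_integer(),
      ct = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed Ct table at line %d: expected %s",
                  probs$row[1], probs$expected[1]))
  }
  if (any(is.na(data))) {
    abort(sprintf("missing value in Ct table at data row %d",
                  which(rowSums(is.na(data)) > 0)[1]))
  }
  validate_ct_records(data)
}

#' Write a tidy table as TSV
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' Sequence ids are the header text up to the first whitespace; residues
#' are uppercased. Empty records and gap characters are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id` and `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort("FASTA file contains no records")
  ids <- sub("\\s.*$", "", names(seqs))
  residues <- toupper(as.character(seqs))
  if (any(nchar(residues) == 0)) {
    abort(sprintf("empty FASTA record: %s", ids[nchar(residues) == 0][1]))
  }
  if (any(grepl("-", residues, fixed = TRUE))) {
    abort("FASTA sequences must not contain gap characters")
  }
  tibble(id = unname(ids), residues = unname(residues))
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id` and `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
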