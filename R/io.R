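#' Read a transcriptome from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file of transcript
#' models into a tibble. The header token before the first whitespace becomes
#' the transcript id and the remainder the description. Sequences are
#' uppercased and `U` is mapped to `T`, so RNA-style transcript FASTA is
#' accepted; the resulting alphabet must be restricted to `A`, `C`, `G`, `T`,
#' `N`.
#'
#' @param path Path to an existing FASTA file.
#'
#' @return A tibble with one row per record and columns `id`, `sequence`,
#'   `description`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">t1 first model", "ACGTACGT", ">t2", "GGGCCC"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("Could not parse FASTA: ", conditionMessage(e)))
  )
  if (length(set) == 0) abort("FASTA file contains no records.")
  headers <- names(set)
  if (is.null(headers)) headers <- rep("", length(set))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    abort(paste0("Record ", which(!nzchar(ids))[1], " has an empty id."))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate transcript id in FASTA: '", dup[1], "'."))
  }
  seqs <- chartr("U", "T", toupper(as.character(set)))
  bad <- stringr::str_locate(seqs, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(paste0(
      "Invalid character '", substr(seqs[i], bad[i], bad[i]),
      "' in record '", ids[i], "' at position ", bad[i],
      " (allowed: A, C, G, T, N, U)."
    ))
  }
  if (any(nchar(seqs) < 1)) {
    i <- which(nchar(seqs) < 1)[1]
    abort(paste0("Record '", ids[i], "' has an empty sequence."))
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs),
                 description = unname(desc))
}

probe_table_cols <- c(
  "probe_id", "transcript_id", "start", "sequence",
  "gc_percent", "tm_celsius", "position_score", "origin"
)

#' Write a probe table as TSV
#'
#' Writes probes in a stable tab-separated format (UTF-8, header row, `.`
#' decimal separator) with columns `probe_id`, `transcript_id`, `start`,
#' `sequence`, `gc_percent`, `tm_celsius`, `position_score`, `origin`.
#' The format round-trips losslessly through [read_probe_table()].
#'
#' @param probes A probe tibble, e.g. `tidy(design_array(...))`. Extra
#'   columns are dropped; an empty table yields a header-only file.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_probe_table()], [design_array()]
#' @export
write_probe_table <- function(probes, path) {
  missing_cols <- setdiff(probe_table_cols, names(probes))
  if (length(missing_cols) > 0) {
    abort(paste0("Probe table lacks column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  out <- dplyr::select(probes, dplyr::all_of(probe_table_cols))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a probe table written by [write_probe_table()]
#'
#' Validates that probe ids are unique and that all probes share one length
#' (mixed-length probe sets are rejected).
#'
#' @param path Path to a probe TSV.
#' @return A probe tibble in file order.
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) abort(paste0("Probe table not found: ", path))
  probes <- readr::read_tsv(
    path,
    col_types = readr::cols(
      probe_id = readr::col_character(),
      transcript_id = readr::col_character(),
      start = readr::col_integer(),
      sequence = readr::col_character(),
      gc_percent = readr::col_double(),
      tm_celsius = readr::col_double(),
      position_score = readr::col_double(),
      origin = readr::col_character()
    ),
    progress = FALSE
  )
  if (nrow(probes) > 0) {
    dup <- probes$probe_id[duplicated(probes$probe_id)]
    if (length(dup) > 0) {
      abort(paste0("Duplicate probe_id in table: '", dup[1], "'."))
    }
    len <- unique(nchar(probes$sequence))
    if (length(len) > 1) {
      abort("Probe table mixes probe lengths; a single length is required.")
    }
  }
  probes
}
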