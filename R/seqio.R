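#' @useDynLib orthosub, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Residue alphabets. Ambiguity letters are accepted on input but never
# proposed as replacements and score 0 wherever the matrix has no entry.
CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AMBIGUITY_AA <- c("X", "B", "Z", "U")
ALLOWED_AA <- c(CANONICAL_AA, AMBIGUITY_AA)

#' Construct a protein sequence record
#'
#' A sequence record is a one-row tibble with columns `id`, `description`
#' and `residues`. Residues are uppercased and validated against the 20
#' canonical amino-acid letters plus the ambiguity letters X, B, Z and U;
#' `*` stop symbols and whitespace are stripped. Gap characters are
#' rejected: records hold plain, unaligned sequences.
#'
#' @param id Record identifier (first whitespace-delimited token of a FASTA
#'   header); must be a non-empty string without whitespace.
#' @param residues Amino-acid sequence as a single string.
#' @param description Free-text description (may be empty).
#' @return A one-row tibble with columns `id`, `description`, `residues`.
#' @examples
#' seq_record("q1", "mkva*")
#' @export
seq_record <- function(id, residues, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) ||
      grepl("[[:space:]]", id)) {
    abort("`id` must be a single non-empty token without whitespace")
  }
  residues <- normalize_residues(residues, id)
  tibble(id = id, description = description %||% "", residues = residues)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_residues <- function(residues, id) {
  if (!is.character(residues) || length(residues) != 1L) {
    abort("`residues` must be a single string")
  }
  residues <- toupper(gsub("[*[:space:]]", "", residues))
  if (!nzchar(residues)) {
    abort(sprintf("record '%s' has an empty sequence", id))
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% ALLOWED_AA)
  if (length(bad)) {
    abort(sprintf(
      "invalid residue '%s' at position %d in record '%s'",
      chars[bad[1]], bad[1], id
    ))
  }
  residues
}

#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order (file order is the tie-break when
#' homologs are ranked). Lowercase residues are uppercased; `*` stop
#' symbols and whitespace are stripped; any character outside the allowed
#' alphabet after normalization is an error reporting the offending
#' position. Duplicate ids are an error: the id is the join key in all
#' downstream reports.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record and columns `id`,
#'   `description`, `residues`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  xs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("cannot read FASTA '%s': %s",
                                      path, conditionMessage(e)))
  )
  if (length(xs) == 0L) {
    abort(sprintf("no sequences in '%s'", path))
  }
  headers <- trimws(names(xs))
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(ids == headers, "",
                 trimws(sub("^[^[:space:]]+[[:space:]]+", "", headers)))
  if (any(!nzchar(ids))) {
    abort(sprintf("record %d has an empty header", which(!nzchar(ids))[1]))
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    abort(sprintf("duplicate sequence id '%s' in '%s'", dup[1], path))
  }
  seqs <- unname(as.character(xs))
  out <- purrr::map(seq_along(ids), function(i) {
    seq_record(ids[i], seqs[i], desc[i])
  })
  dplyr::bind_rows(out)
}

#' Write protein sequences to a FASTA file
#'
#' Output is re-readable by [read_fasta()], reproducing ids, descriptions
#' and residues exactly.
#'
#' @param records A tibble of sequence records (columns `id`,
#'   `description`, `residues`).
#' @param path Output path.
#' @param line_width Residues per sequence line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  validate_seq_records(records)
  headers <- ifelse(nzchar(records$description),
                    paste(records$id, records$description),
                    records$id)
  xs <- Biostrings::BStringSet(stats::setNames(records$residues, headers))
  Biostrings::writeXStringSet(xs, path, width = as.integer(line_width))
  invisible(path)
}

validate_seq_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("id", "residues") %in% names(records)) || nrow(records) == 0L) {
    abort("expected a non-empty tibble of sequence records (id, residues)")
  }
  if (!"description" %in% names(records)) {
    records$description <- ""
  }
  dup <- records$id[duplicated(records$id)]
  if (length(dup)) {
    abort(sprintf("duplicate sequence id '%s'", dup[1]))
  }
  invisible(records)
}

seq_length <- function(record) nchar(record$residues[1])

residue_at <- function(residues, pos) substr(residues, pos, pos)
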