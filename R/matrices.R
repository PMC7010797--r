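.orthosub_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' Integer log-odds scores for ordered residue pairs, identical to the
#' EMBOSS `EBLOSUM62` values used by classical local-alignment tools.
#' Includes rows for the ambiguity letters B, Z and X; pairs without a
#' matrix entry (e.g. involving U) score 0 during alignment.
#'
#' @return A symmetric integer matrix with residue-letter dimnames and a
#'   `"matrix_name"` attribute.
#' @export
blosum62 <- function() {
  if (is.null(.orthosub_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    attr(m, "matrix_name") <- "BLOSUM62"
    .orthosub_env$blosum62 <- validate_score_matrix(m)
  }
  .orthosub_env$blosum62
}

#' Read a substitution matrix in NCBI/EMBOSS text format
#'
#' Parses the plain-text matrix layout used by NCBI and the EMBOSS data
#' directory: `#` comment lines, a header row of column letters, then one
#' row per residue letter with integer scores.
#'
#' @param path Path to the matrix file.
#' @param name Matrix name recorded in reports; defaults to the file name.
#' @return A symmetric numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) abort(sprintf("'%s' is not a matrix file", path))
  cols <- strsplit(lines[1], "[[:space:]]+")[[1]]
  rows <- strsplit(lines[-1], "[[:space:]]+")
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
              dimnames = list(vapply(rows, `[`, "", 1L), cols))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1]))
    if (length(v) != length(cols) || anyNA(v)) {
      abort(sprintf("malformed matrix row '%s' in '%s'", rows[[i]][1], path))
    }
    m[i, ] <- v
  }
  attr(m, "matrix_name") <- name
  validate_score_matrix(m)
}

validate_score_matrix <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    abort("substitution matrix must have residue-letter dimnames")
  }
  shared <- intersect(rownames(m), colnames(m))
  s <- m[shared, shared, drop = FALSE]
  if (!isTRUE(all.equal(s, t(s), check.attributes = FALSE))) {
    abort("substitution matrix is not symmetric")
  }
  canon <- intersect(CANONICAL_AA, shared)
  if (any(diag(s[canon, canon, drop = FALSE]) <= 0)) {
    abort("every canonical diagonal entry must be positive")
  }
  m
}

# Score for one residue pair; 0 when the matrix lacks either letter.
score_pair <- function(matrix, a, b) {
  ia <- match(a, rownames(matrix))
  ib <- match(b, colnames(matrix))
  s <- rep(0, length(ia))
  ok <- !is.na(ia) & !is.na(ib)
  s[ok] <- matrix[cbind(ia[ok], ib[ok])]
  s
}

#' Alignment parameters
#'
#' Bundles the substitution matrix and affine gap penalties used for every
#' pairwise alignment. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. Defaults follow the classical
#' Smith-Waterman tooling for proteins: BLOSUM62, gap open 10, gap
#' extend 0.5. These defaults are configurable and are recorded in every
#' report and run manifest.
#'
#' @param gap_open Penalty charged when a gap is opened (>= `gap_extend`).
#' @param gap_extend Penalty per additional gapped position (>= 0).
#' @param matrix Substitution matrix (see [blosum62()],
#'   [read_score_matrix()]).
#' @return An object of class `align_params`.
#' @export
align_params <- function(gap_open = 10, gap_extend = 0.5,
                         matrix = blosum62()) {
  if (!is.numeric(gap_open) || !is.numeric(gap_extend) ||
      gap_extend < 0 || gap_open < gap_extend) {
    abort("need gap_open >= gap_extend >= 0")
  }
  structure(
    list(gap_open = as.numeric(gap_open),
         gap_extend = as.numeric(gap_extend),
         matrix = validate_score_matrix(matrix),
         matrix_name = attr(matrix, "matrix_name") %||% "custom"),
    class = "align_params"
  )
}

#' @export
print.align_params <- function(x, ...) {
  cat(sprintf("<align_params> matrix=%s gap_open=%g gap_extend=%g\n",
              x$matrix_name, x$gap_open, x$gap_extend))
  invisible(x)
}
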