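#' Smith-Waterman local alignment of two protein sequences
#'
#' Exact optimal local alignment under affine gap penalties (Gotoh
#' dynamic programming), the alignment model of the classical `water`
#' program. Every homolog is aligned exactly; there is no heuristic
#' seeding. If the optimal score is 0 (nothing aligns above the noise
#' floor) an empty alignment is returned rather than an error.
#'
#' Ties are broken deterministically: among maximal cells the one with the
#' smallest (query, hit) coordinate in row-major order is used, and during
#' traceback a diagonal step is preferred over a gap in the hit, which is
#' preferred over a gap in the query.
#'
#' @param query,hit One-row sequence-record tibbles (see [seq_record()],
#'   [read_fasta()]).
#' @param params Alignment parameters, see [align_params()].
#' @return A `local_alignment` object: aligned strings, score, 1-based
#'   inclusive coordinates on both ungapped sequences, percent identity
#'   and similarity over all alignment columns, and the parameters used.
#' @examples
#' a <- smith_waterman(seq_record("q", "HEAGAWGHEE"),
#'                     seq_record("h", "PAWHEAE"))
#' tidy(a)
#' @export
smith_waterman <- function(query, hit, params = align_params()) {
  validate_seq_records(query)
  validate_seq_records(hit)
  q <- query$residues[1]
  h <- hit$residues[1]
  rn <- rownames(params$matrix)
  qc <- match(strsplit(q, "")[[1]], rn)
  hc <- match(strsplit(h, "")[[1]], rn)
  qc[is.na(qc)] <- 0L
  hc[is.na(hc)] <- 0L
  raw <- sw_align_cpp(q, h, qc - 1L, hc - 1L, params$matrix,
                      params$gap_open, params$gap_extend)
  new_local_alignment(query$id[1], hit$id[1], raw,
                      query_length = nchar(q), hit_length = nchar(h),
                      params = params)
}

new_local_alignment <- function(query_id, hit_id, raw, query_length,
                                hit_length, params) {
  pid <- compute_identity_similarity(
    list(aligned_query = raw$aligned_query, aligned_hit = raw$aligned_hit),
    params$matrix
  )
  aq <- strsplit(raw$aligned_query, "")[[1]]
  ah <- strsplit(raw$aligned_hit, "")[[1]]
  structure(
    list(query_id = query_id, hit_id = hit_id,
         aligned_query = raw$aligned_query, aligned_hit = raw$aligned_hit,
         score = raw$score,
         query_start = raw$query_start, query_end = raw$query_end,
         hit_start = raw$hit_start, hit_end = raw$hit_end,
         query_length = query_length, hit_length = hit_length,
         identity_pct = pid[["identity_pct"]],
         similarity_pct = pid[["similarity_pct"]],
         gap_columns = sum(aq == "-" | ah == "-"),
         gap_open = params$gap_open, gap_extend = params$gap_extend,
         matrix_name = params$matrix_name),
    class = "local_alignment"
  )
}

#' Percent identity and similarity of a local alignment
#'
#' Both percentages use the total number of alignment columns, gap columns
#' included, as the denominator (the convention of the classical `water`
#' report). Identity counts columns whose two letters are equal;
#' similarity counts columns whose residue pair scores strictly positively
#' under the matrix (gap columns and pairs without a matrix entry never
#' count). Under BLOSUM62 every canonical identity scores positively, so
#' identity never exceeds similarity with the default matrix.
#'
#' @param alignment A `local_alignment` (or any list with elements
#'   `aligned_query` and `aligned_hit`).
#' @param matrix Substitution matrix used for the similarity criterion.
#' @return Named numeric vector `c(identity_pct, similarity_pct)`, in
#'   `[0, 100]`, kept at full precision.
#' @export
compute_identity_similarity <- function(alignment, matrix = blosum62()) {
  aq <- strsplit(alignment$aligned_query, "")[[1]]
  ah <- strsplit(alignment$aligned_hit, "")[[1]]
  n <- length(aq)
  if (n == 0L) {
    return(c(identity_pct = 0, similarity_pct = 0))
  }
  if (n != length(ah)) abort("aligned strings differ in length")
  if (any(aq == "-" & ah == "-")) abort("all-gap alignment column")
  ident <- sum(aq == ah & aq != "-")
  res <- aq != "-" & ah != "-"
  simil <- sum(score_pair(matrix, aq[res], ah[res]) > 0)
  c(identity_pct = 100 * ident / n, similarity_pct = 100 * simil / n)
}

#' Map a query position into homolog coordinates
#'
#' Walks the alignment columns to find the column holding the given
#' ungapped query position and reports what the homolog carries there:
#' its residue letter (with its 1-based coordinate), a gap, or `outside`
#' when the local alignment does not cover the position.
#'
#' @param alignment A `local_alignment`.
#' @param query_pos Vector of 1-based positions on the ungapped query.
#' @return A tibble with one row per position: `query_pos`, `status`
#'   (one of `"residue"`, `"gap"`, `"outside"`), `residue` (letter or
#'   `NA`), `hit_pos` (1-based coordinate or `NA`).
#' @export
map_position <- function(alignment, query_pos) {
  query_pos <- as.integer(query_pos)
  if (any(is.na(query_pos)) || any(query_pos < 1L) ||
      any(query_pos > alignment$query_length)) {
    abort(sprintf("query position out of range 1..%d",
                  alignment$query_length))
  }
  aq <- strsplit(alignment$aligned_query, "")[[1]]
  ah <- strsplit(alignment$aligned_hit, "")[[1]]
  # running ungapped coordinates per column
  qpos <- cumsum(aq != "-") + alignment$query_start - 1L
  hpos <- cumsum(ah != "-") + alignment$hit_start - 1L
  purrr::map_dfr(query_pos, function(p) {
    if (length(aq) == 0L || p < alignment$query_start ||
        p > alignment$query_end) {
      return(tibble(query_pos = p, status = "outside",
                    residue = NA_character_, hit_pos = NA_integer_))
    }
    col <- which(aq != "-" & qpos == p)[1]
    if (ah[col] == "-") {
      tibble(query_pos = p, status = "gap",
             residue = NA_character_, hit_pos = NA_integer_)
    } else {
      tibble(query_pos = p, status = "residue",
             residue = ah[col], hit_pos = as.integer(hpos[col]))
    }
  })
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf(
    "<local_alignment> %s vs %s  score=%g  identity=%.1f%%  similarity=%.1f%%\n",
    x$query_id, x$hit_id, x$score, x$identity_pct, x$similarity_pct))
  if (nzchar(x$aligned_query)) {
    cat(sprintf("  query %d..%d, hit %d..%d, %d columns (%d gap)\n",
                x$query_start, x$query_end, x$hit_start, x$hit_end,
                nchar(x$aligned_query), x$gap_columns))
  } else {
    cat("  (empty alignment)\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Summarise a local alignment as a one-row tibble
#'
#' The columns mirror the one-line TSV alignment summary written by the
#' command-line tools.
#'
#' @param x A `local_alignment`.
#' @param ... Unused.
#' @export
tidy.local_alignment <- function(x, ...) {
  tibble(query_id = x$query_id, hit_id = x$hit_id, score = x$score,
         identity_pct = x$identity_pct, similarity_pct = x$similarity_pct,
         query_start = x$query_start, query_end = x$query_end,
         hit_start = x$hit_start, hit_end = x$hit_end,
         columns = nchar(x$aligned_query), gap_columns = x$gap_columns)
}

#' Write an alignment as aligned-pair FASTA
#'
#' Two records with gap characters, query first. This aligned form is an
#' export format only; [read_fasta()] deliberately rejects gapped input.
#'
#' @param alignment A `local_alignment`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(alignment, path) {
  hdr <- c(sprintf("%s %d-%d", alignment$query_id,
                   alignment$query_start, alignment$query_end),
           sprintf("%s %d-%d", alignment$hit_id,
                   alignment$hit_start, alignment$hit_end))
  xs <- Biostrings::BStringSet(stats::setNames(
    c(alignment$aligned_query, alignment$aligned_hit), hdr))
  Biostrings::writeXStringSet(xs, path, width = 60L)
  invisible(path)
}
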