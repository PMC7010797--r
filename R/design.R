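#' Specify the target positions of a replacement design
#'
#' The target specification names the residue type to eliminate (the
#' forbidden residue, classically cysteine) and groups the target
#' positions into clusters of structurally coupled sites. Positions in one
#' cluster must all be replaced from a single donor homolog, so that the
#' donated residues are known to coexist in an extant protein. A singleton
#' position is simply a cluster of size one.
#'
#' @param query One-row sequence-record tibble.
#' @param forbidden_residue Single canonical amino-acid letter.
#' @param clusters List of integer vectors of 1-based query positions
#'   (pairwise disjoint); or a cluster-spec string such as
#'   `"140,470,484;237,286;359;393"` (see [parse_cluster_spec()]).
#' @return A `target_spec` object.
#' @export
target_spec <- function(query, forbidden_residue, clusters) {
  validate_seq_records(query)
  forbidden_residue <- toupper(forbidden_residue)
  if (length(forbidden_residue) != 1L ||
      !forbidden_residue %in% CANONICAL_AA) {
    abort("`forbidden_residue` must be one canonical amino-acid letter")
  }
  if (is.character(clusters) && length(clusters) == 1L) {
    clusters <- parse_cluster_spec(clusters)
  }
  if (!is.list(clusters) || length(clusters) == 0L) {
    abort("`clusters` must be a non-empty list of position vectors")
  }
  clusters <- lapply(clusters, function(cl) sort(as.integer(cl)))
  if (any(lengths(clusters) == 0L)) abort("empty cluster")
  all_pos <- unlist(clusters)
  dup <- all_pos[duplicated(all_pos)]
  if (length(dup)) {
    abort(sprintf("position %d appears in more than one cluster", dup[1]))
  }
  L <- seq_length(query)
  if (any(all_pos < 1L | all_pos > L)) {
    abort(sprintf("positions must lie in 1..%d", L))
  }
  found <- vapply(all_pos, function(p) residue_at(query$residues[1], p), "")
  bad <- which(found != forbidden_residue)
  if (length(bad)) {
    abort(sprintf(
      "query carries '%s', not '%s', at target position %d",
      found[bad[1]], forbidden_residue, all_pos[bad[1]]
    ))
  }
  structure(list(query_id = query$id[1],
                 forbidden_residue = forbidden_residue,
                 clusters = clusters),
            class = "target_spec")
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf("<target_spec> eliminate '%s' at %s\n", x$forbidden_residue,
              format_cluster_spec(x$clusters)))
  invisible(x)
}

#' Rank database homologs by percent identity to the query
#'
#' Aligns every database record to the query with [smith_waterman()] and
#' sorts by percent identity, descending. The sort is stable: ties keep
#' database input order, so identical inputs always give identical ranks.
#' Records whose optimal local alignment is empty are ranked last with
#' identity 0.
#'
#' @param query One-row sequence-record tibble.
#' @param database Tibble of homolog records (e.g. pre-fetched BLAST hits
#'   read with [read_fasta()]).
#' @param params See [align_params()].
#' @return A tibble, one row per homolog in rank order: `rank`, `hit_id`,
#'   `score`, `identity_pct`, `similarity_pct`, coordinate columns, and a
#'   list-column `alignment` of `local_alignment` objects.
#' @export
rank_homologs <- function(query, database, params = align_params()) {
  validate_seq_records(query)
  if (!is.data.frame(database) || nrow(database) == 0L) {
    abort("homolog database is empty")
  }
  validate_seq_records(database)
  rows <- purrr::map(seq_len(nrow(database)), function(i) {
    aln <- smith_waterman(query, database[i, ], params)
    cbind(tidy(aln), tibble(alignment = list(aln), .input_order = i))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$identity_pct, out$.input_order), ]
  out$rank <- seq_len(nrow(out))
  out$.input_order <- NULL
  dplyr::relocate(as_tibble(out), "rank")
}

is_ranking <- function(ranked) {
  is.data.frame(ranked) &&
    all(c("rank", "hit_id", "identity_pct", "alignment") %in% names(ranked))
}

#' Find the closest homolog donating replacements for one cluster
#'
#' Scans homologs in rank order (closest first). A homolog qualifies for a
#' cluster if and only if, at every cluster position, the alignment maps
#' the query position onto a canonical homolog residue different from the
#' forbidden residue — a gap, an uncovered position, or an ambiguity
#' letter disqualifies it, since none of those can be written as a point
#' mutation. The first qualifying homolog becomes the donor.
#'
#' @param ranked Output of [rank_homologs()].
#' @param cluster Integer vector of coupled 1-based query positions.
#' @param forbidden_residue The residue letter being eliminated.
#' @return A tibble with one row per cluster position (`position`,
#'   `from_residue`, `to_residue`, `hit_coordinate`, `donor_id`,
#'   `donor_rank`, `donor_identity_pct`, `donor_similarity_pct`), or
#'   `NULL` when no homolog qualifies.
#' @export
find_cluster_replacement <- function(ranked, cluster, forbidden_residue) {
  if (!is_ranking(ranked)) abort("`ranked` must come from rank_homologs()")
  cluster <- sort(as.integer(cluster))
  for (i in seq_len(nrow(ranked))) {
    aln <- ranked$alignment[[i]]
    mapped <- map_position(aln, cluster)
    ok <- mapped$status == "residue" &
      mapped$residue %in% CANONICAL_AA &
      mapped$residue != forbidden_residue
    if (all(ok)) {
      return(tibble(
        position = mapped$query_pos,
        from_residue = forbidden_residue,
        to_residue = mapped$residue,
        hit_coordinate = mapped$hit_pos,
        donor_id = ranked$hit_id[i],
        donor_rank = ranked$rank[i],
        donor_identity_pct = ranked$identity_pct[i],
        donor_similarity_pct = ranked$similarity_pct[i]
      ))
    }
  }
  NULL
}

#' Apply point substitutions to a sequence
#'
#' @param query One-row sequence-record tibble.
#' @param substitutions Tibble with columns `position`, `from_residue`,
#'   `to_residue`; positions must be distinct and `from_residue` must
#'   match the query. An empty table returns the sequence unchanged.
#' @param id_suffix Suffix appended to the record id to mark the variant.
#' @return A one-row sequence-record tibble of the same length.
#' @examples
#' apply_substitutions(
#'   seq_record("q", "MKC"),
#'   tibble::tibble(position = 3L, from_residue = "C", to_residue = "S")
#' )
#' @export
apply_substitutions <- function(query, substitutions,
                                id_suffix = "_variant") {
  validate_seq_records(query)
  res <- query$residues[1]
  if (!is.null(substitutions) && nrow(substitutions) > 0L) {
    pos <- as.integer(substitutions$position)
    if (anyDuplicated(pos)) {
      abort(sprintf("duplicate substitution position %d",
                    pos[duplicated(pos)][1]))
    }
    for (k in seq_along(pos)) {
      found <- residue_at(res, pos[k])
      expected <- substitutions$from_residue[k]
      if (found != expected) {
        abort(sprintf(
          "substitution at position %d expects '%s' but query has '%s'",
          pos[k], expected, found
        ))
      }
      substr(res, pos[k], pos[k]) <- substitutions$to_residue[k]
    }
  }
  seq_record(paste0(query$id[1], id_suffix), res,
             description = trimws(paste(query$description[1],
                                        "engineered variant")))
}

#' Design a variant that eliminates a residue type
#'
#' The full evolution-guided replacement search: rank all homologs by
#' identity once, then, independently for each cluster of coupled
#' positions, take the substitutions from the closest homolog that
#' carries acceptable residues at every position of the cluster
#' simultaneously. One variant may therefore mix donors across clusters.
#' Clusters with no qualifying homolog (e.g. positions that are 100%
#' conserved across the database) are reported as unresolved and left
#' unchanged in the variant; the design is then flagged incomplete rather
#' than aborted.
#'
#' @param query One-row sequence-record tibble.
#' @param database Tibble of homolog records.
#' @param target A [target_spec()] (or a cluster-spec string, combined
#'   with `forbidden_residue`).
#' @param params See [align_params()].
#' @param overrides Optional named character vector of user-chosen
#'   replacements, e.g. `c("393" = "S")`: the named position is forced to
#'   that residue (validated canonical and different from the forbidden
#'   residue) and flagged as user-chosen in the report, whatever the donor
#'   search returned.
#' @param forbidden_residue Used only when `target` is a cluster string.
#' @param ranked Optionally, a precomputed [rank_homologs()] table to
#'   reuse.
#' @return A `variant_design` object; see [tidy.variant_design()] and
#'   [glance.variant_design()].
#' @export
design_variant <- function(query, database, target,
                           params = align_params(), overrides = NULL,
                           forbidden_residue = NULL, ranked = NULL) {
  if (!inherits(target, "target_spec")) {
    if (is.null(forbidden_residue)) {
      abort("`target` must be a target_spec (or supply forbidden_residue)")
    }
    target <- target_spec(query, forbidden_residue, target)
  }
  overrides <- validate_overrides(overrides, target)
  if (is.null(ranked)) {
    ranked <- rank_homologs(query, database, params)
  }

  per_cluster <- purrr::map(seq_along(target$clusters), function(ci) {
    cl <- target$clusters[[ci]]
    sug <- find_cluster_replacement(ranked, cl, target$forbidden_residue)
    if (is.null(sug)) {
      sug <- tibble(position = sort(as.integer(cl)),
                    from_residue = target$forbidden_residue,
                    to_residue = NA_character_,
                    hit_coordinate = NA_integer_,
                    donor_id = NA_character_, donor_rank = NA_integer_,
                    donor_identity_pct = NA_real_,
                    donor_similarity_pct = NA_real_)
    }
    sug$cluster <- ci
    sug
  })
  subs <- dplyr::bind_rows(per_cluster)
  subs$override <- FALSE
  if (length(overrides)) {
    idx <- match(as.integer(names(overrides)), subs$position)
    subs$to_residue[idx] <- unname(overrides)
    subs$override[idx] <- TRUE
  }
  subs$resolved <- !is.na(subs$to_residue)
  subs <- dplyr::relocate(subs, "cluster")

  unresolved <- sort(unique(subs$cluster[!subs$resolved]))
  variant <- apply_substitutions(
    query, subs[subs$resolved, , drop = FALSE]
  )
  structure(
    list(query = query, target = target, params = params,
         ranked = ranked, substitutions = subs,
         unresolved_clusters = unresolved, variant = variant,
         overrides = overrides,
         complete = length(unresolved) == 0L),
    class = "variant_design"
  )
}

validate_overrides <- function(overrides, target) {
  if (is.null(overrides) || length(overrides) == 0L) {
    return(character())
  }
  pos <- suppressWarnings(as.integer(names(overrides)))
  if (anyNA(pos)) abort("override names must be positions")
  all_pos <- unlist(target$clusters)
  bad <- setdiff(pos, all_pos)
  if (length(bad)) {
    abort(sprintf("override position %d is not a target position", bad[1]))
  }
  res <- toupper(unname(unlist(overrides)))
  if (any(!res %in% CANONICAL_AA)) {
    abort("override residues must be canonical amino-acid letters")
  }
  if (any(res == target$forbidden_residue)) {
    abort("an override cannot reintroduce the forbidden residue")
  }
  stats::setNames(res, pos)
}

#' @export
print.variant_design <- function(x, ...) {
  cat(sprintf("<variant_design> %s: eliminate '%s' at %d positions in %d clusters\n",
              x$query$id[1], x$target$forbidden_residue,
              nrow(x$substitutions), length(x$target$clusters)))
  done <- x$substitutions[x$substitutions$resolved, , drop = FALSE]
  if (nrow(done)) {
    cat("  substitutions:",
        paste0(done$from_residue, done$position, done$to_residue,
               ifelse(done$override, "*", ""), collapse = ", "), "\n")
  }
  if (length(x$unresolved_clusters)) {
    cat("  UNRESOLVED clusters:",
        paste(x$unresolved_clusters, collapse = ", "), "\n")
  } else {
    cat("  design complete\n")
  }
  invisible(x)
}

#' Substitution table of a variant design
#'
#' One row per target position with the donor homolog, its identity and
#' rank, the donated residue and whether the user overrode it — the same
#' rows the command-line report TSV contains.
#'
#' @param x A `variant_design`.
#' @param ... Unused.
#' @export
tidy.variant_design <- function(x, ...) {
  as_tibble(x$substitutions)
}

#' One-row summary of a variant design
#'
#' @param x A `variant_design`.
#' @param ... Unused.
#' @export
glance.variant_design <- function(x, ...) {
  tibble(query_id = x$query$id[1],
         forbidden_residue = x$target$forbidden_residue,
         n_positions = nrow(x$substitutions),
         n_clusters = length(x$target$clusters),
         n_resolved_clusters =
           length(x$target$clusters) - length(x$unresolved_clusters),
         n_substitutions = sum(x$substitutions$resolved),
         n_donors = dplyr::n_distinct(
           stats::na.omit(x$substitutions$donor_id)),
         db_size = nrow(x$ranked),
         complete = x$complete)
}

#' Per-position residue variation across ranked homologs
#'
#' For the top `top_n` homologs (closest first), reports the residue each
#' one carries at every requested query position — the evidence base from
#' which replacements are chosen, and the way to see which residues
#' natural variation offers at a site.
#'
#' @param ranked Output of [rank_homologs()].
#' @param positions Integer vector of 1-based query positions.
#' @param top_n Number of top-ranked homologs to include (default: all).
#' @return A `variation_profile` tibble: `position`, `rank`, `source_id`,
#'   `identity_pct`, `status`, `residue`, `hit_pos`, in rank order within
#'   each position.
#' @seealso [profile_tally()] for the per-position residue frequencies.
#' @export
variation_profile <- function(ranked, positions, top_n = nrow(ranked)) {
  if (!is_ranking(ranked)) abort("`ranked` must come from rank_homologs()")
  if (!is.numeric(top_n) || top_n < 1L) abort("`top_n` must be >= 1")
  top_n <- min(as.integer(top_n), nrow(ranked))
  positions <- sort(unique(as.integer(positions)))
  rows <- purrr::map(seq_len(top_n), function(i) {
    mapped <- map_position(ranked$alignment[[i]], positions)
    tibble(position = mapped$query_pos, rank = ranked$rank[i],
           source_id = ranked$hit_id[i],
           identity_pct = ranked$identity_pct[i],
           status = mapped$status, residue = mapped$residue,
           hit_pos = mapped$hit_pos)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$position, .data$rank)
  class(out) <- c("variation_profile", class(out))
  out
}

#' Per-position residue frequency tally of a variation profile
#'
#' @param profile Output of [variation_profile()].
#' @return A tibble `position`, `residue`, `n` (descending `n` within each
#'   position). Gapped and uncovered positions are tallied under the
#'   pseudo-residues `"-"` and `"."`.
#' @export
profile_tally <- function(profile) {
  profile %>%
    dplyr::mutate(residue = dplyr::case_when(
      .data$status == "gap" ~ "-",
      .data$status == "outside" ~ ".",
      TRUE ~ .data$residue
    )) %>%
    dplyr::count(.data$position, .data$residue, name = "n") %>%
    dplyr::arrange(.data$position, dplyr::desc(.data$n), .data$residue)
}
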