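# Seeded RNG scoping: one integer seed drives one named pseudo-random
# stream without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate one synthetic homolog of a query sequence
#'
#' Emulates an ortholog at a controlled evolutionary distance: starting
#' from the query, randomly chosen positions are substituted until the
#' fraction of unchanged positions equals `target_identity` (rounded to
#' the nearest achievable count). Replacement residues are drawn from the
#' 19 alternatives with probability proportional to `exp(BLOSUM62 score)`
#' against the original residue, so synthetic families show the
#' similarity > identity pattern of real ortholog alignments. `planted`
#' residues are then written at their positions verbatim (they count as
#' substitutions when they differ from the query — and may equal the
#' query residue to pin a position). Optionally, short indels
#' (length 1-3) are applied at `indel_rate` per position, never touching
#' planted positions. Deterministic given `seed`.
#'
#' @param query One-row sequence-record tibble.
#' @param id Identifier of the generated record.
#' @param target_identity Fraction of positions left unchanged, in (0, 1].
#' @param planted Named character vector of residues keyed by 1-based
#'   query position, e.g. `c("140" = "M")`, or `NULL`.
#' @param indel_rate Per-position probability of starting an indel
#'   (default 0, which keeps position bookkeeping trivial).
#' @param seed Integer seed; embedded in the output description for
#'   provenance.
#' @return A one-row sequence-record tibble with attribute `truth`: a
#'   list with the realized substitution count, the query-to-homolog
#'   coordinate map, and the planted map in homolog coordinates.
#' @export
generate_homolog <- function(query, id, target_identity, planted = NULL,
                             indel_rate = 0, seed = 1L) {
  validate_seq_records(query)
  if (!is.numeric(target_identity) || target_identity <= 0 ||
      target_identity > 1) {
    abort("`target_identity` must be in (0, 1]")
  }
  if (indel_rate < 0 || indel_rate >= 1) abort("`indel_rate` must be in [0, 1)")
  chars <- strsplit(query$residues[1], "")[[1]]
  L <- length(chars)
  planted_pos <- integer()
  planted_res <- character()
  if (!is.null(planted) && length(planted)) {
    planted_pos <- as.integer(names(planted))
    planted_res <- toupper(unname(unlist(planted)))
    if (anyNA(planted_pos) || any(planted_pos < 1L | planted_pos > L)) {
      abort("planted positions must be 1-based positions on the query")
    }
    if (any(!planted_res %in% CANONICAL_AA)) {
      abort("planted residues must be canonical amino-acid letters")
    }
    if (anyDuplicated(planted_pos)) abort("duplicate planted position")
  }

  n_mut <- round((1 - target_identity) * L)
  planted_diff <- sum(planted_res != chars[planted_pos])
  n_extra <- n_mut - planted_diff
  if (n_extra < 0) {
    abort(sprintf(
      "target_identity %.3f allows %d substitutions but %d are planted",
      target_identity, n_mut, planted_diff
    ))
  }

  S <- blosum62()
  out <- with_local_seed(seed, {
    free <- setdiff(seq_len(L), planted_pos)
    mut_pos <- sort(sample(free, n_extra))
    new_chars <- chars
    for (p in mut_pos) {
      orig <- chars[p]
      alts <- setdiff(CANONICAL_AA, orig)
      w <- exp(score_pair(S, rep(orig, length(alts)), alts))
      new_chars[p] <- sample(alts, 1L, prob = w)
    }
    new_chars[planted_pos] <- planted_res

    # coordinate map: query position -> homolog position (NA if deleted)
    coord_map <- seq_len(L)
    if (indel_rate > 0) {
      hom <- as.list(new_chars)   # hom[[i]]: residues emitted for query pos i
      lead <- character()         # insertion before position 1
      p <- 1L
      while (p <= L) {
        if (stats::runif(1) < indel_rate) {
          len <- sample(1:3, 1L)
          if (stats::runif(1) < 0.5) {
            span <- p:min(L, p + len - 1L)
            span <- span[!span %in% planted_pos]
            for (d in span) hom[[d]] <- character()
          } else {
            ins <- sample(CANONICAL_AA, len, replace = TRUE)
            hom[[p]] <- c(hom[[p]], ins)
          }
          p <- p + len
        } else {
          p <- p + 1L
        }
      }
      emitted <- lengths(hom)
      first_of <- cumsum(c(length(lead), emitted[-L])) + 1L
      coord_map <- ifelse(emitted == 0L, NA_integer_, first_of)
      new_chars <- c(lead, unlist(hom))
    }
    list(res = paste(new_chars, collapse = ""), coord_map = coord_map)
  })

  rec <- seq_record(
    id, out$res,
    description = sprintf("synthetic homolog seed=%d target_identity=%.3f",
                          as.integer(seed), target_identity)
  )
  attr(rec, "truth") <- list(
    target_identity = target_identity,
    n_substituted = n_mut,
    realized_identity = 1 - n_mut / L,
    coord_map = out$coord_map,
    planted = if (length(planted_pos)) {
      tibble(position = planted_pos, residue = planted_res,
             homolog_pos = out$coord_map[planted_pos])
    } else {
      tibble(position = integer(), residue = character(),
             homolog_pos = integer())
    }
  )
  rec
}

#' Generate a synthetic ortholog family
#'
#' One homolog per plan, in plan order, each generated with
#' [generate_homolog()] under a per-plan seed derived from `seed`.
#' Alongside the records, a ground-truth manifest (true identities,
#' planted maps) is returned for test assertions.
#'
#' @param query One-row sequence-record tibble.
#' @param plans Tibble with columns `id`, `target_identity`, and
#'   optionally `planted` (list-column of named character vectors) and
#'   `indel_rate`.
#' @param seed Integer master seed.
#' @return A list of class `synthetic_family`: `records` (tibble of all
#'   homologs, plan order), `manifest` (per-homolog ground truth), and
#'   `planted` (long tibble of planted residues with homolog
#'   coordinates).
#' @export
generate_database <- function(query, plans, seed = 1L) {
  if (!is.data.frame(plans) || nrow(plans) == 0L) {
    abort("`plans` must be a non-empty tibble of homolog plans")
  }
  if (!all(c("id", "target_identity") %in% names(plans))) {
    abort("plans need columns `id` and `target_identity`")
  }
  if (anyDuplicated(plans$id)) abort("plan ids must be unique")
  if (!"planted" %in% names(plans)) plans$planted <- list(NULL)
  if (!"indel_rate" %in% names(plans)) plans$indel_rate <- 0
  seed <- as.integer(seed)

  recs <- vector("list", nrow(plans))
  truths <- vector("list", nrow(plans))
  for (i in seq_len(nrow(plans))) {
    rec <- generate_homolog(query, plans$id[i], plans$target_identity[i],
                            planted = plans$planted[[i]],
                            indel_rate = plans$indel_rate[i],
                            seed = (seed + i - 1L) %% .Machine$integer.max)
    truths[[i]] <- attr(rec, "truth")
    attr(rec, "truth") <- NULL
    recs[[i]] <- rec
  }
  manifest <- tibble(
    id = plans$id,
    target_identity = plans$target_identity,
    realized_identity = vapply(truths, `[[`, 0, "realized_identity"),
    n_substituted = vapply(truths, `[[`, 0, "n_substituted"),
    indel_rate = plans$indel_rate,
    n_planted = vapply(truths, function(t) nrow(t$planted), 0L),
    seed = seed
  )
  planted <- dplyr::bind_rows(
    purrr::map2(plans$id, truths,
                function(id, t) dplyr::mutate(t$planted, id = id))
  )
  structure(list(records = dplyr::bind_rows(recs), manifest = manifest,
                 planted = dplyr::relocate(planted, "id"), seed = seed),
            class = "synthetic_family")
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat(sprintf("<synthetic_family> %d homologs (seed %d)\n",
              nrow(x$records), x$seed))
  print(x$manifest)
  invisible(x)
}

#' Write a synthetic family to disk
#'
#' Emits `database.fasta`, the ground-truth `manifest.tsv` and a
#' `params.txt` key-value file into `dir` (the `gen-fixtures` command's
#' output layout).
#'
#' @param family A `synthetic_family` from [generate_database()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixture_set <- function(family, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(database = file.path(dir, "database.fasta"),
             manifest = file.path(dir, "manifest.tsv"),
             params = file.path(dir, "params.txt"))
  write_fasta(family$records, files[["database"]])
  readr::write_tsv(family$manifest, files[["manifest"]])
  writeLines(c(sprintf("tool_version\t%s", orthosub_version()),
               sprintf("seed\t%d", family$seed),
               sprintf("n_records\t%d", nrow(family$records))),
             files[["params"]])
  invisible(files)
}

#' The packaged synthetic chaperonin-like query
#'
#' A synthetic 543-residue stand-in for an archaeal group II chaperonin
#' subunit, carrying cysteine at exactly seven positions — 140, 237, 286,
#' 359, 393, 470 and 484 — which mirror the cluster geometry of the
#' documented design problem: three coupled equatorial sites (140, 470,
#' 484), two coupled apical sites (237, 286) and two singleton
#' intermediate-domain sites (359, 393). It is generated data, not a
#' natural sequence, and ships with the package so the whole pipeline
#' runs offline.
#'
#' @return A one-row sequence-record tibble.
#' @export
chaperonin_example_query <- function() {
  read_fasta(system.file("extdata", "synthetic_chaperonin_query.fasta",
                         package = "orthosub", mustWork = TRUE))
}

#' The packaged synthetic chaperonin ortholog family
#'
#' Builds the study conditions of the documented cysteine-less design as
#' a synthetic family around [chaperonin_example_query()]: a close decoy
#' relative (92% identity) that still carries cysteine at all but one
#' equatorial position, an equatorial donor at 85.8% identity planting
#' M140/Y470/T484, an apical donor at 66.3% planting E237/V286, an
#' intermediate-domain donor at 59.2% planting V359, and a distant
#' relative at 45% with non-cysteine residues everywhere. The decoy also
#' plants S393, so the closest source of a serine at 393 is a close
#' relative — and its M140 alone cannot resolve the coupled equatorial
#' cluster, forcing the 85.8% donor.
#'
#' @param seed Integer seed for the generator.
#' @return A `synthetic_family`; see [generate_database()].
#' @export
chaperonin_example_family <- function(seed = 20200210L) {
  query <- chaperonin_example_query()
  keepC <- function(at) stats::setNames(rep("C", length(at)), at)
  plans <- tibble(
    id = c("decoy_close", "equatorial_donor", "apical_donor",
           "intermediate_donor", "distant_relative"),
    target_identity = c(0.92, 0.858, 0.663, 0.592, 0.45),
    planted = list(
      c("140" = "M", "393" = "S", keepC(c(470, 484, 237, 286, 359))),
      c("140" = "M", "470" = "Y", "484" = "T",
        keepC(c(237, 286, 359, 393))),
      c("237" = "E", "286" = "V", keepC(c(140, 470, 484, 359, 393))),
      c("359" = "V", keepC(c(140, 470, 484, 237, 286, 393))),
      c("140" = "A", "470" = "S", "484" = "S", "237" = "D", "286" = "I",
        "359" = "T", "393" = "A")
    )
  )
  generate_database(query, plans, seed = seed)
}

#' The cluster grouping of the packaged chaperonin example
#'
#' @return A list of integer vectors:
#'   `{140, 470, 484}, {237, 286}, {359}, {393}`.
#' @export
chaperonin_example_clusters <- function() {
  parse_cluster_spec("140,470,484;237,286;359;393")
}
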