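#' Load heavy-atom coordinates for selected residues of one chain
#'
#' Reads a PDB or mmCIF structure and returns the heavy-atom (non-hydrogen)
#' coordinates of the requested residues on one chain, in the author
#' residue numbering of that chain. Hydrogens are excluded; for altloc
#' duplicates a single atom is retained (highest occupancy, then altloc
#' 'A'). Requested residues absent from the model are reported with a
#' warning and carried in the `"missing"` attribute — never fabricated.
#'
#' @param path Path to a PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`)
#'   file; the format is chosen by extension.
#' @param chain_id Chain identifier.
#' @param positions Integer vector of residue numbers to extract; `NULL`
#'   extracts every residue of the chain.
#' @return A `residue_coordinates` tibble: `position`, `resid`, `elety`,
#'   `x`, `y`, `z` (Angstrom), with attribute `missing`.
#' @export
load_residue_coordinates <- function(path, chain_id, positions = NULL) {
  ext <- tolower(tools::file_ext(path))
  pdb <- suppressWarnings(if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  })
  atoms <- pdb$atom
  if (!chain_id %in% unique(atoms$chain)) {
    abort(sprintf("chain '%s' not found (chains present: %s)", chain_id,
                  paste(sort(unique(atoms$chain)), collapse = ", ")))
  }
  atoms <- atoms[atoms$chain == chain_id & atoms$type == "ATOM", ,
                 drop = FALSE]
  # heavy atoms only
  elesy <- toupper(trimws(if ("elesy" %in% names(atoms)) atoms$elesy else ""))
  is_h <- ifelse(!is.na(elesy) & nzchar(elesy),
                 elesy %in% c("H", "D"),
                 grepl("^[0-9]*[HD]", toupper(trimws(atoms$elety))))
  atoms <- atoms[!is_h, , drop = FALSE]
  # altloc: keep one atom per (residue, atom name)
  o <- atoms$o
  o[is.na(o)] <- 1
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  ord <- order(atoms$resno, atoms$elety, -o, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(atoms[, c("resno", "elety")]), , drop = FALSE]

  if (is.null(positions)) {
    positions <- sort(unique(atoms$resno))
  }
  positions <- sort(unique(as.integer(positions)))
  missing <- setdiff(positions, atoms$resno)
  if (length(missing) == length(positions)) {
    abort(sprintf("none of the requested residues are present in chain '%s'",
                  chain_id))
  }
  if (length(missing)) {
    warn(sprintf("residues absent from chain '%s': %s", chain_id,
                 paste(missing, collapse = ", ")))
  }
  atoms <- atoms[atoms$resno %in% positions, , drop = FALSE]
  out <- tibble(position = as.integer(atoms$resno), resid = atoms$resid,
                elety = trimws(atoms$elety),
                x = atoms$x, y = atoms$y, z = atoms$z)
  if (any(!is.finite(c(out$x, out$y, out$z)))) {
    abort("non-finite coordinates in structure file")
  }
  out <- dplyr::arrange(out, .data$position)
  attr(out, "missing") <- missing
  class(out) <- c("residue_coordinates", class(out))
  out
}

#' Synthetic residue coordinates from bare points
#'
#' Convenience constructor for building `residue_coordinates` directly
#' from atom positions (used for simulated geometries and tests).
#'
#' @param position Integer vector, one entry per atom.
#' @param xyz Numeric matrix with one row per atom and columns x, y, z.
#' @export
residue_coordinates <- function(position, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (length(position) != nrow(xyz)) abort("one position per atom row")
  if (any(!is.finite(xyz))) abort("coordinates must be finite")
  out <- tibble(position = as.integer(position), resid = "UNK",
                elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(out, "missing") <- integer()
  class(out) <- c("residue_coordinates", class(out))
  out
}

#' Group positions into steric-contact clusters
#'
#' Two residues are in contact when the minimum distance over all their
#' heavy-atom pairs is below `cutoff` Angstrom; clusters are the
#' connected components of the contact graph (single linkage), so a chain
#' of pairwise contacts is one cluster. Positions replaced together must
#' come from one donor sequence, which is why contacting residues are
#' coupled.
#'
#' @param coords A `residue_coordinates` tibble
#'   (see [load_residue_coordinates()]).
#' @param positions Positions to cluster; every one must be present in
#'   `coords`.
#' @param cutoff Contact distance cutoff in Angstrom. The default, 4.5,
#'   is a conventional heavy-atom contact threshold; it is a free
#'   parameter recorded in reports, not a value with independent
#'   authority.
#' @return List of integer vectors (sorted within, ordered by smallest
#'   member); every input position appears in exactly one.
#' @export
contact_clusters <- function(coords, positions, cutoff = 4.5) {
  if (!is.numeric(cutoff) || cutoff <= 0) abort("`cutoff` must be > 0")
  positions <- sort(unique(as.integer(positions)))
  absent <- setdiff(positions, coords$position)
  if (length(absent)) {
    abort(sprintf("no coordinates for position %d", absent[1]))
  }
  pts <- lapply(positions, function(p) {
    as.matrix(coords[coords$position == p, c("x", "y", "z")])
  })
  n <- length(positions)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      adj[i, j] <- adj[j, i] <-
        min_pair_distance(pts[[i]], pts[[j]]) < cutoff
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- lapply(split(positions, comp), function(v) sort(v))
  clusters <- unname(clusters[order(vapply(clusters, min, 1L))])
  clusters
}

min_pair_distance <- function(a, b) {
  # all-pairs Euclidean distances between two heavy-atom sets
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Format clusters as a cluster-spec string
#'
#' Inverse of [parse_cluster_spec()]; the output feeds the `design`
#' command line directly, so structure-derived clusters compose with the
#' sequence search.
#'
#' @param clusters List of integer vectors.
#' @return A string such as `"140,470,484;237,286;359;393"`.
#' @export
format_cluster_spec <- function(clusters) {
  paste(vapply(clusters, function(cl) paste(sort(cl), collapse = ","), ""),
        collapse = ";")
}
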