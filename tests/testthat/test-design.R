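# Brute-force qualification scan used to verify donor minimality: test a
# homolog for a cluster directly from its alignment, independent of
# find_cluster_replacement's scan order.
qualifies <- function(ranked_row_alignment, cluster, forbidden) {
  m <- map_position(ranked_row_alignment, cluster)
  all(m$status == "residue" & m$residue %in% CANONICAL_ALPHABET &
        m$residue != forbidden)
}

best_qualifying_rank <- function(ranked, cluster, forbidden) {
  ok <- vapply(ranked$alignment, qualifies, TRUE,
               cluster = cluster, forbidden = forbidden)
  if (!any(ok)) NA_integer_ else min(ranked$rank[ok])
}

test_that("homologs are ranked by identity with stable ties", {
  q <- toy_query()
  fam <- generate_database(q, tibble::tibble(
    id = c("far", "near", "mid"),
    target_identity = c(0.5, 0.9, 0.7)
  ), seed = 5)
  db <- dplyr::bind_rows(fam$records, q)
  ranked <- rank_homologs(q, db)
  expect_equal(ranked$hit_id, c("toy_query", "near", "mid", "far"))
  expect_equal(ranked$rank, 1:4)
  expect_equal(ranked$identity_pct[1], 100)
  expect_true(all(diff(ranked$identity_pct) <= 0))

  # exact duplicates tie; input order is the tie-break
  dup <- dplyr::bind_rows(
    rec("twin_b_first", fam$records$residues[2]),
    rec("twin_a_second", fam$records$residues[2])
  )
  r2 <- rank_homologs(q, dup)
  expect_equal(r2$hit_id, c("twin_b_first", "twin_a_second"))

  expect_error(rank_homologs(q, fam$records[0, ]), "empty")
})

test_that("cluster replacement comes from the closest qualifying homolog", {
  q <- toy_query()
  cl <- c(10L, 25L)
  # rank 1 keeps C at 25 (disqualified), rank 2 is the planted donor
  fam <- generate_database(q, tibble::tibble(
    id = c("close_partial", "donor", "far_full"),
    target_identity = c(0.95, 0.85, 0.6),
    planted = list(c("10" = "S", "25" = "C", "40" = "C", "55" = "C"),
                   c("10" = "M", "25" = "V", "40" = "C", "55" = "C"),
                   c("10" = "A", "25" = "T", "40" = "S", "55" = "S"))
  ), seed = 9)
  ranked <- rank_homologs(q, fam$records)
  expect_equal(ranked$hit_id[1], "close_partial")

  sug <- find_cluster_replacement(ranked, cl, "C")
  expect_equal(unique(sug$donor_id), "donor")
  expect_equal(sug$position, cl)
  expect_equal(sug$from_residue, c("C", "C"))
  expect_equal(sug$to_residue, c("M", "V"))
  expect_equal(sug$donor_rank[1], best_qualifying_rank(ranked, cl, "C"))

  # suggested residues are exactly what map_position reports on the donor
  donor_aln <- ranked$alignment[[which(ranked$hit_id == "donor")]]
  m <- map_position(donor_aln, cl)
  expect_equal(sug$to_residue, m$residue)
  expect_equal(sug$hit_coordinate, m$hit_pos)

  # no qualifying homolog -> NULL, not an error
  none <- find_cluster_replacement(ranked, 55L, "C")
  expect_equal(none$donor_id[1], "far_full")
  all_c <- rank_homologs(q, dplyr::bind_rows(q, q %>% dplyr::mutate(id = "q2")))
  expect_null(find_cluster_replacement(all_c, cl, "C"))
})

test_that("gaps, uncovered positions and ambiguity letters disqualify donors", {
  q <- rec("q", "MKCLAVEHGW")
  # hit aligns but has X at the mapped position 3
  hx <- rec("hx", "MKXLAVEHGW")
  ranked <- rank_homologs(q, hx)
  expect_null(find_cluster_replacement(ranked, 3L, "C"))
  # hit with the position deleted (gap at query pos 3)
  hgap <- rec("hgap", "MKLAVEHGW")
  rg <- rank_homologs(q, hgap)
  m <- map_position(rg$alignment[[1]], 3L)
  expect_true(m$status %in% c("gap", "outside"))
  expect_null(find_cluster_replacement(rg, 3L, "C"))
})

test_that("substitutions are applied exactly and validated", {
  q <- rec("q", "MKC")
  out <- apply_substitutions(
    q, tibble::tibble(position = 3L, from_residue = "C", to_residue = "S"))
  expect_equal(out$residues, "MKS")
  expect_true(startsWith(out$id, "q"))
  expect_false(identical(out$id, "q"))

  expect_equal(apply_substitutions(q, NULL)$residues, "MKC")
  expect_error(
    apply_substitutions(
      q, tibble::tibble(position = 2L, from_residue = "C",
                        to_residue = "S")),
    "position 2 expects 'C' but query has 'K'")
  expect_error(
    apply_substitutions(
      q, tibble::tibble(position = c(3L, 3L), from_residue = "C",
                        to_residue = c("S", "A"))),
    "duplicate")
})

test_that("target_spec enforces its invariants", {
  q <- toy_query()
  expect_error(target_spec(q, "C", list(c(10, 11))),
               "carries 'R', not 'C', at target position 11")
  expect_error(target_spec(q, "C", list(c(10), c(10, 25))),
               "more than one cluster")
  expect_error(target_spec(q, "C", list(c(10, 999))), "1..60")
  expect_error(target_spec(q, "CC", list(10)), "one canonical")
  expect_error(target_spec(q, "C", list()), "non-empty")
  ts <- target_spec(q, "C", "10,25;40;55")
  expect_equal(ts$clusters, TOY_CLUSTERS)
})

test_that("design_variant resolves clusters independently and builds the variant", {
  q <- toy_query()
  fam <- generate_database(q, tibble::tibble(
    id = c("close_partial", "donor_a", "donor_b"),
    target_identity = c(0.95, 0.85, 0.65),
    planted = list(c("10" = "S", "25" = "C", "40" = "V", "55" = "C"),
                   c("10" = "M", "25" = "V", "40" = "C", "55" = "C"),
                   c("10" = "A", "25" = "T", "40" = "S", "55" = "Y"))
  ), seed = 13)
  d <- design_variant(q, fam$records, target_spec(q, "C", TOY_CLUSTERS))

  expect_true(d$complete)
  tab <- tidy(d)
  expect_equal(nrow(tab), 4L)
  # one donor per cluster; clusters may mix donors across the design
  expect_equal(tab$donor_id[tab$position %in% c(10, 25)],
               c("donor_a", "donor_a"))
  expect_equal(tab$donor_id[tab$position == 40], "close_partial")
  expect_equal(tab$donor_id[tab$position == 55], "donor_b")

  # variant contract: same length, differs exactly at substituted positions
  v <- d$variant$residues
  expect_equal(nchar(v), 60L)
  qc <- strsplit(q$residues, "")[[1]]
  vc <- strsplit(v, "")[[1]]
  expect_equal(which(qc != vc), sort(tab$position))
  expect_true(all(vc[tab$position] != "C"))

  g <- glance(d)
  expect_equal(g$n_substitutions, 4L)
  expect_equal(g$n_resolved_clusters, 3L)
  expect_true(g$complete)
})

test_that("unresolved clusters are reported, left unchanged, and flagged", {
  q <- toy_query()
  fam <- generate_database(q, tibble::tibble(
    id = "only",
    target_identity = 0.9,
    planted = list(c("10" = "M", "25" = "V", "40" = "C", "55" = "C"))
  ), seed = 3)
  d <- design_variant(q, fam$records, target_spec(q, "C", TOY_CLUSTERS))
  expect_false(d$complete)
  expect_equal(d$unresolved_clusters, c(2L, 3L))
  tab <- tidy(d)
  expect_true(all(is.na(tab$to_residue[tab$position %in% c(40, 55)])))
  vc <- strsplit(d$variant$residues, "")[[1]]
  expect_equal(vc[c(40, 55)], c("C", "C"))  # untouched
  expect_equal(vc[c(10, 25)], c("M", "V"))
})

test_that("overrides force user-chosen residues and are validated", {
  q <- toy_query()
  fam <- generate_database(q, tibble::tibble(
    id = "donor",
    target_identity = 0.9,
    planted = list(c("10" = "M", "25" = "V", "40" = "T", "55" = "V"))
  ), seed = 21)
  ts <- target_spec(q, "C", TOY_CLUSTERS)
  d <- design_variant(q, fam$records, ts, overrides = c("55" = "S"))
  tab <- tidy(d)
  expect_equal(tab$to_residue[tab$position == 55], "S")
  expect_true(tab$override[tab$position == 55])
  expect_false(any(tab$override[tab$position != 55]))
  expect_equal(substr(d$variant$residues, 55, 55), "S")

  # an override can complete a cluster no homolog resolves
  fam2 <- generate_database(q, tibble::tibble(
    id = "keeper", target_identity = 0.9,
    planted = list(c("10" = "M", "25" = "V", "40" = "T", "55" = "C"))
  ), seed = 22)
  d2 <- design_variant(q, fam2$records, ts, overrides = c("55" = "A"))
  expect_true(d2$complete)

  expect_error(design_variant(q, fam$records, ts, overrides = c("55" = "C")),
               "reintroduce")
  expect_error(design_variant(q, fam$records, ts, overrides = c("55" = "J")),
               "canonical")
  expect_error(design_variant(q, fam$records, ts, overrides = c("12" = "S")),
               "not a target position")
})

test_that("coupling matters: a partial match at the top forces a lower donor", {
  q <- toy_query()
  cl <- c(10L, 25L)
  fam <- generate_database(q, tibble::tibble(
    id = c("close_partial", "coupled_donor"),
    target_identity = c(0.95, 0.8),
    planted = list(c("10" = "S", "25" = "C", "40" = "C", "55" = "C"),
                   c("10" = "M", "25" = "V", "40" = "C", "55" = "C"))
  ), seed = 31)
  ranked <- rank_homologs(q, fam$records)
  # singleton runs would pick the closest homolog for position 10
  single <- find_cluster_replacement(ranked, 10L, "C")
  expect_equal(single$donor_id, "close_partial")
  # the coupled cluster must fall through to the lower-identity donor
  coupled <- find_cluster_replacement(ranked, cl, "C")
  expect_equal(unique(coupled$donor_id), "coupled_donor")
  expect_lt(coupled$donor_identity_pct[1], single$donor_identity_pct[1])
})

test_that("identical inputs give identical designs (determinism)", {
  q <- toy_query()
  fam <- generate_database(q, tibble::tibble(
    id = c("a", "b"),
    target_identity = c(0.9, 0.7),
    planted = list(c("10" = "M", "25" = "V", "40" = "T", "55" = "V"),
                   c("10" = "A", "25" = "T", "40" = "S", "55" = "Y"))
  ), seed = 77)
  ts <- target_spec(q, "C", TOY_CLUSTERS)
  d1 <- design_variant(q, fam$records, ts)
  d2 <- design_variant(q, fam$records, ts)
  expect_identical(tidy(d1), tidy(d2))
  expect_identical(d1$variant, d2$variant)
})

test_that("variation profiles report ranked residues and tallies", {
  q <- toy_query()
  ranked_self <- rank_homologs(q, q)
  prof <- variation_profile(ranked_self, c(10L, 40L))
  expect_equal(prof$residue, c("C", "C"))  # only the query's own residue
  expect_equal(prof$rank, c(1L, 1L))

  # plant 'S' at position 40 in half the homologs
  plans <- tibble::tibble(
    id = sprintf("h%d", 1:6),
    target_identity = seq(0.95, 0.7, length.out = 6),
    planted = rep(list(c("40" = "S"), c("40" = "C")), 3)
  )
  fam <- generate_database(q, plans, seed = 8)
  ranked <- rank_homologs(q, fam$records)
  prof <- variation_profile(ranked, 40L)
  tal <- profile_tally(prof)
  expect_equal(tal$n[tal$residue == "S"], 3L)
  expect_equal(sum(tal$n), 6L)
  # rows follow homolog rank within each position
  expect_equal(prof$rank, sort(prof$rank))

  expect_error(variation_profile(ranked, 40L, top_n = 0), "top_n")
  p2 <- variation_profile(ranked, 40L, top_n = 2)
  expect_equal(nrow(p2), 2L)

  # a fully conserved position offers no alternatives and the design
  # flags it unresolvable
  prof55 <- variation_profile(rank_homologs(q, fam$records), 55L)
  expect_true(all(prof55$residue == "C"))
  d <- design_variant(q, fam$records, target_spec(q, "C", list(55L)))
  expect_false(d$complete)
})

test_that("donor minimality holds against a brute-force scan", {
  set.seed(55)
  q <- toy_query()
  for (trial in 1:3) {
    n <- 8
    plans <- tibble::tibble(
      id = sprintf("t%d_h%d", trial, 1:n),
      target_identity = stats::runif(n, 0.55, 0.97),
      planted = lapply(1:n, function(i) {
        res <- sample(c("C", "M", "V", "S", "T"), 4, replace = TRUE)
        stats::setNames(res, c(10, 25, 40, 55))
      })
    )
    fam <- generate_database(q, plans, seed = 100 + trial)
    ranked <- rank_homologs(q, fam$records)
    for (cl in TOY_CLUSTERS) {
      sug <- find_cluster_replacement(ranked, cl, "C")
      want <- best_qualifying_rank(ranked, cl, "C")
      if (is.na(want)) {
        expect_null(sug)
      } else {
        expect_equal(sug$donor_rank[1], want)
      }
    }
  }
})
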