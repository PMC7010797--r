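---
title: "Evolution-guided residue replacement: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution-guided residue replacement: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(orthosub)
library(dplyr)
```

## The method

`orthosub` designs protein variants that remove every occurrence of a chosen
residue type (the *forbidden residue*, classically cysteine) at specified
positions, by copying replacements from the closest orthologs that already
lack it. The premise is that a substitution observed in a closely related,
presumably functional protein has been vetted by selection, which a naive
Cys→Ser/Ala scheme has not. The package assumes the homolog database is a
reasonable sample of the family (it performs no retrieval itself) and that
alignment homology identifies structurally equivalent positions.

The pipeline has three computational stages.

**1. Exact pairwise local alignment.** Each homolog is aligned to the query
with Smith–Waterman under affine gaps via the Gotoh recurrences

$$H_{ij} = \max(0,\; H_{i-1,j-1} + s(q_i, h_j),\; E_{ij},\; F_{ij})$$
$$E_{ij} = \max(H_{i,j-1} - g_{open},\; E_{i,j-1} - g_{ext}), \qquad
  F_{ij} = \max(H_{i-1,j} - g_{open},\; F_{i-1,j} - g_{ext})$$

so a gap of length $L$ costs $g_{open} + (L-1)\,g_{ext}$. There is no
heuristic seeding: with a few thousand homologs and queries of a few hundred
residues, exact quadratic DP per pair is cheap (the DP is compiled C++), and
optimality matters because the donor search inspects individual aligned
columns. Percent identity and similarity both use the *total number of
alignment columns, gap columns included*, as denominator — the convention of
the classical `water` report, which users of that tool will expect their
numbers to match. Similarity counts columns whose residue pair scores
strictly positively under the matrix; under BLOSUM62 all canonical diagonal
entries are positive, so identity ≤ similarity with the default matrix (the
package asserts this; with a pathological custom matrix it need not hold).

**2. Identity ranking.** Homologs are sorted by identity, descending, with a
stable sort (ties keep database input order) so runs are bit-reproducible.
Empty alignments (optimal score 0) rank last with identity 0; they are a
legitimate result, not an error.

**3. Coupled-cluster donor search.** Target positions are grouped into
clusters of structurally coupled sites. A homolog qualifies for a cluster
only if `map_position` returns a canonical residue different from the
forbidden one at *every* clustered position; the first qualifying homolog in
rank order donates the whole cluster's substitutions. Clusters are searched
independently, so one variant may mix donors — the coupling constraint is
within clusters only, which is exactly the structural argument: residues in
contact must be compatible with each other, while distant sites are assumed
separable.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| substitution matrix | BLOSUM62 | log-odds (half-bits) | the default of the standard local-alignment tools whose identity figures this package mirrors |
| `gap_open` | 10 | score | idem; configurable, and recorded in every report/manifest |
| `gap_extend` | 0.5 | score per extra gapped position | idem |
| contact `cutoff` | 4.5 | Å, minimum heavy-atom distance | a conventional heavy-atom contact threshold; "steric contact" has no single authoritative number, so the cutoff is a flagged, logged parameter, and both side-chain and backbone atoms count (the simplest defensible reading) |
| `top_n` (profiles) | all homologs | count | variation profiles are usually inspected near the top of the ranking |

Because the defaults of the classical tooling are not a law of nature, every
report and run manifest records matrix name and both gap penalties; re-running
with the manifest's parameters reproduces byte-identical outputs.

## Numerical and tie-breaking choices

- **Scores are doubles, never rounded during DP**; `gap_extend = 0.5` makes
  half-integer scores routine, and all score values are exactly
  representable in binary floating point, so traceback equality tests are
  exact.
- **Traceback ties**: among maximal cells the smallest (query, hit)
  coordinate in row-major order wins; within a cell, diagonal is preferred
  over gap-in-hit over gap-in-query, and closing a gap run is preferred to
  extending it. Any consistent rule would give an optimal alignment; fixing
  one makes outputs deterministic, which reports and tests rely on.
- **Empty alignments** (max score 0) return zero-length aligned strings with
  identity = similarity = 0 rather than erroring, so a single unrelated
  database entry cannot abort a batch run.
- **Ambiguity letters** (X, B, Z, U) are accepted on input because real
  BLAST dumps contain them, but score 0 wherever the matrix lacks an entry,
  never count as similar, and disqualify a donor at a mapped target position
  — an ambiguous letter cannot be written as a point mutation. The same
  logic excludes gapped and uncovered positions: only residue-for-residue
  swaps are ever proposed.
- **Coordinates are 1-based inclusive** at every user-facing surface,
  matching mutation notation such as C140M.
- **Degenerate inputs**: duplicate FASTA ids are a hard error (ids join
  reports); an all-conserved cluster yields an explicit unresolved marker
  and a distinct process exit status (3), not a crash, mirroring the
  biological reality that 100%-conserved sites offer no extant alternative.

## Open design points, and how they were decided

- **Gap adjacency.** The donor criterion requires a non-gap residue *at* each
  clustered position only; a donor with an indel *near* (but not at) the
  cluster is acceptable. Requiring a locally gap-free window would conflate
  alignment uncertainty with the coupling constraint; users worried about
  local indels can inspect the variation profile.
- **Residue choice at a variable site.** When several replacements exist in
  close relatives, the package reports the top-ranked donor's residue —
  a mechanical, reproducible rule — and supports per-position manual
  overrides (e.g. choosing an isosteric serine among extant options). An
  override is validated (canonical, not the forbidden residue, at a target
  position), applied unconditionally, and flagged `override = TRUE` in the
  report; a cluster counts as resolved when every position ends
  non-forbidden via donor or override. This keeps the automatic rule free of
  guessed chemistry while letting the designer exercise judgement visibly.
- **Cluster independence.** Clusters never share a donor requirement; the
  alternative (one donor for all clusters) would discard most of the
  database for no structural reason.
- **The query in its own database** needs no special-casing: it carries the
  forbidden residue at every target position and so never qualifies.

## What the synthetic generator emulates — and what it does not

`generate_homolog()` mutates a query to an exact target identity, drawing
replacement residues with probability proportional to `exp(BLOSUM62 score)`
so that generated families reproduce the similarity > identity pattern of
real ortholog alignments; chosen residues can be *planted* (or pinned to the
query residue) at chosen positions, and short indels (length 1–3, never on
planted positions) can be switched on with full coordinate bookkeeping. One
integer seed determines everything; each FASTA header embeds it.

The packaged study system (`chaperonin_example_query()`,
`chaperonin_example_family()`) is a synthetic stand-in for an archaeal
group II chaperonin design problem: a 543-residue query with cysteine at
exactly 140, 237, 286, 359, 393, 470, 484 and a five-member family whose
identity levels (92%, 85.8%, 66.3%, 59.2%, 45%) and planted substitutions
(M140/Y470/T484, E237/V286, V359, S393) realise the documented design
scenario, including a close decoy whose single equatorial substitution forces
the coupled cluster to a more distant donor. These generator defaults *are*
the study conditions and are not adjusted per run.

What the generator does **not** emulate: phylogenetic correlation between
homologs (each is drawn independently from the query), site-rate
heterogeneity, compositional drift, long indels, and alignment error against
deep divergence. Passing tests therefore demonstrate the correctness of the
algorithmic pipeline under controlled conditions — not that any particular
natural database contains a suitable donor, which is an empirical property
of the family being engineered.

## Problem sizes used in the test suite

The suite verifies alignment scores against an exhaustive chain-enumeration
oracle on 500+ random peptide pairs (length ≤ 8, reduced alphabet — small
enough for the oracle to be exact), against an independent aligner
implementation on longer pairs, and runs the full design on the 543-residue
family (5 homologs) under several seeds. These sizes exercise every code
path while keeping the default test run in tens of seconds; the method itself
has no intrinsic size limit beyond quadratic DP cost per pair.

## Known limitations

- No stability/energy scoring of candidate replacements; the ranking is by
  whole-sequence identity, a proxy for compatibility, not a biophysical
  model.
- Contact clustering is single-chain; inter-subunit contacts in an assembly
  are not considered.
- No remote homolog retrieval: the database is the user's responsibility
  (`fetch_homologs_stub()` documents the expected multi-FASTA input).
- Positions 100% conserved across the database are unresolvable by
  construction; the design is flagged incomplete rather than inventing a
  replacement.

## Session walk-through

```{r example}
query  <- chaperonin_example_query()
family <- chaperonin_example_family(seed = 1)
ranked <- rank_homologs(query, family$records)
select(ranked, rank, hit_id, identity_pct, similarity_pct)

design <- design_variant(query, family$records,
                         target_spec(query, "C", chaperonin_example_clusters()),
                         ranked = ranked)
tidy(design)
glance(design)

profile_tally(variation_profile(ranked, c(393L)))
```
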