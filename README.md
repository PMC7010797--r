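# orthosub

Evolution-guided design of residue-replacement protein variants in R.

## The problem

Site-specific labeling chemistry (maleimides, iodoacetamides) needs a protein
with a *single* reactive cysteine, but most proteins carry several. The common
fix — mutating each extra cysteine to serine or alanine by trial and error —
frequently destroys expression, stability or activity. `orthosub` takes the
rational route instead: natural variation across orthologs has already tested
which replacements a protein family tolerates, so for every unwanted residue
the best guide is the *closest relative that already lacks it*.

The method, for a query protein, a database of homolog sequences (e.g.
pre-fetched BLAST hits) and a set of target positions:

1. **Align** every homolog to the query with an exact Smith–Waterman local
   alignment under affine gap penalties (Gotoh dynamic programming; a gap of
   length *L* costs `open + (L−1)·extend`, default BLOSUM62 / 10 / 0.5).
   Percent identity and similarity are computed over *all* alignment columns,
   gap columns included.
2. **Rank** the homologs by percent identity, descending (ties keep input
   order, so runs are deterministic).
3. **Replace per cluster.** Target positions whose residues are in steric
   contact form a *cluster* and must be replaced coincidently: scanning down
   the ranking, a homolog qualifies for a cluster only if it carries a
   canonical, non-forbidden residue at *every* clustered position — a gap,
   an uncovered position or an ambiguity letter disqualifies it. The first
   (closest) qualifying homolog donates the substitutions; different clusters
   may use different donors. Clusters can be derived from a structure:
   residues whose minimum heavy-atom distance is below a cutoff (default
   4.5 Å) are coupled, and clusters are the connected components of that
   contact graph.
4. **Build the variant** by applying all donated substitutions; clusters with
   no qualifying homolog are reported unresolved (common for 100%-conserved
   sites) and the design is flagged incomplete rather than aborted.

The residue type is not restricted to cysteine — any canonical amino acid can
be targeted (single-tryptophan or single-lysine designs work the same way).

## Worked example

The package ships a fully synthetic, offline study system: a 543-residue
chaperonin-like query with cysteines at 140, 237, 286, 359, 393, 470 and 484
(three coupled equatorial sites, a coupled apical pair, two singletons), and a
generator that builds an ortholog family around it at controlled identities
with known substitutions planted.

```r
library(orthosub)

query  <- chaperonin_example_query()
family <- chaperonin_example_family(seed = 1)
design <- design_variant(query, family$records,
                         target_spec(query, "C", chaperonin_example_clusters()))
design
#> <variant_design> synthetic_chaperonin_query: eliminate 'C' at 7 positions in 4 clusters
#>   substitutions: C140M, C470Y, C484T, C237E, C286V, C359V, C393S
#>   design complete

dplyr::select(tidy(design), cluster, position, from_residue, to_residue,
              donor_id, donor_rank, donor_identity_pct)
#> # A tibble: 7 × 7
#>   cluster position from_residue to_residue donor_id           donor_rank
#>     <int>    <int> <chr>        <chr>      <chr>                   <int>
#> 1       1      140 C            M          equatorial_donor            2
#> 2       1      470 C            Y          equatorial_donor            2
#> 3       1      484 C            T          equatorial_donor            2
#> 4       2      237 C            E          apical_donor                3
#> 5       2      286 C            V          apical_donor                3
#> 6       3      359 C            V          intermediate_donor          4
#> 7       4      393 C            S          decoy_close                 1
```

Reading the table: the *closest* relative (`decoy_close`, rank 1, ~92%
identity) substitutes only one of the three coupled equatorial cysteines, so
it is rejected for that cluster and donates only the singleton S393; the
coupled cluster falls through to `equatorial_donor` (~85.8% identity), which
carries M/Y/T at all three sites simultaneously. The variant sequence
(`design$variant`) is the query with exactly those seven point mutations and
no cysteine left at any target position. `glance(design)` summarises the run
(7 substitutions, 4/4 clusters resolved, 4 distinct donors, complete).

Structure-derived clusters and the shell interface compose the same way:

```sh
orthosub.R contacts --structure subunit.pdb --chain A --positions 140,237,286,359,393,470,484
# -> 140,470,484;237,286;359;393
orthosub.R design --query query.fasta --db hits.fasta --residue C \
    --clusters "140,470,484;237,286;359;393" --override 393=S --out design_out/
```

(`orthosub.R` is installed under `system.file("scripts", package = "orthosub")`.
Exit status 0 = complete design, 3 = some cluster unresolved, 2 = error.)

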