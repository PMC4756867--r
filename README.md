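# subsite

Peptidase substrate specificity profiling and cleavage-site conservation
scoring in R.

A peptidase hydrolyses a substrate at the scissile bond between the P1 and
P1′ residues; flanking residues are numbered P4…P1 on the non-prime
(N-terminal) side and P1′…P4′ on the prime side, and the enzyme pockets
that accommodate them S4…S4′ (Schechter–Berger nomenclature). Given a
curated collection of substrate cleavages — each record a peptidase
(MEROPS identifier), a substrate, the UniProt residue number of P1 and the
P4–P4′ window — `subsite` answers two questions that matter to anyone
working on protease specificity or degradomics:

1. **What does this peptidase prefer in each binding pocket?**
   Per-pocket occurrence counts over the 20 amino acids (plus `X` for
   non-standard residues and blocking/reporter groups), decile-shaded
   display matrices, WebLogo-style information-content letter heights, and
   a rule-based symbolic profile: one or two dominant amino acids (≥ 50%
   of cleavages), an amino-acid property group (λ aliphatic, @ aromatic,
   \+ acidic, − basic, Σ small, Ω other) when the group beats every single
   residue, or — for peptidases with ≥ 200 known cleavages — up to two
   *negative* preferences, amino acids never observed in the pocket.
   Each profile carries a **reliability score**: the average percentage
   pairwise difference between the windows of all substrate pairs,

   score = 100 · Σ differences / (n_pairs · n_positions_considered),

   with the number of positions considered computed from pocket occupancy
   (8 for typical endopeptidase sets, 5 for amino-/carboxypeptidases, 6
   for dipeptidyl-/peptidyl-dipeptidases, 2 for dipeptidases). Scores
   ≥ 75 are trustworthy (green), 50–74 less so (yellow), < 50 cautionary
   (red); profiles from fewer than 40 cleavages additionally carry a
   low-confidence flag, and displays are only emitted at 10 or more.

2. **Is this particular cleavage physiologically plausible?** The
   "analyse substrates" workflow scores conservation of a cleavage site
   across an orthologue alignment (emulating a UniRef50 cluster): a
   substitution at a window position is *acceptable* only if that amino
   acid is known to occupy the same binding pocket in at least one other
   substrate of the same peptidase; otherwise it is an *unacceptable
   replacement*. The per-pocket counts of unacceptable replacements — low
   means conserved, hence likely physiological — are reported per
   submitted cleavage, in batch, from a three-column submission file
   (MEROPS id, UniProt accession, P1 position; at most 5000 lines /
   10 MiB).

The package also derives processing-event cleavages (initiator-Met
removal, signal/transit peptides, propeptide and chain boundaries) from
UniProt flat-file annotations with sequence-drift QC, and ships seeded
generators for synthetic collections and alignments so every code path is
testable offline.

## Worked example

```r
library(subsite)

# a synthetic endopeptidase with a basic preference at P1
coll <- simulate_collection(profile_spec(
  peptidase = "M12.217", n_records = 60,
  pocket_probs = list(P1 = c(K = 0.55, R = 0.25, A = 0.1, G = 0.1),
                      "P1'" = c(L = 0.4, V = 0.3, I = 0.2, S = 0.1)),
  seed = 42))

rel  <- reliability_score(coll, "M12.217")
prof <- call_preferences(build_matrix(coll, "M12.217"),
                         "endopeptidase", rel)
prof
#> preference_profile for M12.217 ( 60 cleavages )
#>   reliability: 86.1% (green)
#>  pocket     state call symbol      pct  band
#>      P4      none <NA>   <NA>       NA  <NA>
#>      P3      none <NA>   <NA>       NA  <NA>
#>      P2      none <NA>   <NA>       NA  <NA>
#>      P1 preferred    K      K 63.33333 60-69
#>     P1' preferred    L      L 53.33333 50-59
#>     P2'      none <NA>   <NA>       NA  <NA>
#>     P3'      none <NA>   <NA>       NA  <NA>
#>     P4'      none <NA>   <NA>       NA  <NA>
```

The P1 pocket is called for Lys (63% of cleavages, shade band 60–69); the
reliability score of 86% (green band) says the substrate windows are
varied, so the inferred preference is trustworthy.

```r
# conservation of one cleavage across six orthologues, with a His
# substitution planted at P1' in two of them
aln <- simulate_orthologues(orthologue_spec(
  reference_id = "P87671", ref_length = 100, n_rows = 6,
  p1_position = 50, sub_prob = 0.08, indel_prob = 0.05,
  planted = data.frame(row = 1:2, pocket = "P1'", residue = "H"),
  seed = 7))

item <- list(merops_id = "M12.217", substrate_accession = "P87671",
             p1_position = 50)
analyse_cleavage(coll, aln, item)
#> conservation_result: M12.217 cleaving P87671 after residue 50
#>   homologues: 6  known cleavages: 60
#>   unacceptable replacements:
#>  P4  P3  P2  P1 P1' P2' P3' P4'
#>   0   0   0   0   2   0   0   0

render_alignment(aln, item, coll)
#> M12.217 cleaves P87671 after residue 50 (window P4-P4')
#>           P4  P3  P2  P1  P1' P2' P3' P4'
#> > P87671  =D= =K= =S= =I= =S= =V= =V= =I=
#>   HOM0001 =D= =K= =S= =I= !H! =V= =V= =I=
#>   HOM0002 =D= =K= =S= =I= !H! =V= =V= =I=
#>   HOM0003 =D= =K= =S= =I= =S= =V= =V= =I=
#>   ...
```

His has never been seen at P1′ in any other substrate of this peptidase,
so the two substituted orthologues count as unacceptable replacements
(`!H!`); every other window residue is identical (`=X=`). Two
unacceptable replacements out of five homologues at a single pocket is a
mild warning sign — the cleavage may be physiological only in a subset of
species, or the peptidase's specificity may be incompletely explored.

A thin command-line wrapper mirrors the same operations
(`inst/cli/subsite.R`): `specificity`, `reliability`, `preferences`,
`analyse-substrates`, `substrate-map`, `import-uniprot`, `simulate`.

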