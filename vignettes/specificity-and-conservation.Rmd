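---
title: "Profiling peptidase specificity and scoring cleavage-site conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling peptidase specificity and scoring cleavage-site conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subsite)
```

## The data model

A cleavage record describes one scissile-bond event: the peptidase (a
MEROPS identifier such as `M12.217`, or a family-level code such as `M24`
when only the family is known, or `NA` when the responsible enzyme is
unknown), the substrate, the 1-based residue number of the P1 residue in
the full UniProt coding sequence, and the window of up to four residues on
either side of the bond (P4–P4′). Coordinates are 1-based with inclusive
intervals, matching UniProt feature conventions; the bond lies between
`p1_position` and `p1_position + 1`, so a valid P1 always has a P1′
neighbour.

Window slots hold one of three kinds of token: a standard amino acid, `X`
for a non-standard residue or a blocking/reporter group (the original
token, e.g. `Abz` or `EDDnp`, is preserved in a separate `group_labels`
field for display, but all scoring treats it as `X`), or *empty* for a
position beyond a terminus or absent from a short synthetic substrate.
Empty slots can only form contiguous runs at the outer edges of the
window, and P1 is never empty. Each record carries one of a closed set of
six cleavage classes (`physiological`, `pathological`,
`non-physiological`, `synthetic`, `theoretical`, `unclassified`);
unrecognised class strings are mapped to `unclassified` with a parse
issue rather than dropped, and every malformed line is reported in the
issue table so curation errors stay visible.

The activity class of a peptidase determines which pockets can
structurally exist: an aminopeptidase has no S4–S2, a carboxypeptidase no
S2′–S4′, a dipeptidyl-peptidase no S4–S3, a peptidyl-dipeptidase no
S3′–S4′, and a dipeptidase only S1 and S1′. These masks affect *display*
(masked pockets are never called), but every quantity computed from the
data — notably the number of positions considered by the reliability
score — is derived from the observed occupancy, not assumed from the
class, because exopeptidase collections dominated by short synthetic
substrates often occupy fewer pockets than the class nominally allows.

## The reliability score

Inferred preferences are only as good as the diversity of the substrates
behind them: a collection dominated by variants of one synthetic peptide
will show strong apparent preferences that merely echo the residues held
constant in the assay. The reliability score quantifies diversity as the
average percentage difference between windows. All `n(n−1)/2` unordered
record pairs are compared pocket by pocket over the considered positions
(pockets occupied in at least one record), differences are summed, and

$$\mathrm{score} = 100 \cdot
  \frac{\sum \text{differences}}
       {n_\text{pairs} \cdot n_\text{positions considered}}.$$

Non-standard tokens are replaced by `X` before comparison. The pairwise
rules reduce to plain token inequality with `X` and *empty* treated as
ordinary symbols: `X` vs `X` and empty vs empty are equal; `X` vs a
residue, and empty vs a residue at a considered pocket, differ. These
choices make a collection of identical windows score exactly 0 and a pair
of windows differing everywhere score exactly 100. The implementation
tallies symbol counts per pocket (so each pocket costs O(n) rather than
O(n²)); the test suite checks it against an independent exhaustive
double-loop oracle to 1e−9.

Bands follow the published interpretation: ≥ 75 green (varied substrates,
preferences likely correct), 50–74 yellow, < 50 red. Two further gates
use published constants: a specificity display (logo + matrix) is only
emitted for peptidases with ≥ 10 known cleavages, and any profile built
from fewer than 40 cleavages carries a low-confidence caution flag.

## Calling pocket preferences

With `p(a)` the percentage of all cleavages carrying amino acid `a` at a
pocket (the denominator is the total cleavage count, not per-pocket
occupancy — occupancy is reported alongside so sparse pockets remain
interpretable), each unmasked pocket is called by the first matching
rule:

1. **Single residues.** If the largest `p(a)` ≥ 50%, the pocket is called
   for that residue; a second residue is listed only if its own
   percentage also reaches 50% (possible only at a 50/50 split). The
   shade band comes from the combined percentage: 50–59, 60–69, 70–79,
   80–89, 90+.
2. **Property groups.** Otherwise, if a group's summed percentage reaches
   50% *and* exceeds every single residue's percentage, the group symbol
   is called: λ aliphatic (I, L, V), @ aromatic (F, W, Y), + acidic
   (D, E), − basic (R, H, K), Σ small (A, C, G, S), Ω other
   (N, Q, M, P, T). A dominant single residue therefore always beats a
   group symbol; the group rule exists for peptidases whose preference is
   genuinely distributed across chemically similar residues.
3. **Negative preferences.** Otherwise, when 200 or more cleavages are
   known, up to two amino acids with zero count at the pocket are
   reported as not acceptable. The 200-cleavage gate exists because some
   amino acids (Cys, Trp) are rare near cleavage sites, so absence only
   becomes meaningful at depth. Candidates are ranked by lowest
   whole-matrix frequency (the rarest residues are the most informative
   absences), ties broken alphabetically. A pocket never observed
   occupied yields no negative call at all — for many exopeptidases the
   prime-side pockets are empty only because synthetic substrates lack
   those residues, and reporting twenty "unacceptable" amino acids there
   would be misleading.

The 50% threshold is the floor of the lowest shade band in the published
display scheme; the display never shades below 50%, so no weaker call is
defensible from it. Tie-breaking everywhere is by higher count first,
then alphabetical one-letter code, which makes every profile
deterministic.

Matrix display shading uses decile bins `floor(pct / 10)` capped at 10,
so a 100% cell shares the top bin with 90–99% cells; whether the original
display used ten true deciles or a 90+ cap is not stated anywhere we know
of, and the capped floor is documented as this package's choice. Logo
letter heights are relative frequencies over observed standard residues
(`X` excluded) scaled by the Shannon information content
`R = log2(20) − H` in bits, without small-sample correction — the
standard WebLogo construction.

## Conservation of cleavage sites

The conservation workflow operationalises one hypothesis: a cleavage site
conserved across orthologues is likely physiologically relevant, where
conservation means *conserved in terms of peptidase binding*, not mere
sequence identity. For each submitted cleavage the substrate's orthologue
alignment (pre-computed, emulating a UniRef50 cluster alignment; this
package deliberately consumes aligned FASTA rather than running an
aligner or fetching clusters) is mapped gap-aware so that each window
pocket corresponds to one alignment column. Each non-reference residue
at a mapped column is then classified:

* `identical` — equal to the reference residue;
* `acceptable` — different, but observed at the same pocket in at least
  one *other* substrate of the same peptidase (the query cleavage itself
  is excluded when building the allowed set; other cleavages of the same
  substrate still contribute);
* `unacceptable` — a standard amino acid never seen in that pocket;
* `undetermined` — `X` or another non-standard symbol;
* `gap`.

Only `unacceptable` is counted; gaps and undetermined residues are
deliberately neutral, and pockets absent from the reference (a cleavage
within three residues of a terminus) count zero. Allowed sets pool all
cleavage classes by default — the batch runner accepts a class filter for
users who want, say, physiological evidence only. The per-pocket counts
are monotone by construction: adding substrates to the collection can
only move calls from `unacceptable` to `acceptable`, never the reverse,
and the tests exercise this property directly.

Batch submissions follow the service's file contract: three columns
(MEROPS identifier, UniProt accession, P1 position), an optional header,
at most 5000 data lines and 10 MiB per file. One result row is emitted
per input line — items without an alignment get a status note instead of
being dropped — with the peptidase's total cleavage count and the number
of aligned homologues included so the reader can judge how much the
counts mean: unacceptable counts from a 15-cleavage peptidase say little,
and a high count at a single no-preference pocket can simply mean the
orthologues substituted to a rare amino acid whose acceptability is
unknown. The package reports raw counts and surfaces this caveat rather
than guessing a normalisation. `n_homologues` counts all alignment rows
including the reference; the counting convention is stated here because
printed cluster sizes elsewhere do not say whether the query is included.

## UniProt-derived processing events

SwissProt feature annotations (INIT_MET, SIGNAL, TRANSIT, PROPEP, CHAIN,
PEPTIDE) are converted to cleavage records. Initiator-Met removal maps to
a methionyl aminopeptidase for prokaryotes and to the family-level code
`M24` for eukaryotes (either eukaryotic MetAP may act); signal peptides
map to signal peptidase (prokaryote) or the signal peptidase complex
(eukaryote). The concrete identifiers are configuration values
(`ingest_config()`), not constants, since different MEROPS releases spell
them differently. Viral entries use the eukaryote-style mapping on the
assumption that host machinery does the processing. Transit-peptide and
propeptide/chain/peptide boundaries are emitted with an *unmapped*
peptidase by default because the responsible enzyme is usually unknown.
Features whose evidence matches a configurable marker list (ECO inference
codes, "By similarity", "Potential", "Probable") are treated as predicted
and skipped — theoretical cleavages are not collected. The QC check
re-derives the window from the current sequence and compares checksums,
so a UniProt sequence update that touches the window names the drifted
pockets, and one outside the window still fails on checksum alone.

## What the generators emulate (and what they do not)

`simulate_collection()` draws windows i.i.d. per pocket from categorical
distributions — adequate for testing counting, calling and scoring logic,
but real collections are not i.i.d.: substrates cluster by assay series,
pockets correlate, and classes mix. `simulate_orthologues()` mutates a
reference with uniform per-site substitutions and indels; it uses no
empirical substitution matrix (PAM/BLOSUM), holds the cleavage window
invariant unless substitutions are planted, and inserts indels only so
that reference coordinates stay stable (insertions are global column
events where the reference carries a gap; deletions are per-row). Planted
substitutions override every other process, which is what makes
exact-recovery tests possible. Passing tests on these fixtures
demonstrates that the arithmetic and the rules are right; it does not
demonstrate calibration on real degradomics data, where assay bias is the
dominant error source.

Default generator conditions used across the test suite: uniform pocket
distributions over the 20 amino acids; planted preferences at 65% mass
for recovery tests (comfortably above the 50% calling threshold at
n = 200, where sampling noise is ±3–4 points); collections of 20–500
records; alignments of up to 50 rows and a few hundred columns with
substitution probabilities around 0.05–0.1 and indel probabilities up to
0.2. Recovery and property tests run over 20 fixed seeds; the
column-mapping oracle runs over 500 random alignments. All generators
restore the ambient RNG state, so seeds compose predictably.

## Numerical and degenerate-input choices

* The reliability score needs ≥ 2 records; the count matrix needs ≥ 1;
  both fail loudly naming the peptidase rather than returning zeros.
* A pocket with zero occupancy has all-zero logo heights and no
  preference or negative call.
* Duplicate cleavage records (same peptidase/substrate/position from
  multiple references) are kept as separate records and collapsed only in
  displays (the substrate processing map), since the record count is
  itself a datum.
* Serialization is exact: the collection TSV dialect (tab-separated, `.`
  for absent optional fields, windows as 8 `-`-joined tokens with empty
  slots rendered as the empty string) round-trips record-for-record, and
  batch outputs are byte-identical across runs.
* All thresholds in the code — 50% calling, 200-cleavage negative gate,
  40-cleavage confidence gate, 10-cleavage display gate, 75/50 band
  boundaries, 5000-line/10 MiB submission limits — are the published
  service constants, kept as named constants in one place.

## Known limitations

* Preference calling precedence gives a ≥ 50% single residue priority
  over its containing group; a reading of the display legend under which
  a group symbol replaces a single residue whenever the group sum is
  larger is also defensible, but would make single-residue calls nearly
  unreachable for residues with popular neighbours, so the single-first
  rule is used and documented here.
* Down-weighting of near-identical paralogues within an orthologue
  cluster is not attempted; a cluster containing a non-substrate
  paralogue will inflate unacceptable counts, and the alignment rendering
  is the intended diagnostic.
* The UniProt parser covers the ID/AC/OC/FT/SQ blocks it needs, in both
  the current and classic FT layouts; it is not a general flat-file
  library.
* Family-level MEROPS codes are validated as a letter plus 2–3
  alphanumerics; single-digit family labels (e.g. "S1" written without a
  leading zero) do not validate and should be given as `S01`-style codes.
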