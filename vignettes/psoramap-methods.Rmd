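---
title: "Methods: linkage mapping, macrosynteny and Ks divergence dating in psoramap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage mapping, macrosynteny and Ks divergence dating in psoramap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`psoramap` reimplements, as one tested pipeline, the three analyses that
produce a first-generation genome resource for an orphan legume: an F2
genetic linkage map from genotyping-by-sequencing (GBS) markers, a
macro-synteny alignment of that map against chromosome-level reference
genomes of related phaseoloid species, and divergence-time estimates from
synonymous-substitution (Ks) distributions anchored at the papilionoid
whole-genome duplication (WGD). This vignette explains the models, the
parameters that matter, the numerical choices, and what the simulation-based
tests do and do not establish.

## 1. The F2 genotype model and phasing

An F2 population derives from selfing a single F1, so every locus segregates
1:2:1 for codominant SNP calls (`AA`/`AB`/`BB`) and 3:1 for dominant
presence/absence variants (PAV, `P`/`A`), where heterozygotes are
indistinguishable from the presence class. Phased F2 scores are stored as
class codes 0/1/2 (copies of the parent-2 allele); a dominant marker is
tagged by which parent carries its presence allele (`dom1`/`dom2`), so a
phase swap is always the involution `code -> 2 - code`.

Phasing rules, applied marker by marker against the two parent rows:

* SNP with at least one homozygous parent: that parent's allele fixes the
  orientation (this also covers one missing parent).
* SNP with both parents heterozygous or missing: both candidate phasings —
  exact allele swaps — are retained (`dual-retained`) and resolved after
  mapping against the nearest unambiguously phased markers, choosing the
  candidate with the smaller estimated recombination fraction. Ties keep the
  first neighbour's phase, with a warning.
* PAV with one parent absent: presence must descend from the other parent,
  fixing the orientation even when that parent's own call is missing.
* PAV with both parents present: dual-retained (a heterozygous parent reads
  `P`).
* Both parents homozygous for one allele at a segregating marker (SNP), or
  both absent (PAV): the marker is flagged inconsistent and excluded — a
  single corrupted marker call is far more likely than a mislabelled
  individual, so the marker, not the individual, is dropped. Monomorphic
  markers are excluded as unmappable.

Individuals are screened by double-crossover counts: along a provisional
order, a genotype run of length one flanked by identical genotypes implies
crossovers in two adjacent tiny intervals, which at realistic map densities
is essentially always a genotyping error. Individuals whose count exceeds
`median + k * MAD` (default `k = 5`; the MAD is floored at 0.5 so an
all-clean population does not flag on zero spread) are reported for removal.
The threshold is a parameter because no principled universal constant
exists; the default is conservative. Batch-level PAV removal
(`filter_pav_by_missingness`) generalises the common situation where one
sequencing pool has lower depth: all PAV calls of the listed batches are
discarded, then PAV markers above a missingness ceiling are dropped.

## 2. Two-point recombination fractions

For loci at recombination fraction r, F1 gametes carry parental haplotypes
with probability (1-r)/2 each and recombinants with r/2 each; an F2
genotype is the sum of two independent gametes, giving the classic 3x3
joint table. Dominant markers collapse the appropriate cells. `estimate_rf`
maximises this likelihood over r in [0, 0.5] by 1-D continuous optimisation
(with explicit endpoint checks), and reports the LOD against r = 0.5. The
estimator is validated against a brute-force grid search (step 1e-4) of the
same likelihood, rebuilt in the tests from an explicit gamete enumeration.

`rf_matrix` computes all pairs at once: class-combination counts are
accumulated as indicator cross-products (a few BLAS calls per class pair)
and the log-likelihood is scanned over an r grid (step 0.0025), so a
2000-marker matrix costs seconds rather than hours. The matrix also records
`rf_up`, the largest r whose log-likelihood is within 1.92 (the 95%
chi-square cutoff) of the maximum. This matters because dominant markers in
repulsion carry very little linkage information in an F2: their ML point
estimates have enormous variance and regularly collapse to spuriously tight
values. Ordering on `rf_up` — the conservative end of the likelihood
interval — is what keeps those pairs from masquerading as tight linkage;
it is also the quantitative justification for the field's habit of treating
codominant markers as "priority" markers.

Map distances use the Kosambi function, d = 25 ln((1+2r)/(1-2r)) cM, with
closed-form inverse r = tanh(d/50)/2; the round trip is exact to 1e-10
across the domain.

## 3. Building the map

**Grouping.** Single-linkage transitive closure over pairs with
rf <= threshold and LOD >= 3, at thresholds 0.10, 0.15, 0.20: groups formed
at a lower threshold are carried forward and merged only if linked at the
next one. Because single linkage merges groups on a single edge, the
pipeline additionally requires the pair's whole likelihood interval to sit
below the threshold (`rf_up` <= threshold): the one class of pairs whose
point estimates collapse spuriously to tight linkage — dominant markers in
repulsion — is precisely the class with wide intervals, and without the
gate a lone such pair can fuse two chromosomes. The LOD floor is standard
practice; the group count is not forced — ten groups must emerge from the
data, as they do on the default simulation across seeds. Groups below a
minimum size (default 4) are reported unplaced.

**Binning.** Markers of the same score type whose non-missing calls never
conflict are binned (missing is a wildcard); the member with the fewest
missing calls represents the bin, ties broken by id. With per-call error
rates around 0.5%, exact pattern identity is rare even for co-located
markers, so bins are sparser in error-prone simulated data than in real GBS
data, where reads from one locus produce literally identical patterns.

**Ordering.** The contract is to minimise total adjacent Kosambi length,
but at marker spacings below the rf resolution that objective alone is
treacherous: orders that zigzag through estimation noise can cost *less*
than the true order, so a pure local-search TSP heuristic converges to
globally scrambled arrangements. `seriate_order` therefore takes its global
structure from the first principal coordinate of the `rf_up` distance
matrix (classical MDS, which integrates all pairwise information and is
robust to pairwise noise), falling back to a greedy nearest-neighbour chain
seeded at a codominant marker when the embedding is degenerate. Local
polish then runs windowed 2-opt reversals (window 10) plus Or-opt block
relocations (segments up to 12 markers, optionally reversed, any
destination): block moves repair embedding folds — cohesive segments
stranded far from their true place — while the windows prevent the
objective from restructuring the global order it cannot actually resolve.

**Jackknife stability.** The full-data order is re-estimated on resamples
that drop 10% of individuals. A marker is stable in a resample when its
full-data neighbours sit within `neighbor_window` (default 5) positions of
it; markers stable in fewer than 80% of resamples are removed and the rest
reordered once. With strict adjacency (window 1) virtually every marker at
sub-resolution spacing fails — neighbours swap freely between resamples
without the order being wrong at any meaningful scale — so the window keeps
the stability score sensitive to genuine placement instability only.
Removed markers are later *attached*: assigned to the skeleton interval
whose flanking markers jointly minimise summed rf (reported as an interval,
not a point), or left unplaced if rf exceeds 0.3 to every skeleton marker.
Dual-retained markers are phase-resolved against the skeleton and attached
the same way. Every input marker ends in exactly one class: skeleton,
redundant, attached, or unplaced.

**Positions and summaries.** Skeleton positions accumulate
Kosambi-transformed adjacent rf re-estimated by continuous ML; multipoint
likelihood refinement is deliberately out of scope. Summary tables report
per-group skeleton/redundant/attached/total counts, length (1 decimal),
mean adjacent interval `length/(skeleton-1)` (2 decimals) and the maximum
interval; the totals row computes its overall mean as
`total length / (total skeleton - n groups)`.

On the default simulation (2042 markers in the published per-group
proportions, 178 individuals, 0.5% error, 3% missing) the pipeline recovers
ten groups, places ~98% of markers in their true group, and orders every
group's skeleton at |Spearman rho| >= 0.996 against truth, in about four
minutes on one CPU. Two caveats: simulated map *lengths* inflate (roughly
2.4x here) because error-driven rf noise accumulates over many dense
adjacent intervals — the well-known map-inflation effect, which real
pipelines counter with multipoint error correction; and evenly spaced
simulated markers under-produce redundant bins relative to real GBS data.
Passing tests therefore certify grouping and ordering, not absolute map
length.

## 4. Macro-synteny filtering

Inputs are standard 12-column translated-BLAST tabular hits of ~90 bp
marker tags against chromosome-level genomes. The chain is:

1. **Parse and cut**: drop hits with e-value above 1e-5 and hits to
   subjects absent from the chromosome-length table (unanchored
   scaffolds); malformed rows abort with their line number. Reversed
   subject coordinates (minus-strand translated hits) are normalised to
   `sstart <= send` with an orientation flag — display convention only.
2. **Top hits**: one best hit per marker (e-value, then bitscore, then
   lexicographic chromosome). For a WGD-carrying target the filter runs in
   two stages — best hit per (marker, chromosome), then the best two per
   marker — so a marker keeps at most two hits, never two on one
   chromosome.
3. **Isolated matches**: with all matches ordered by concatenated genomic
   position (natural-sorted chromosomes, then hit midpoint, ties by marker
   id), a match is removed iff no other match in the five-match window
   centred on it shares its (linkage group, chromosome) pairing. Flags are
   computed in one pass on the pre-removal list, so removal is
   order-independent and does not cascade. Windows truncate at the list
   ends rather than deleting legitimate terminal-block matches. A strictly
   centred window is used; an "any window containing the match" variant
   would be more permissive, and the centred reading reproduces the
   textbook worked example either way.
4. **Concatenated coordinates**: x = cumulative bp offset of preceding
   chromosomes + hit midpoint (the midpoint choice is arbitrary at genome
   scale); y = cumulative cM offset of preceding groups + map position.
   Output is a gnuplot-style blank-line-separated series file per
   (group x chromosome) pairing plus a base-graphics PNG with boundary
   gridlines.

Per-stage drop counts are attached to every result, and the suite asserts
the audit identity `parsed = retained + dropped(evalue) +
dropped(unanchored) + dropped(top-hit) + dropped(unmapped) +
dropped(isolated)` on arbitrary simulated inputs.

The match simulator lays linkage groups collinearly across chromosomes,
applies inversions, translocations and fissions with validated breakpoints,
duplicates the chromosome set under WGD (second hits independently jittered
by up to 20 kb), and emits noise rows at uniform genomic positions. True-hit
e-values are log-uniform over [1e-9, 9e-6] and noise over [1e-6, 1e-5]:
both pass the significance cut, the ranges overlap, and occasionally a
noise hit beats a weak true hit — so the isolated-match filter, not the
e-value cut, is what removes it, which is precisely the failure mode the
filter exists for.

## 5. Ks divergence dating

**Gene-pair lists.** From all-by-all protein-level hit tables, hits at
e-value <= 1e-5 and identity > 90% are kept (the identity filter is applied
to the report's identity column), self-hits are discarded for a species
against itself, each query keeps its lowest-e-value partner (ties by
bitscore, then id), and the two query directions are unioned into one list
of unordered pairs.

**NG86.** Ka/Ks uses Nei-Gojobori (1986) with Jukes-Cantor correction,
implemented from the standard code rather than wrapping an external
alignment/PAML chain: synonymous site fractions per codon position count
the three single-nucleotide changes with stop-producing changes excluded
from the denominator (so S + N = 3 per ungapped codon, asserted to 1e-9);
multi-difference codons average observed differences over all minimal
substitution pathways, excluding pathways through stops (falling back to
all pathways in the unreachable corner where every pathway is blocked);
pS = Sd/S and pN = Nd/N are corrected by K = -(3/4) ln(1 - 4p/3), with a
`saturated` flag when p >= 3/4. The estimator is pinned to an independent
per-codon counting oracle (a separate implementation with its own code
table and explicit permutation enumeration) to 1e-9 on fixtures with known
substitution counts, and is exactly symmetric in its arguments. Input pairs
must arrive as equal-length in-frame alignments (gapped codons are
skipped); de novo pairwise alignment is outside the package's scope.

**Peaks.** Ks peaks are the local maxima of a Gaussian kernel density
evaluated on a 0.001 grid over [0, range]. The kernel sits on log-Ks
support with Silverman bandwidth, and the density maps back via
f(x) = f_log(log x)/x: Ks distributions are strongly right-skewed, and a
linear-support kernel drags the mode upward by several percent — enough to
corrupt age ratios. All local maxima are reported with the global one
flagged, so a bimodal population (speciation peak plus WGD paralog peak)
exposes both candidates and the user — like the original manual reading —
chooses; the pipeline default takes the global peak.

**The replicate-leaf distance matrix.** Every species contributes two
leaves representing the gene populations descending from the two halves of
its most recent WGD. For species whose most recent WGD is the shared
papilionoid one, the two replicates land in opposite papilionoid
half-clades; a species with a more recent lineage-specific WGD (Glycine)
contributes that WGD's two halves, which both sit inside one papilionoid
half. Entries: a species' own replicates are separated by its self-pair
peak; cross-species leaves in the same half by the pair's speciation peak
(taken as representative of both halves, since observed cross-species peaks
cannot be assigned to a half); cross-half pairs by the papilionoid-WGD peak
(cross-species paralogs), defaulting to the mean self-peak of the species
without recent WGDs. This is the unique reading under which exact peaks
yield an exactly ultrametric matrix — the premise of the downstream
least-squares fit.

**Topology, heights, ages.** Neighbor-joining (default; UPGMA available)
infers the topology, rooted on the branch separating the two papilionoid
half-clades — the branch that *is* the papilionoid WGD. Node heights then
minimise the ultrametric least-squares criterion
sum over leaf pairs of (d_ij - 2 h_MRCA(i,j))^2 subject to h >= 0 and
h(parent) >= h(child). Because each pair constrains exactly one node, this
is a weighted isotonic regression on the tree order, solved exactly by
bottom-up violator pooling (merge a node with its largest violating
descendant block until monotone); the fit matches `phangorn::nnls.tree`
(ultrametric) to machine precision in the cross-check test, and the
hand-solvable three-leaf case (d(A,B)=2, d(A,C)=d(B,C)=6 giving heights 1
and 3) exactly. Ages scale linearly, age = root_age x h/h_root, with the
root calibrated to 56.5 MYA — the papilionoid-origin date
indistinguishable from the papilionoid WGD. After calibration every
root-to-leaf path equals the root age to 1e-9.

**Simulator and recovery.** `sim_ks_config_default` mirrors the study
system: five legumes, papilionoid WGD at 56.5 MYA over all of them, a
Glycine WGD at 10.4 MYA, speciation nodes at 17.4 (Bituminaria-Glycine),
25.9, 30.2 and a 45 MYA crown split, clock 0.0117 Ks/MY (placing the
papilionoid peak near Ks 0.66, the range seen in legume paralog data).
Per-pair Ks values are lognormal around the configured mode with sdlog
0.25 — unimodal and right-skewed like real single-peak populations, but
without the paralog shoulder, saturation tail, or alignment artefacts of
real data. On 5000 pairs per species pair the pipeline recovers the exact
replicate-leaf topology and all node ages within 10%; the published dates
from real transcriptomes are not reproducible without those data, and no
claim about them follows from these tests.

## 6. Problem sizes, determinism, degenerate inputs

Test and acceptance runs use the published study dimensions where they are
known (2042 markers in the published per-group sizes and lengths, 178
individuals, 10 linkage groups, five species, 5000 gene pairs per species
pair) and 20 jackknife resamples — enough for a 0.05-resolution stability
score at a few minutes' runtime; the CLI default is 30. All generators
derive independent substreams from one user seed and are bit-reproducible.
Deterministic tie-breaks: lexicographic marker/gene id everywhere a ranking
ties; chain orientation fixed by comparing end-marker ids; bin
representatives by missingness then id. Degenerate inputs have defined
behaviour rather than heuristics: zero-length maps give rf 0, rf = 0.5 is
an error in the Kosambi transform (infinite distance), groups of fewer than
three markers return their input order, fewer than five individuals refuse
outlier flagging, fewer than 50 Ks values refuse peak detection, fewer than
five matches skip isolated-match removal with a warning, and a zero root
height refuses calibration.

## 7. Known limitations

* Map lengths inflate with genotyping error (Section 3); orders and
  groupings are accurate, absolute cM spans are upper bounds.
* No multipoint distance re-estimation, no sex-specific maps or consensus
  merging, no segregation-distortion filter (none is applied by default),
  no QTL machinery.
* The synteny module consumes BLAST tabular output; it does not run BLAST,
  test block significance, or reconstruct ancestral karyotypes.
* NG86 with Jukes-Cantor is a deliberate, testable substitute for
  codon-model ML; rate heterogeneity and relaxed clocks are out of scope,
  and `build_peak_matrix` accepts externally computed peaks for users who
  prefer codeml-derived Ks.
* The Ks simulator draws independent lognormal pairs; it does not emulate
  alignment error, GC effects, or the continuous paralog background of
  real genomes.
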