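---
title: "Methods: variant classification and HRM genotyping in an allotetraploid amplicon panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant classification and HRM genotyping in an allotetraploid amplicon panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cultivated peanut is an allotetraploid (AABB) whose two subgenomes descend
from the diploids *Arachis duranensis* (A) and *A. ipaensis* (B). A PCR
amplicon from the tetraploid usually co-amplifies both subgenome copies of a
locus, and sometimes paralogous duplicates within one genome, so a Sanger
consensus is a *superposition* of 1-4 template sequences. A variable position
can therefore be three very different things:

* **SNP** — a homologous variant segregating among varieties at one position
  of one subgenome; the only class usable as a genetic marker.
* **HSV** — a homoeologous sequence variant: a fixed difference between the A
  and B subgenomes of a single genotype.
* **PSV** — a paralogous sequence variant between duplicated copies within
  one genome.

HSVs and PSVs are roughly 10-100 times denser than SNPs in this system;
mistaking them for SNPs is the dominant false-discovery mode of polyploid
marker development. The package implements the progenitor-guided
discrimination strategy: sequence the same amplicon in both diploid
progenitors and in a variety panel, infer which copies survive in the
tetraploid, and classify every variable column.

## Observation model

We abstract a Sanger trace with double peaks as an IUPAC consensus: at each
position the observed letter encodes the *set* of bases present across the
co-amplified copies (`observe_amplicon()`). The model is noiseless and
substitution-only, so alignment columns map 1:1 to reference coordinates; a
minimum secondary-peak threshold, base quality, and indels are not modeled.
`align_global()` (ambiguity-aware Needleman-Wunsch/Gotoh, deterministic
diagonal-up-left tie-break) exists for externally supplied sequences with
indels; two letters match when their decomposed base sets intersect.

## Copy composition

`infer_copy_composition()` enumerates the copy sets expressible from the
three observations — both genomes, one genome only, a within-genome paralog
pair (only when the corresponding progenitor amplicon is heterozygous: in a
diploid inbred, amplicon heterozygosity itself implies co-amplified
paralogs), or both genomes plus a paralog pair — predicts the tetraploid
consensus for each by per-position superposition, and keeps the hypothesis
with fewest mismatches. Ties break in the fixed order AB, A-only, B-only,
A-paralogs, B-paralogs, AB-paralogs, reflecting that most loci retain both
genomes.

Two identifiability facts shaped the design:

* **Elimination acts on sequence units.** If one member of a paralog pair
  could be lost alone, the resulting observation would be exactly identical
  to other compositions (e.g. retaining `{A2, B}` is indistinguishable from
  `{A1, A2, B}` whenever B carries the ancestral base at the PSV columns).
  No observation-space classifier can sort such cases, so the simulator
  eliminates a subgenome's multi-copy unit as a whole — which is also how
  sequence elimination after polyploidisation is usually described: the
  multi-copy sequence is lost, and more readily than single-copy sequence.
* **Panel-variable columns are masked during composition scoring.** A SNP
  near 50% frequency makes the majority variety pattern ambiguous; judging a
  composition on segregating columns would let a SNP veto the correct
  hypothesis. The panel driver infers composition from the per-column modal
  variety letter over panel-invariant columns only (ties break toward the
  smaller base set, then alphabetically).

## Site classification

Given an explained composition, `classify_sites()` works column by column:
a fixed single-base difference between retained A and B is an HSV; a
heterozygous progenitor column whose paralog pair is retained and uniform
across varieties is a PSV; a column on which varieties differ among
themselves is a SNP if the variation is attributable to one copy while all
other copies' contribution stays fixed. Columns uniform across varieties but
different from the progenitor prediction are reported as fixed differences,
not SNPs (they do not segregate in the panel); triallelic or otherwise
unexplainable columns are flagged unresolvable rather than forced into a
class.

Two honest limitations of column-wise attribution:

* When both progenitors carry the *same* base at a SNP column (the generic
  case for a recent mutation), the carrying subgenome cannot be identified
  from the consensus; such SNPs get `subgenome = NA`. In practice subgenome
  anchoring comes from neighboring HSVs/PSVs (as in subgenome-specific
  primer design), not from the SNP column itself.
* A SNP whose minor allele coincides with the homoeologous base at an HSV
  column (the CT x CC pattern that breaks allelic segregation in crosses) is
  detected and flagged `hsv_coincident`; the simulator can plant such sites
  (`hsv_coincident_frac`, default 0) to exercise the case.

## The synthetic panel

The generator's defaults state the data regime the method targets: 600 bp
amplicons; HSV rate 1/50 bp (the observed range being roughly 1/32 to
1/77 bp); PSV rate 1/50 bp (range 1/27 to 1/87) on the ~20% of loci per
genome carrying a duplicate (progenitor amplicon heterozygosity was 12-25%);
SNP rate 1/1500 bp (range about 1/1000 to 1/2600); a 96-variety panel; 20%
of loci unsequenceable (multi-fragment/indel amplicons, matching ~80%
sequencing success); elimination probabilities 0.05/0.15 for
single-copy/multi-copy units (the paper reports the direction of this
inequality, not rates). Minor-allele frequencies are uniform on (0.01, 0.5];
ancestral base composition is uniform. Mutations are substitutions only.
What a green test therefore establishes: correctness of the inference logic
under the stated densities at zero read noise — not robustness to trace
noise, indels, primer bias, or population structure, none of which the
generator emulates.

RIL simulation is deliberately minimal: unlinked markers, one parental
allele per line, residual heterozygosity (1/2)^selfing-generations
(default 6), optional missing calls. It exists to validate the 1:1
segregation test, not to build maps.

## Marker statistics

PIC = 1 - sum(p_i^2). The denominator convention matters: allele frequencies
use the full panel size (96), not the number of successfully genotyped
varieties. This is the only convention that reproduces the published
allele-count tables whose counts sum below 96 (e.g. counts 71+15 = 86 give
the printed 0.429 with /96 but 0.288 with /86); the alternative is available
behind `denominator = "genotyped"`. One published row (GSS-10) is internally
inconsistent under any convention — its counts imply 0.342, its printed PIC
is 0.234 — and the recomputed value is also what makes the printed GSS group
mean (0.249) reproducible; the package reports the computed value and the
mismatch. LD r-squared is the squared Pearson correlation of 0/1 calls over
pairwise-complete varieties (equal to D^2/(p1 p2 q1 q2) for phase-known
inbreds); fragments whose SNPs are fully linked (r^2 = 1, tolerance 1e-9,
transitive closure) collapse to their first SNP by position. Segregation
distortion uses the df = 1 goodness-of-fit chi-square at alpha = 0.05
(neither stated in the source; both conventional).

## HRM engine

Each duplex species melts as a two-state logistic: F(T) =
sum w_d logistic((Tm_d - T)/width) on the 72-90 degC grid in 0.1 degC steps
(181 points). Tm comes from the standard GC/length formula 81.5 +
0.41 GC% - 675/L minus a configurable `salt_offset` (default 12 degC,
standing in for buffer/dye effects so that 80-250 bp products melt inside
the grid). A heterozygote contributes two homoduplexes and two
heteroduplexes at weight 1/4 each, heteroduplex Tm lowered by
`delta` = 1 degC per mismatch; `width` defaults to 0.8 degC. Under this
model a GC-neutral substitution (A/T or C/G swap) produces no Tm shift — a
real limitation of GC-composition Tm prediction, which is why default
synthetic marker amplicons carry transition SNPs and why the amplicon
default is 80 bp: one substitution changes 1/80 of the GC content, the
largest shift the nested-product size range allows. This mirrors actual HRM
assay design practice (shortest possible amplicons).

Normalization fits per-curve baselines on 73-75 and 88-90 degC windows and
rescales to 100%-0%, then subtracts a reference curve. The classic *linear*
baseline is the default, but it is statistically unsound under heavy
per-point noise: a slope estimated on a 2 degC window and extrapolated
across the 18 degC grid amplifies noise roughly a hundredfold. Because the
two-state model's plateaus are flat, `baseline = "constant"` (window means)
is exact for synthetic curves and is what the genotyping driver uses,
together with lowess smoothing of the difference curves (span 0.15).

Clustering is agglomerative (complete linkage) on the maximum-absolute curve
distance, cut at a threshold (default 5 normalized-fluorescence units) or at
a known group count k — for a validated biallelic marker in a homozygous
inbred panel, two groups are expected a priori. The cut is then polished by
centroid reassignment (Lloyd iterations): pairwise distances between noisy
curves overlap long before the cluster *mean* curves do, so the polish is
what turns a marginal pairwise separation into per-sample assignments; at
zero noise it is a no-op. The amplification QC filter drops samples whose
half-maximum crossing cycle deviates from the panel median by more than a
configurable window (default 5 cycles; no fidelity to any instrument's
criterion is claimed).

## Numerical and interface choices

Coordinates are 0-based half-open internally, 1-based in all reports.
Variant classes collapse strand-symmetrically to C/T(G/A), A/C(T/G),
A/T(T/A), C/G(G/C). Reports round PIC to 3 decimals, SNP densities to whole
bp, HSV/PSV densities to one decimal. Run configs are JSON (no YAML parser
in the supported dependency set); every pipeline stage derives its seed
deterministically from the global seed, and reruns of the same config are
byte-identical. Residual variety heterozygosity is not modeled (varieties
are treated as inbred); `selfing_generations` is exposed for RILs instead of
guessing a value.
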