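---
title: "Models and methods behind crisprkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crisprkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprkit)
```

# Scope and scientific setting

crisprkit packages the computational side of a CRISPR/Cas9 knockout study
of a plant gene, modelled on the rice Aux/IAA auxin-repressor family.
Aux/IAA proteins carry four conserved domains: Domain I (repression),
Domain II (the TIR1/AFB-recognised degron with the GWPPV core), and
Domains III/IV (dimerisation). Edits placed just downstream of the degron
can remove a few residues (in-frame deletions) or shift the reading frame
(single-base insertions); a frameshift predicted to truncate Domains
III/IV can nevertheless be neutralised if the transcript adopts an
alternative 5' splice donor whose exon-shortening shift restores the
frame. The package implements each analysis in that story as a tested,
reusable operation, together with generators that synthesise inputs with
the statistical structure the analyses assume.

# Diversity statistics

`nucleotide_diversity()` averages, over all unordered sample pairs, the
per-site difference proportion; sites carrying a gap or N in either
member of a pair are excluded for that pair only (*pairwise deletion*).
With `corrected = TRUE` each pairwise proportion is Jukes–Cantor
corrected, d = −(3/4)·ln(1 − 4p/3), before averaging, so the corrected
value always dominates the raw one, with equality exactly at zero. The
correction saturates at p = 3/4 and raises a classed error there rather
than returning an arbitrary large number.

`tajimas_d()` uses *complete deletion* — any column with a gap or N in
any sample is removed before both S and the mean pairwise difference
count k̂ are taken — and the uncorrected k̂, with the standard
normalising constants a₁, a₂, b₁, b₂, c₁, c₂, e₁, e₂ for the sample
size. The corrected/uncorrected and pairwise/complete-deletion split
follows the common default behaviour of the classic command-line tools
for these statistics: multiple-hit correction is applied where a
distance is reported (π, Ka, Ks), and the D statistic is left on its
original definition. S = 0 returns `NA` (the statistic is undefined),
never 0.

`nei_gojobori()` counts potential synonymous sites per codon as the
fraction of the nine single-base neighbours preserving the amino acid;
mutations creating stop codons count as nonsynonymous in the site
totals, so every sense codon contributes exactly S + N = 3 sites (a
test pins this for all 61). Observed differences at codons differing at
more than one position are averaged with equal weight over all
substitution orderings whose intermediates are not stop codons; if every
ordering is blocked (possible only for rare codon pairs), all orderings
are used. The proportions pS and pN are then Jukes–Cantor corrected.
For alignment-level summaries (`domain_scan()`), Ka and Ks are means
over all sample pairs and the ratio is the ratio of those means; domain
intervals are trimmed to whole codons of the alignment-wide frame
before codon-based counting. The study this package is modelled on did
not state whether its family-wide Ka/Ks was mean-pairwise or
versus-reference; mean-pairwise is the package's documented default
rather than a claim about the original computation.

`k2p_distance()` evaluates K = −½ln(1−2P−Q) − ¼ln(1−2Q) on
pairwise-valid sites and raises a saturation error when a logarithm
argument is non-positive. `neighbor_joining()` is a from-scratch
Saitou–Nei agglomeration because its contract is stricter than what
generic implementations guarantee: ties in the Q criterion are broken
deterministically toward the lexicographically smallest pair of cluster
labels (a cluster is labelled by its smallest leaf), and a negative
branch length is clamped to zero with the deficit moved to its sibling
so path lengths are preserved. On additive matrices it provably recovers
the generating topology; tests verify this on random 5-leaf trees and
cross-check against an independent implementation.

# Edit inference and protein consequences

`infer_edit()` reduces a wild-type/mutant sequence pair to one edit
block by claiming the longest common *suffix* first and then as much
prefix as remains. Claiming the suffix first places an ambiguous indel
(one that could sit at several equivalent positions, as in a repeat) at
its leftmost position — the VCF normalization convention — so
downstream coordinates are stable and comparable. Pairs that differ in
one contiguous block with both alleles non-empty and unequal lengths
are classed `complex`; identical inputs are an error rather than a
zero-length edit.

`classify_consequence()` works at the protein level with an anchored
diff: longest common prefix claimed first, then suffix. Prefix-first
resolution matters when the flanking protein sequence is repetitive —
the removed block is then reported at the first divergent residue. A
CDS length change not divisible by 3 is a frameshift regardless of the
protein diff. A premature stop is recorded only when translation halts
before the final codon of the mutant CDS itself, so a clean in-frame
deletion (which still ends at its own last codon) is not flagged. A
domain is reported lost when fewer than half of its wild-type residues
survive; the 50% rule is this package's operationalisation of
"domain deleted by frameshift", which the motivating experiment stated
without a criterion.

The packaged `table2_fixture()` embeds the printed 47-nt target region
in a synthetic single-exon gene at a codon phase chosen so the 3-bp
deletion removes one complete GCG codon — the alanine the experiment
describes — and the 39-bp deletion removes 13 codons. The downstream
filler encodes stop codons in both shifted frames within ~20 codons so
a +1 insertion yields a premature stop upstream of the fixture's
Domains III/IV. The real locus coordinates are not reproduced; only the
frame relationships carry scientific content, and the fixture is
labelled synthetic throughout.

# Splice junctions and frame restoration

`extract_junctions()` delegates SAM parsing to Rsamtools and CIGAR
arithmetic to GenomicAlignments: each N operation's skipped interval is
one junction, reported as first/last intronic base, 1-based inclusive
(the coordinate style junction tables are usually printed in);
internally all interval arithmetic is 0-based half-open and converted
only at the I/O boundary. Counts aggregate per sample, so results are
invariant to read order and to splitting input across files. The
default minimum junction support is 1 read (configurable in the CLI):
the analyses here operate on deeply sequenced amplicons where even rare
junctions are real observations, and thresholding is left explicit.

`junction_proportion()` divides a junction's support by the total
support of all junctions overlapping a locus, by default the annotated
intron's interval. The denominator is a genuine modelling choice — the
motivating study never defines one — and restricting it to the
annotated intron's overlap keeps proportions comparable between samples
whose distal junction repertoires differ.

`enumerate_rescue_junctions()` encodes frame restoration as a residue
class: a donor shift s (positive = more exon removed) after an edit of
net length change ℓ restores the frame iff (ℓ − s) ≡ 0 (mod 3).
Without genomic sequence the enumeration is arithmetic-only and flagged
`unverified`; with sequence, the shifted intron must begin GT and end
AG and the respliced CDS must reach its annotated stop without a
premature one, and the predicted protein is returned. Property tests
check the residue-class condition against brute-force
splice-then-translate across insertion lengths 0–5 and shifts 1–30.
The two observed novel junctions of the motivating experiment lie 11 bp
and 13 bp into the exon from the annotated donor; the printed genomic
start coordinates pair slightly inconsistently with those magnitudes
(the more distal start is attached to the smaller shift), so the
package treats the shift magnitudes, not the absolute coordinates, as
the meaningful quantities. Whether the 11-bp junction participates in
rescuing the second annotated isoform is not decidable from printed
information and is left out of scope.

`build_mosaic_transcript()` joins the coding exonic sequence of one
isoform 5' of a breakpoint junction to another isoform's 3' of it and
translates — the predicted "mosaic" product when a novel junction
bridges two isoforms. `delta_delta_ct()` averages replicate Ct values
arithmetically (triplicate reactions, no aggregation rule stated in the
protocols this models; the arithmetic mean of Ct is the conventional
choice) and reports 2^−ΔΔCt against a reference gene and calibrator
sample.

# The off-target screen

The effective-mutation filter keeps a variant iff it is (i) homozygous
for the alternate allele, (ii) different from the wild-type call at the
same site, (iii) supported by strictly more than 3 reads, (iv) at
mapping quality ≥ 50, and (v) at effective matched degree ≥ 0.90,
where the effective matched degree of a read is matched alignment
length over whole read length (soft clips count in the denominator;
`emd_from_cigar()` computes it from CIGAR strings). Mapping quality is
taken as the variant-site aggregate from the VCF record — the
per-read reading is also defensible, and the threshold argument
accepts either convention since both arrive as a number per record.
Homozygosity comes from the genotype field; mutant sites with no
wild-type call cannot satisfy (ii) and are excluded with a warning
rather than silently assumed reference. The filter is monotone in
every threshold (tested). Region annotation uses the precedence
exon > UTR > intron > intergenic, with "exon" meaning coding sequence;
for exonic SNVs the amino-acid effect is read off the codon table on
either strand. The by-eye genome-browser inspection of candidate gene
families that such studies describe has no algorithmic counterpart;
`screen_gene_list()` substitutes the same filter restricted to each
listed gene's span and reports per-gene verdicts.

# Synthetic data: what it emulates and what it does not

`simulate_coalescent_alignment()` implements Hudson's neutral
coalescent: exponential waiting times with rate k(k−1)/2, infinite
sites, mutation count Poisson(θL/2) for total branch length L in units
of 2N generations, so E[S] = θ·a₁ and E[D] = 0. Defaults (n = 20,
θ = 5, 999 bp) give desk-scale replicates: the distributional
acceptance checks use 200 replicates, which runs in a few seconds and
bounds the Monte-Carlo error on mean D well inside the ±0.3 band used.
No recombination or demography is modelled — appropriate at
single-gene CDS scale for a null calibration, but it means the
generator cannot emulate linkage patterns or population structure of
real panels, and passing tests say nothing about those. Mutations are
placed by per-site weights, so a domain with rate multiplier r has
elevated expected density without disturbing the genealogy.

`simulate_gene_with_reads()` writes error-free junction-spanning reads
drawn multinomially from a declared junction mixture over the packaged
rescue gene. Read errors, coverage heterogeneity and mapping ambiguity
are deliberately absent (alignment and calling are out of scope), so
junction-count recovery is exact up to multinomial sampling; tests
check recovered proportions against binomial confidence intervals, not
against aligner behaviour. `simulate_variant_table()` plants true edits
with safety margins above every filter threshold (reads ≥ 5, MQ ≥ 55,
EMD ≥ 0.95) and noise records each violating exactly one named
threshold, with the truth recorded in a sidecar; downstream tests read
truth only from the sidecar. The rescue gene's exon bodies are GCA
repeats so that no reading frame of exonic sequence can form a stop
codon except the annotated terminal one — this makes the frame-
restoration residue class exactly equivalent to splice-then-translate
on this gene, which is the property the tests pin; real exons can of
course contain stops in shifted frames, which is why
`enumerate_rescue_junctions()` performs the premature-stop check
against the actual sequence whenever one is supplied.

# Numerical and interface conventions

- Coordinates are 1-based inclusive in every file format and reported
  table; 0-based half-open arithmetic is internal only.
- Degenerate inputs are classed conditions, not sentinel numbers:
  saturation of JC/K2P, S = 0 for Tajima's D, zero junction coverage,
  identical sequences for edit inference.
- N bases are missing data (excluded pairwise), never a fifth state;
  codons containing N translate to X.
- π is reported per site; the per-mille display used in some
  publication figures is a formatting option (`permille`), factor 1000.
- All generators take explicit integer seeds and are byte-reproducible.

# Known limitations

Alignment construction (MUSCLE/MAFFT), read mapping, variant calling
and transcript assembly are consumed, not performed. The
population-scale results of the motivating study (hundreds of genomes,
genome-wide variant catalogues, junction fold-changes between real
genotypes) depend on raw data that is not published; the package
substitutes property-based checks under its own generators for those
quantities, and the acceptance artefacts recompute only the printed,
desk-scale numbers. The neighbor-joining tree carries no bootstrap
support; model selection beyond K2P is out of scope.
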