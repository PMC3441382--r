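---
title: "Methods: annotating HMW glutenin subunit genes with glutannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating HMW glutenin subunit genes with glutannot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glutannot)
```

## The biology being modelled

High molecular weight glutenin subunits (HMW-GSs) are seed storage proteins
of wheat and its wild relatives, encoded by tightly linked x-type and
y-type genes at the *Glu-1* loci. A mature subunit has a stereotyped
architecture: a ~21-residue secretory signal peptide, a conserved
N-terminal domain (~81–89 residues in x-type, ~104 in y-type), a central
low-complexity repetitive domain assembled from tripeptide, hexapeptide and
nonapeptide motifs, and a conserved 42-residue C-terminal domain. Two
features matter for dough quality and for evolution: the cysteine
complement (x-type typically 3/0/1 cysteines across the three mature
domains, y-type 5/1/1), and the size of the repetitive domain, which grows
by tandem duplication of repeat blocks — the signature of unequal
crossover. `glutannot` turns each step of the structural characterization
of such genes into tested, deterministic code: translation, anatomy, repeat
grammar, insertion detection, promoter element annotation, and two
phylogeny views (neighbor-joining tree and median-joining network).

## Translation and ORF accounting

`translate_orf()` applies the standard genetic code, stops at the first
in-frame stop, and treats one or two stop codons at the very end of the ORF
(the tandem `TGATAG` configuration typical of *Glu-1* genes) as trailing
stops: consumed and counted, never translated. A stop followed by sense
codons flags the record as pseudogene-like; translation is returned up to
the stop with a warning status. Codons containing `N` translate to `X`.
Because published ORF lengths and residue counts for these genes do not
reconcile under a single formula, reports always carry both the raw codon
count (including trailing stops) and the mature residue length rather than
deriving one from the other.

## Subunit anatomy

The mature subunit starts at the conserved `EGEAS` pentapeptide;
`strip_signal_peptide()` takes the leftmost occurrence within the first 40
residues as the boundary (no SignalP-style prediction — the anchor is
diagnostic in this family). Typing uses residue 6 of the mature sequence
(`G`/`E` = x, `R`/`K` = y) with the N-terminal domain length as fallback
(75–95 → x, 96–115 → y) when residue 6 is uninformative.

`partition_domains()` fixes the C-terminal domain at the final 42 residues
— constant across all published alleles — and defines the repetitive domain
as starting at the first position from which at least **three consecutive
lexicon motifs** match, ending at the C-terminal boundary. The
three-in-a-row rule is our operationalization (the literature reports
boundaries, not algorithms); it is robust to isolated spurious motif hits
inside the N-terminal domain. If no onset exists the body is reported as
N-terminal with an empty repetitive span and a warning, never an error.
`cysteine_census()` counts per-domain cysteines and flags conformance with
the known patterns, treating the x-type variant with one extra
repetitive-domain cysteine (the 1Dx5 pattern) as known rather than deviant.
Two published domain-length rows (for 1Dx2.1 and the *1Ay (Ta-e3)* variant)
are internally inconsistent (the domains do not sum to the printed total);
they are documented here and excluded from any numeric check.

## Repeat grammar

The repetitive domain is parsed against a motif lexicon; the default is
the canonical glutenin set — tripeptide `GQQ` (≤1 mismatch), hexapeptide
`PGQGQQ` (≤2), nonapeptide `GYYPTSPQQ` and variant `GYYPTSLQQ` (≤2) — and
is user-overridable via a TSV config (`read_lexicon()`), since exact motif
consensus choices can matter when reproducing counts on real accessions.
`segment_repeats()` is an exact dynamic program over positions minimizing,
lexicographically, (1) unassigned residues, then (2) total Hamming
mismatches; at equal cost longer motifs are preferred earlier in the
sequence, making the parse deterministic. Mismatch is Hamming distance
only: indels inside a motif token are not modelled (they fall into
unassigned spans), which keeps the DP linear-time per lexicon entry and
reproducible. The test suite checks the DP optimum against an exhaustive
enumeration of all tilings on 200 random domains of up to 30 residues, and
the length identity `3·tri + 6·hexa + 9·nona + unassigned = length` is
asserted on every segmentation the package ever produces.

## Insertion blocks and tandem-duplication evidence

`detect_insertions()` globally aligns a query subunit to a same-type
reference (Needleman–Wunsch with affine gaps via Biostrings; match +2,
mismatch −1, gap open −10, gap extend −0.2 — deliberately long-gap-friendly
so a 100+-residue duplication aligns as one block rather than scattered
gaps) and reports every maximal run of reference gaps of at least
`min_block = 30` residues. The threshold separates block duplications from
single-repeat-scale changes, which surface as mismatches or short gaps
instead; both cutoff and scores are `run_config()` parameters.

Gap placement for a tandem duplication is intrinsically ambiguous: the
block can slide while its first/last characters match the flanking
sequence, at identical alignment score. Reported spans are therefore
canonicalized: among all score-equivalent placements, the one whose
fragment parses best against the motif lexicon (fewest unassigned residues,
then fewest mismatches, ties leftmost) is chosen. For duplications at
repeat-token boundaries this recovers the copy exactly, and it is the
reason detected block censuses match planted compositions in the tests.

`verify_tandem_duplication()` compares the block to the equal-length
windows immediately upstream and downstream (within the repetitive domain),
reporting the best flank, percent identity over alignment columns and the
variant positions. The adjacent-window definition is our choice of
comparison; the source material shows such comparisons graphically without
a numeric rule. The empirical null for this statistic — 100 shuffles of a
block against its flank — sits near 42% identity on the Q/G-rich glutenin
alphabet (global alignment inflates raw positional identity), far below a
true copy's ~100%; the tests freeze bounds derived from that null.

## Promoter element annotation

Six conserved cis-regulatory elements are scanned, in their canonical
5′→3′ order: E motif `TGTAACCC`, N motif `TGAGTCAT`, partial enhancer
`TTTGCAAA`, the 38-bp complete enhancer, TATA box `CTATAAAAG` and the
transcription start motif `TTATCA`. Mismatch caps default to 2 for the
8–9-bp elements, 3 for the enhancer and 1 for the 6-bp start motif: the
published allele table shows up to 2 substitutions in short elements and 3
in the enhancer, so stricter caps would misclassify real alleles as
deleted. The enhancer additionally admits a single 1-bp deletion (a gapped
window of length 37), reported as a deletion-containing hit rather than
element loss, as seen in the 1Bx7 promoter. Only the given strand is
searched (promoters are supplied in gene orientation).

One design decision deserves emphasis: the partial enhancer's consensus is
a verbatim substring of the complete enhancer, so a naive left-to-right
scan whose partial-enhancer search ran first would capture the enhancer's
core and destroy the enhancer call whenever the true partial enhancer is
deleted. Elements are therefore anchored longest-consensus-first (ties by
canonical order), each constrained not to overlap already-anchored
elements and to respect the canonical element order; results are reported
in 5′→3′ order. An element with no qualifying window is reported
`deleted`.

## Phylogeny of the conserved region

The phylogenetically informative region is the 5′ promoter plus the CDS
for the signal peptide and N-terminal domain, concatenated in that order
(`extract_phylo_region()`); the repetitive domain is excluded as too labile
to align. Distances are p-distances with pairwise deletion — gaps treated
as missing data per pair. The original analysis used MEGA's Maximum
Composite Likelihood model; we use the p-distance instead and treat the
substitution-model choice as immaterial for these highly similar sequences
— a claim the test suite itself exercises by showing topology recovery on
synthetic families. Alignment is accepted pre-aligned (the supported path;
the synthetic generator emits gap-free alignments); ClustalW-equivalent
multiple alignment is out of scope.

Neighbor joining uses the Saitou–Nei algorithm via `ape::nj` on a
lexicographically ordered matrix (deterministic output); negative branch
lengths are clamped to zero with the remainder transferred to an adjacent
branch, so displayed lengths stay non-negative without inflating the tree
length. Bootstrap support resamples alignment columns with replacement
under a caller-supplied seed (mandatory, recorded on the output); support
is the percentage of replicate NJ trees containing each internal
bipartition.

The median-joining network first condenses identical haplotypes and drops
invariant sites, then computes a minimum-spanning network (Kruskal by
increasing weighted distance, keeping every feasible link at each distance
level; `epsilon` widens the feasible levels, default 0). Median (Steiner)
vectors — per-site majorities of node triples adjacent in the network —
are added one at a time whenever they strictly shorten the network, ties
broken lexicographically; obsolete medians are pruned afterwards. This is
a deterministic Steiner-improvement variant of median joining; with
`epsilon = 0` the result contains a minimum-spanning network of its final
node set, every observed haplotype is retained, and on the package's hand
cases it matches the enumerated minimum networks. The conventional uniform
site weight of 10 is the default and is recorded, with epsilon, in the
output metadata.

## The synthetic-data generator

`generate_subunit()` emits genes whose translation has the exact canonical
architecture: fixed 21-residue signal peptide, per-type N-terminal domain
(86 or 104 residues, cysteines planted to the canonical counts), a
repetitive domain concatenated from lexicon motifs (defaults sized to a
typical subunit: x ≈ 690, y ≈ 480 repetitive residues), and a fixed
42-residue C-terminal with one cysteine; the ORF ends in the tandem stops
`TGATAG`. Codon choice is uniform over synonyms — no codon-usage model, as
no tested property depends on one. Everything derives from the seeded RNG,
so output is byte-identical per seed.

Ground-truth bookkeeping shapes three further choices. First, the y-type
repetitive-domain cysteine is planted as a single substitution inside one
motif token (within its mismatch cap), so the motif parse and census are
unaffected. Second, the region preceding a planted duplication ends with
the `GYYPTSLQQ` variant while block nonapeptides use `GYYPTSPQQ`; since
every motif ends in `QQ`, this is what makes the duplication's upstream
boundary unambiguous and lets the canonicalized detector recover the
planted span exactly. Third, `sub_rate` substitutions are applied to the
shared pre-duplication sequence — the gene and its returned reference
mutate at identical sites — modelling an allele pair's joint divergence
from the motif consensus. The copies of a planted duplication therefore
stay identical unless `n_subs` variants are requested, and those always
include the copy's final residue so the variant copy is uniquely anchored
in the alignment.

`generate_promoter()` plants the elements at seeded offsets in random
background and then deterministically disrupts any background window that
would tie or beat a planted element under the scanner — by chance an 8-mer
within 2 mismatches occurs about 4 times per 900 bp, so without this
scrubbing planted-offset recovery could not be guaranteed. An element
planted with more substitutions than its cap is expected to scan as
`deleted` (the threshold boundary case). `generate_family()` evolves a
seeded root sequence along a given tree with a fixed per-branch
substitution count placed at globally distinct sites while any remain, so
pairwise Hamming distances are additive along the tree — which is what
makes exact NJ topology recovery a fair test.

What the generator does **not** emulate: codon usage bias, indel mutations,
repeat-unit turnover within the repetitive domain, promoter microsatellite
variation, or recombination. Passing tests on synthetic data therefore
demonstrate algorithmic correctness under the stated generative model, not
performance on the full messiness of real accessions; the accession-based
checks in the test suite run only when the user supplies the named GenBank
records as FASTA (they are not redistributed and the package never
downloads).

## Problem sizes and numerical choices

The shipped tests use repetitive domains of a few hundred to ~1000
residues, alignments of 200–500 bp, families of 6 leaves, 100–200 bootstrap
replicates and 200-case property sweeps — sizes chosen so the whole suite
demonstrates each property at full strength while running in well under a
minute per file. The DP and scanner are exact algorithms, so size scaling
changes runtime, not results; bootstrap replicates in production use
default to 1000. Alignment scores inherit single-precision gap arithmetic
from the aligner (differences ~1e-6, covered by test tolerances). All
coordinates in every report are 1-based inclusive, stated in each header;
ties anywhere (DP token choice, element windows, median candidates, NJ
input order) are broken by fixed documented rules so identical inputs give
identical bytes.

## Known limitations

- The default motif lexicon is the canonical one, but exact repeat counts
  on real accessions can depend on lexicon choice; the lexicon is a config
  file precisely so such reproduction can be tuned without code change.
- Signal-peptide detection relies entirely on the `EGEAS` anchor and will
  not strip signal peptides of non-conforming subunits.
- The insertion detector reports blocks relative to a single same-type
  reference; ancestral-state inference over multiple references and
  DNA-level breakpoint reconstruction are out of scope.
- The median-joining implementation targets small haplotype sets (tens of
  sequences); its triple enumeration is quadratic in network degree and is
  not meant for population-scale data.
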