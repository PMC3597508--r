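---
title: "Models and methods: fungal alternative splicing and subfunctionalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: fungal alternative splicing and subfunctionalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedup)
```

## The biological problem

Fungal genomes rarely diversify their proteomes by alternative splicing, but
a handful of genes do it in a deeply conserved way. The ancestral
*SKI7/HBS1* gene of budding yeasts encodes two translation-surveillance
factors from one locus: splicing at a *proximal* 3′ splice site keeps an
alternative coding segment carrying the Ski7-diagnostic motifs S1 and S2 and
yields the long, Ski7-functional protein; splicing at the *distal* site
removes that segment and yields the short, Hbs1-functional protein. After
whole-genome duplication (WGD), the two copies each lost one splice form:
the *HBS1* copy lost the intron by precise excision (the cDNA-recombination
signature), the *SKI7* copy lost exon 1 and gained a new start codon at the
first methionine of motif S1 — subfunctionalization by loss of alternative
splicing. The PP2C phosphatase gene *PTC7* shows the same logic on a
different axis: its spliced mRNA encodes a mitochondrially targeted
phosphatase, its intron-retained mRNA a nuclear-envelope protein whose
transmembrane helix is encoded by the retained intron, and in one post-WGD
lineage the two isoforms survive as two separate genes.

`splicedup` implements the complete comparative pipeline around these
observations: splice-signal modelling, isoform enumeration, ORF-consequence
analysis, motif-complement classification, localization calls, and the
subfunctionalization verdict, plus a synthetic-locus generator that plants
each architecture with known truth so the whole chain is testable offline.

## Splice-signal model

Donor, branch-point and acceptor signals are position weight matrices built
from aligned sites with a per-letter pseudocount (default 0.5) and scored as
log-odds against a uniform 0.25 background in bits. Defaults are the
canonical budding-yeast signals — donor `GTATGT` (with the `GTAAGT`
variant), branch `TACTAAC`, acceptor `TAG`/`CAG` — shipped as overridable
configuration, since they are textbook consensus sequences rather than
matrices fitted to any particular alignment.

Geometry: intron length 40–1000 nt, branch-to-acceptor distance 10–200 nt
(measured from the branch heptamer start to the final G of the intron).
These spans comfortably cover the short introns of *Saccharomycetaceae*
(~100 nt and up) while bounding the search.

Score thresholds are fractions of each PWM's maximal score: donor 0.90,
branch 0.80, acceptor 0.60. The donor and branch cutoffs admit only
consensus-matching sites. This is a deliberate design choice: a uniform
permissive cutoff (e.g. 60% of maximum for all three signals) admits
one-mismatch donors and branch points, which on random sequence produces
several complete spurious donor–branch–acceptor candidates per kilobase —
at that operating point no locus could be said to contain "exactly" its
planted intron, and false-positive measurements on synthetic data would be
meaningless. The acceptor cutoff of 0.60 passes exactly the YAG
trinucleotides, which is the biological rule. All cutoffs are per-signal
configuration on `splice_signal_model()`.

Enumeration reports, for every passing donor, the best-scoring compatible
branch point (ties broken leftmost, for determinism) and *all* acceptors
satisfying the geometry — this is what makes alternative 3′ splice sites
first-class citizens rather than annotation afterthoughts. Overlapping
candidates are resolved at isoform-assembly time by a 5′→3′ greedy chain,
mirroring co-transcriptional commitment. The enumeration is verified
against an exhaustive GT..AG brute-force oracle on random sequence in the
test suite.

## Isoform engine

Events are enumerated one at a time against the constitutive background
(no combinatorial products), matching the isoform inventories actually
observed in these gene families and keeping output linear in the number of
events:

* **Alternative 3′ splice site** — one isoform per acceptor of an
  alternative intron (`ALT3SS_PROXIMAL`, `ALT3SS_DISTAL`).
* **Retention** — an intron is retention-functional iff its length is a
  multiple of three *and* the retained reading frame is stop-free (the
  *PTC7* rule). Retention isoforms are emitted only when functional; the
  consequence record (frame preservation, stop position) is available for
  every CDS-overlapping intron via `retention_consequence()`.
* **Exon skipping** — annotated skippable exon groups are removed together
  with their flanking introns (the basidiomycete mechanism). The
  alternative "terminal-exon" reading of the basidiomycete data (a
  truncated Ski7-like protein from a mis-annotated intron) is deliberately
  not emitted as a second hypothesis; the event vocabulary stays closed and
  the ambiguity is a documented limitation.
* **Alternative start** — the *Candida*-style short transcript is modelled
  as an unspliced mRNA initiated at the ATG encoding the first residue of
  motif S1, located by scanning the three-frame translation of the
  pre-mRNA.

Translation supports NCBI genetic codes 1 and 12 (the CTG-clade code, CUG =
Ser); codons containing ambiguity codes translate conservatively to `X`.
Molecular weights use average residue masses plus one water, reported in
kDa — appropriate for comparison with gel-based size estimates, which is
how these isoforms are sized in practice. A stop is flagged *premature* when
it lies further from the mRNA 3′ end than the constitutive isoform's stop;
anchoring at the 3′ end makes the flag insensitive to how much 5′ leader an
isoform carries.

## Motif classifier

The Ski7/Hbs1 diagnostic motifs (S1–S3, H1, GTPase G1–G5, and the
structured N-terminal domain NTD) are degenerate consensus patterns scored
as the fraction of fixed positions matched, one best hit per motif,
threshold 0.8. The shipped patterns are **synthetic stand-ins**: they play
the documented *roles* of the published motif maps (S1 begins with Met; G3
carries the catalytically important His at a fixed column) but are not
fitted to any alignment, and they are versioned configuration
(`inst/extdata/motifs_synthetic_default.tsv`), not code. Any real analysis
should replace them with patterns distilled from the user's own alignments.
The optional S1′ variant ships in the config but never enters
classification.

Classification is a pure function of the hit set: Hbs1-type requires H1,
all of G1–G5 and an intact G3 His (the His→Ser/Asn/Asp degeneration seen in
derived Ski7 proteins fails this criterion); Ski7-type requires S1, S2 and
S3; both sets → `DUAL`, neither → `NEITHER`. NTD presence is recorded as
supporting evidence only — in the pre-WGD architecture it is encoded by
exon 1 and present in *both* isoforms, so it cannot discriminate. The
expected along-sequence motif order is a soft check that downgrades
confidence without changing the class, since strict order is implied but
not guaranteed across all lineages.

## Localization

Published analyses of these gene families used external servers (TMHMM,
PSORT) that cannot
be embedded or versioned; this module instead ships transparent heuristics
and labels them as such in all provenance output. Transmembrane calls use
mean Kyte–Doolittle hydropathy in a 19-residue window, threshold 1.6,
merged into helices; the N-terminal flag fires for helices starting within
the first 60 residues. The mitochondrial-targeting score on the first 30
residues is `clamp(0.5 + 0.04 (nRK − nDE) + 0.25 (fSLA − 0.35))` — monotone
in basic residues, acidic residues and Ser/Leu/Ala enrichment, saturating
at the ends of the unit interval. The localization call gives the
transmembrane signal total precedence (N-terminal TM → nuclear envelope,
else MTS ≥ 0.5 → mitochondrial, else other), exactly mirroring the *PTC7*
partition in which the retained-intron isoform carries the TM and reaches
the nuclear envelope even though everything downstream is shared. No
agreement with TMHMM/PSORT numbers is promised, and no cleavage-site or
topology prediction is attempted.

## Subfunctionalization caller

The verdict compares functional *capabilities*, not raw class labels:
`DUAL` expands to {Ski7, Hbs1}. A pair is `SUBFUNCTIONALIZED` when the two
paralogs carry different, proper, non-empty subsets whose union restores
the ancestral capability set; `REDUNDANT` when each paralog retains the
full set; `INCOMPLETE_PARTITION` otherwise; `NOT_COMPARABLE` when the
ancestor does not itself have two distinct isoform classes. Working on
capabilities matters because the ancestral *long* isoform legitimately
carries the complete motif complement (it shares its 3′ exon with the short
isoform) and therefore classifies `DUAL`; requiring literal class-set
equality would miscall the canonical case the model is built for. The two
function axes — motif complement for *SKI7/HBS1*-style cases, localization
for *PTC7*-style cases — are never mixed in one verdict.

Mechanism evidence is sequence-level and alignment-free:

* **Precise intron loss** — the ancestor's exon–exon junction k-mers
  (k = 12 each side) concatenated with zero intervening nucleotides must
  occur in the paralog with at most m mismatches. The default m = 3 is
  chosen against the generator's own study conditions: at 5% per-site
  divergence a 24-nt junction carries 1.2 expected mismatches, so m = 2
  would miss ~12% of true junctions while m = 3 misses ~2.6%; a random
  24-mer match at ≤3 mismatches remains vanishingly unlikely.
* **Exon loss + new start** — the paralog's annotated start must sit within
  d = 3 residues of its S1 motif and no NTD (exon-1) homology may remain
  upstream of the start. NTD presence is used as the homology probe
  precisely because the structured N-terminal domain is the exon-1
  diagnostic; this avoids embedding a full aligner.

## Synthetic data: what it emulates, what it does not

`generate()` plants six architectures: Lachancea-style ALT3SS (one intron,
two acceptors, S1/S2 between them, S3–G5 downstream), Saitoella-style
MULTI_INTRON_ALT3SS (seven introns, the second alternative), Candida-style
ALT_TSS (genetic code 12, internal S1 start inside the intron of the short
splice form), basidiomycete-style EXON_SKIP, PTC7-style RETENTION_PAIR
(3n stop-free intron encoding a poly-Ile TM; MTS immediately after the
splice junction), and POST_WGD_PAIR (an ALT3SS ancestor plus one paralog
with the intron precisely excised and one starting at S1 with a degenerate
G3 His, both at 5% per-site divergence outside motifs and signals).

Layout coordinates are fixed per architecture; only background sequence
varies with the seed, so two seeds give different loci with identical
planted coordinates — a deliberate contract that separates background
effects from architecture recovery. Background is i.i.d. nucleotide
sequence at 40% GC (yeast-like). Coding background uses a
hydrophilic-biased amino-acid alphabet so that planted transmembrane
helices are the only hydrophobic runs, and coding segments inside
branch-to-acceptor windows use a restricted synonymous-codon set that
provably cannot form a TAG/CAG trinucleotide in any frame, so planted
acceptors are the only candidate 3′ splice sites in geometric reach. Each
locus is rejection-sampled until enumeration at default thresholds recovers
exactly the planted candidates (at full signal strength), so downstream
false-positive measurements are meaningful; at reduced signal strength the
point is precisely that recovery degrades, and rejection is skipped.
Divergence in POST_WGD_PAIR is substitution-only, never inside motifs,
splice signals or start/stop codons, and never creating an in-frame stop.

What this generator does **not** emulate — and therefore what passing tests
do not show about real data: codon-usage bias, indels, higher-order
background composition, degenerate real splice sites, motif divergence, EST
or expression evidence, and genes whose architecture departs from the six
templates. Recovery rates on this corpus validate the pipeline's internal
consistency, not its sensitivity on real genomes.

## Numerical and interface choices

* Coordinates are 1-based inclusive throughout (the R/IRanges idiom), so
  GFF3 needs no conversion and `substr()` arithmetic is direct. BED output
  converts to 0-based half-open at the boundary, as the format requires.
* Ambiguity codes are legal input everywhere but score as non-matches in
  signal windows and translate to `X`; they can never create a candidate.
* Ties: branch points by score then leftmost; motif hits leftmost-best;
  both for determinism.
* Degenerate inputs: sequences shorter than a PWM or protein windows
  shorter than the hydropathy window yield empty results with a warning,
  never an error; an empty protein is an error for mass and MTS scoring
  (there is no meaningful value to return).
* All randomness flows from one integer seed (`withr::with_seed`
  internally); analyses themselves are deterministic.
* Problem sizes in the shipped tests and acceptance script — 100 random
  2-kb sequences for the enumeration oracle, the exhaustive ≤12-nt
  retention truth table (87,381 introns), and a 60-locus corpus (10 per
  architecture) — were chosen as the smallest scales at which every
  property is exercised with comfortable statistical headroom.

## Known limitations

* The motif patterns and localization heuristics are stand-ins; real
  studies must supply fitted patterns and may prefer external predictors.
* Only genetic codes 1 and 12 are supported.
* Retention outside the CDS, U12-type introns, NMD efficiency, and
  expression-level inference are out of scope.
* The subfunctionalization caller consumes exactly one ancestor and one
  paralog pair per verdict; genome-wide paralog discovery, synteny and
  phylogenetic dating are out of scope.

## Session info

```{r}
sessionInfo()
```
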