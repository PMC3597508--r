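# splicedup

Comparative analysis of fungal alternative splicing and the
subfunctionalization of duplicated genes, for people studying how one gene
becomes two.

A few fungal genes encode two distinct, functional proteins from one locus.
The ancestral *SKI7/HBS1* gene of budding yeasts does it with alternative
3′ splice sites: splicing at the **proximal** acceptor keeps an alternative
coding segment carrying the Ski7 motifs S1 and S2 (long, Ski7-functional
isoform), splicing at the **distal** acceptor removes it (short,
Hbs1-functional isoform). Related lineages achieve the same two-protein
output by internal start codons (CTG-clade *Candida*), exon skipping
(basidiomycetes) or frame-preserving intron retention (*PTC7*, whose
spliced mRNA encodes a mitochondrial phosphatase and whose retained mRNA a
nuclear-envelope one). After gene duplication each copy can lose one
isoform and keep the other — **subfunctionalization by loss of alternative
splicing** — leaving sequence signatures: precise intron excision in one
paralog, exon-1 loss with a new initiation codon at motif S1 in the other.

`splicedup` implements this entire analysis as composable, tibble-centric R
functions:

| stage | functions |
|---|---|
| splice-signal PWMs and intron enumeration | `splice_signal_model()`, `build_pwm()`, `scan_signal()`, `enumerate_introns()` |
| isoform assembly, translation, ORF consequences | `enumerate_isoforms()`, `splice()`, `retention_consequence()`, `find_alt_start()`, `translate_cds()`, `molecular_weight()` |
| Ski7/Hbs1 motif-complement classification | `ski7_hbs1_motifs()`, `scan_motifs()`, `catalytic_his_ok()`, `classify_isoform()` |
| localization heuristics (PTC7 logic) | `hydropathy_tm()`, `mts_score()`, `localize()` |
| subfunctionalization calling | `call_subfunctionalization()`, `detect_precise_intron_loss()`, `detect_exon_loss_new_start()`, `analyze_wgd_pair()` |
| synthetic loci with ground truth | `architecture_spec()`, `generate()`, `generate_suite()`, `evaluate_suite()` |
| orchestration and I/O | `analyze_gene()`, `read_fasta()`, `read_gff3()`, `write_isoforms()`, `write_report()` |

Fitted objects have `tidy()`/`glance()` methods; `plot_gene_model()` and
`autoplot()` draw gene diagrams and hydropathy profiles. A thin
command-line dispatcher (`inst/scripts/splicedup.R`) exposes the stages as
`scan` / `isoforms` / `classify` / `localize` / `subfun` / `simulate`
subcommands.

The core signal model scores windows by log-odds against a uniform
background: for a PWM with pseudocounted column frequencies `p_bj`,

    score(w) = sum_j log2( p[w_j, j] / 0.25 )

with default geometry 40–1000 nt intron length and a 10–200 nt
branch-to-acceptor window, and per-signal score cutoffs expressed as
fractions of the maximal score (donor 0.90, branch 0.80, acceptor 0.60 —
the acceptor cutoff passes exactly YAG). Retention is functional iff the
intron length is `0 mod 3` and the retained frame is stop-free. Genetic
codes 1 and 12 (CUG = Ser) are supported.

## Worked example

```r
library(splicedup)

sim  <- generate(architecture_spec("ALT3SS", seed = 42))  # Lachancea-style locus
gene <- sim$genes[[1]]
enumerate_introns(gene)
#> # A tibble: 1 x 7
#>   donor_pos donor_score branch_pos branch_score acceptors        n_acceptors alternative
#>       <int>       <dbl>      <int>        <dbl> <list>                 <int> <lgl>
#> 1        94        7.19        124            7 <tibble [2 x 2]>           2 TRUE

tidy(analyze_gene(gene))[, c("event", "length_aa", "mass_kda", "class")]
#> # A tibble: 2 x 4
#>   event           length_aa mass_kda class
#> 1 ALT3SS_PROXIMAL       139     16.5 DUAL
#> 2 ALT3SS_DISTAL          99     11.7 HBS1_LIKE
```

One candidate intron with two acceptors: the proximal splice keeps the
S1/S2 segment and yields the longer protein carrying the full motif
complement (`DUAL`); the distal splice yields the shorter, Hbs1-only
protein. On a duplicated pair:

```r
pair <- generate(architecture_spec("POST_WGD_PAIR", seed = 42))
sf   <- analyze_wgd_pair(pair$genes$ancestor, pair$genes$paralog1, pair$genes$paralog2)
sf
#> <subfun_report> SUBFUNCTIONALIZED (axis: MOTIF_COMPLEMENT)
#>   ancestor isoforms: DUAL, HBS1_LIKE
#>   paralogs: HBS1_LIKE / SKI7_LIKE
tidy(sf)
#> # A tibble: 2 x 5
#>   paralog  precise_intron_loss intron_loss_mismatches exon_loss_new_start s1_offset_aa
#> 1 paralog1 TRUE                                     0 FALSE                         NA
#> 2 paralog2 FALSE                                    9 TRUE                           0
```

The pair is called subfunctionalized, with the intron precisely excised in
the Hbs1-like copy and a new start codon at motif S1 (offset 0 residues) in
the Ski7-like copy — the two mechanism signatures the caller tests for.

The shipped motif patterns are synthetic stand-in consensi
(`inst/extdata/motifs_synthetic_default.tsv`); replace them with patterns
distilled from your own alignments for real analyses. See the methods
vignette (`vignettes/methods.Rmd`) for the models, defaults and
limitations.

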