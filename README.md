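# fluopeer

Design and in-silico verification of fluorescent prime editing reporters, in R.

Prime editing installs precise edits through a Cas9 nickase–reverse
transcriptase fusion guided by a pegRNA, but editing efficiency varies wildly
between pegRNA designs, prime-editor variants and loci, and most pathogenic
variants have only a single nearby NGG PAM. A fluorescent reporter plasmid
solves the optimisation problem empirically: a 45–100 nt genomic window is
cloned between a GFP and a Cherry cassette with a stop codon or frameshift
that blocks Cherry, the same pegRNA that targets the genome edits the
plasmid, and successful editing restores the frame and switches Cherry on.
Editing efficiency is then read out by flow cytometry as the ratio of mean
Cherry to mean GFP intensity over GFP⁺ cells, and reporter-edited
(GFP⁺Cherry⁺) cells can be sorted to enrich genomic editing.

`fluopeer` implements the computational substrate of that workflow for
molecular biologists planning prime- or base-editing experiments:

* **PAM/protospacer enumeration** around an edit for editor profiles with
  flexible PAM recognition (PE2/NGG, NG, SpG/NGN, SpRY/NNN; IUPAC patterns),
  scanning a configurable −10..+4 window on both strands, plus batch
  counting over variant flank tables.
* **pegRNA/epegRNA design** under the published constraints — PBS length
  9–15 nt with ≥ 5 G/C, RTT length 10–20 nt, flap covering the full alt
  allele plus downstream homology — with PE3/PE3b nicking-guide design and
  Golden Gate cloning oligos.
* **Reporter insert design**: window/frame selection, native stop or
  frameshift detection, added 1-nt frameshift disruption inside the
  RTT-rewritten span, six-frame base-editing mode, 16-plasmid PAM variant
  panels, and SalI/Acc65I cloning oligos (`TCGACC…G` / `GTACC…GG`).
* **Deterministic editing simulators** (prime editing: nick → PBS anneal →
  RTT flap → flap resolution; base editing: window conversion; restriction/
  ligation) used to verify every design before it is returned.
* **Quantification**: Cherry/GFP ratio score and enrichment fractions from
  CSV event tables; intended-edit and indel percentages from merged amplicon
  reads within a comparison range R of the nick (R = 70 ⇒ 140 bp of flank);
  Spearman/Pearson rank concordance between conditions.
* **Seeded synthetic fixtures** for all of the above — no downloads needed.

## Worked example

Design a reporter for a 2-bp insertion in a random 200-nt target with the
PAM-less SpRY prime editor:

```r
library(fluopeer)

fx <- gen_random_target(seed = 7, length = 200, gc_fraction = 0.5)
fx$edit
#> <edit> insertion at 100: '' -> 'GA'

sites <- find_spacer_sites(fx$target, fx$edit, editor_profiles("SpRY-PE2"))
head(sites, 2)
#>   strand               spacer pam pam_pattern protospacer_start nick_position
#> 1      + CGTTAGGGTATCCCGATGGG GCG         NNN                84           100
#> 2      - GGGGACGATATCGCCCCATC GGG         NNN               117           101
#>   nick_to_edit pam_offset
#> 1            0          4
#> 2            0          4

pegs <- design_pegrnas(fx$target, fx$edit, sites[1, ])
pegs[[1]]
#> <pegRNA> pegRNA strand +
#>   spacer CGTTAGGGTATCCCGATGGG
#>   PBS ATCGGGATACCC (12 nt, 7 G/C)
#>   RTT ACGATATCGCCCCTC (15 nt)

ins <- design_reporter_insert(fx$target, fx$edit, pegs[[1]])
ins
#> <reporter insert> window 63-122 (+), frame offset 2, disruption native_frameshift
#>   pre  (58 nt): CCGGGGGCACTCGGCAAATCGTTAGGGTATCCCGATGGGGCGATATCGTCCCCATACG
#>   post (60 nt): CCGGGGGCACTCGGCAAATCGTTAGGGTATCCCGATGAGGGGCGATATCGTCCCCATACG
```

The 2-bp insertion is itself a frameshift, so the unmodified window is
cloned (disruption `native_frameshift`): the 58-nt pre-edit insert breaks
the GFP–insert–Cherry frame, the 60-nt post-edit insert restores it. The
design is verified by simulated translation and simulated prime editing:

```r
chk <- verify_reporter(ins)
c(pre = chk$pre$cherry_expressed, post = chk$post$cherry_expressed)
#>   pre  post
#> FALSE  TRUE

sim <- simulate_prime_edit(ins$pre_edit_seq, pegs[[1]])
identical(unclass(sim$edited_seq), ins$post_edit_seq)
#> [1] TRUE

ins$oligos$top
#> [1] "TCGACCCCGGGGGCACTCGGCAAATCGTTAGGGTATCCCGATGGGGCGATATCGTCCCCATACGG"
```

The oligo pair carries the SalI/Acc65I overhangs; ligating it into the cut
vector (see `simulate_digest_ligate()`) regenerates both `GTCGAC` and
`GGTACC` junctions.

On the quantification side, planted fractions come back exactly from the
seeded read generator:

```r
wt <- gen_random_target(99, 150, 0.5)$target
ed <- apply_edit(wt, edit_spec("substitution", 80, substr(wt, 80, 80), "A"))
fx <- gen_amplicon_reads(wt, ed, seed = 7, n = 1000, frac_edited = 0.3,
                         frac_indel = 0.1, nick_position = 75)
res <- classify_amplicon_reads(fx$reads, wt, ed, read_class_config(30, 0, 75))
c(res$pe_efficiency_pct, res$indel_pct)
#> [1] 30 10
```

A thin command-line wrapper over the same functions is installed at
`<library>/fluopeer/cli/fluopeer.R` (`scan-pam`, `design-pegrna`,
`design-reporter`, `simulate`, `quant-facs`, `quant-reads`, `rank`).

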