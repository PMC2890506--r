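# PolyPrime

Genome-specific PCR primer design for homoeologous genes in
allopolyploids.

In an allopolyploid such as bread wheat, a gene of interest exists as
homoeologous copies on the A, B and D subgenomes that are >95% identical
in exons but only ~65–85% identical in introns. PolyPrime designs primer
pairs that amplify exactly one subgenome's copy: it finds alignment
columns where the target copy differs from *every* other copy, anchors
the primer 3' terminus on such a site, fits the primer into a
59–61 °C nearest-neighbor melting-temperature window by editing only the
5' end, and verifies specificity with a mismatch-position-aware
in-silico PCR model in which a 3'-terminal mismatch blocks amplification
(class NONE), an internal mismatch at positions 2–5 from the 3' end
gives a faint product (WEAK, disqualifying), and more distal mismatches
are tolerated (STRONG). A pair is genome-specific iff it yields exactly
one STRONG product on its target and no STRONG/WEAK product on any
homoeolog. Selected pairs are tiled so their amplicons (preferably
800–1500 bp, overlapping 80–100 bp) cover the gene, with coverage
reported as the union of amplicon intervals over the gene length.
The package also genotypes deletion-based null alleles from the
presence/absence pattern of diagnostic pairs, and ships a seeded
simulator of homoeologous gene families so the whole pipeline is
testable without any downloads.

Intended users: groups doing locus-resolved resequencing, association
mapping or null-allele diagnostics of multi-copy genes in polyploid
crops (wheat waxy / starch synthase II being the model case).

## Worked example

```r
library(PolyPrime)

fam <- simulateFamily(simulationParams(seed = 5, n_exons = 4))
res <- designPrimers(fam$copies, precomputedAlignment = fam$trueAlignment)
res$coverage
#>   genome n_pairs covered_bp gene_length coverage_fraction coverage_pct
#> 1      A       1        668         996         0.6706827         67.1
#> 2      B       1        665        1036         0.6418919         64.2
#> 3      D       1        658         984         0.6686992         66.9
```

Each simulated subgenome copy (here ~1 kb, 4 exons) gets one
genome-specific pair whose amplicon covers about two thirds of the
gene — a single sub-800-bp gene cannot host two band-sized amplicons;
with the default 11-exon families (~2.7 kb) three pairs per genome
typically tile ~85% of each copy. `chosenPairs(res$solutions[["A"]])` lists the primer
sequences, template coordinates, Tm values, product sizes and
specificity margins; `writeDesignOutputs(res, "out/")` writes the
primer TSV, amplicon BED (0-based), coverage TSV and a JSON run report.

Published primer tables can be re-scored directly:

```r
panel <- readPrimerTable(system.file("extdata",
  "wheat_wx_ssii_primers.tsv", package = "PolyPrime"))
# validatePrimerPanel(panel, copies) gives per-pair specificity verdicts
```

A thin command-line front end covering design / validate / type /
simulate is installed at
`system.file("scripts", "polyprime.R", package = "PolyPrime")`.

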