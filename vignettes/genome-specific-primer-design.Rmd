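---
title: "Designing genome-specific primers for homoeologous genes"
author: "PolyPrime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing genome-specific primers for homoeologous genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PolyPrime)
```

## The problem

Allopolyploid species carry two or more related subgenomes, and a gene of
interest is typically present as a set of homoeologous copies — one per
subgenome — that are nearly identical in their coding exons (often above
95% identity) while their introns have diverged much further (roughly
65–85% identity, with abundant indels). Bread wheat's three waxy
(*GBSSI*) copies and three starch synthase II copies are the canonical
example. PCR primers placed naively amplify all copies at once, which
ruins locus-specific resequencing, association mapping and null-allele
diagnostics. PolyPrime automates the design of *genome-specific* primer
pairs: pairs that amplify exactly one subgenome's copy and none of its
homoeologs.

## The design principle

The discriminating power of a PCR primer is concentrated at its
3' terminus: a template mismatch under the 3'-terminal base blocks
polymerase extension, while the same mismatch placed internally merely
weakens it. The pipeline therefore:

1. **aligns** the homoeologous copies (a progressive star alignment with
   affine gaps — match +1, mismatch −1, gap open 5, gap extend 1 — or a
   user-curated alignment),
2. **finds discriminative sites**: alignment columns where the target
   copy's residue differs from *every* off-target residue (SNP columns,
   or target bases opposite off-target deletion gaps). By default only
   INTRON and JUNCTION columns are searched, because that is where
   homoeologs actually differ; exonic anchors can be enabled and are
   ranked after intronic ones,
3. **anchors candidates**: for each site, up to two primer candidates
   (one per orientation) put the site under the 3'-terminal base,
4. **fits the melting temperature** by growing the primer at its 5' end
   (the 3' anchor never moves) until Tm enters a 59–61 °C window,
5. **filters** candidates on GC content (0.30–0.70), homopolymer runs
   (≤ 5), 3'-terminal fold-back seeds and self-dimer seeds,
6. **verifies specificity in silico** with a mismatch-position-aware
   amplification model (below), and
7. **tiles** the gene with overlapping amplicons and reports union
   coverage.

## The in-silico PCR model

Binding sites are all gapless alignments of a primer to either template
strand with at most `maxMismatches` (default 3) mismatches. Each site is
classified:

| condition                                            | class  |
|------------------------------------------------------|--------|
| 3'-terminal base mismatched, or > 3 total mismatches | NONE   |
| terminal base matched, a mismatch at positions 2–5   | WEAK   |
| all mismatches (if any) beyond position 5            | STRONG |

Positions are counted from the 3' end. A product forms from any
converging pair of sites on opposite strands within the size cap
(default 3000 bp), and its class is the weaker of its two primer
classes. A pair is **genome-specific** iff it yields exactly one STRONG
product on the target copy and no STRONG-or-WEAK product on any
off-target. WEAK off-target products — the faint mismatch-PCR bands a
gel would show when the discriminating SNP sits at position 5 rather
than position 1 — disqualify a pair outright.

The two anchor points of this classification are empirical: a single
internal mismatch at the fifth position from the 3' end still allows a
weak off-target product, while a 3'-terminal mismatch abolishes it. The
exact window (positions 2–5) and the total-mismatch cap are
reconstructions between those observations, chosen to match general
extension biochemistry; both are exposed in `pcrParams()` rather than
hard-coded.

```{r figure-mechanism}
set.seed(206)
rand <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
tgt <- rand(600); off <- tgt
substr(off, 500, 500) <- setdiff(c("A","C","G","T"),
                                 substr(off, 500, 500))[1]
fwd <- substr(tgt, 51, 70)
rc <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))
# SNP at position 5 from the reverse primer's 3' end: weak off-target
isGenomeSpecific(fwd, rc(substr(tgt, 496, 515)), c(A = tgt),
                 c(B = off))$specific
# SNP at the 3' terminus: specific
isGenomeSpecific(fwd, rc(substr(tgt, 500, 519)), c(A = tgt),
                 c(B = off))$specific
```

## Melting temperature

`meltingTemperature()` implements unified nearest-neighbor
thermodynamics with per-terminal initiation terms, the entropic salt
correction 0.368·(N−1)·ln[Na⁺eq], and the divalent/dNTP equivalence
Na⁺eq = monovalent + 120·√(Mg²⁺ − dNTP) (mM). Defaults mirror the
reference PCR mix: 50 mM monovalent, 1.5 mM Mg²⁺, 0.2 mM dNTP, 0.6 µM
primer. No particular Tm model is canonical for this assay family; this
one was chosen because it is the standard nearest-neighbor formulation,
and the test suite pins it against an independent re-implementation to
0.01 °C. `adjustTmBy5Prime()` returns the *shortest* primer in the
16–25 nt window whose Tm lands in 59–61 °C, which makes results
reproducible; the floor of 16 nt (rather than the more usual 17) admits
short GC-rich anchors, and such primers are flagged.

## Tiling and coverage

Amplicons of 800–1500 bp are fully sequenceable from both ends on a
capillary sequencer, and neighboring amplicons should overlap by
80–100 bp so reads assemble. Both bands are *soft*: published designs
for this assay family include 731 bp and 1657 bp products, so
out-of-band sizes are penalized rather than rejected (set
`hard_size_band = TRUE` to forbid them). The optimizer first fixes the
maximum attainable coverage — the union of all specific amplicons — and
then, per contiguous covered segment, selects the minimum number of
amplicons covering it (a sweep that is exact for intervals), breaking
ties by specificity margin and then lexicographically. Coverage is
reported as the **union** of chosen amplicon intervals divided by the
full genomic gene length; overlaps are not double-counted.

## The simulator

`simulateFamily()` emulates the divergence structure that makes this
design problem solvable: an ancestral multi-exon gene (default 11 exons,
the waxy architecture; exons 100–200 bp, introns 70–130 bp) from which
each subgenome copy inherits region-specific substitutions and
intron-confined indels (rate 0.02 events/bp, lengths 1–30 bp).
Divergence parameters are *pairwise* targets: each copy receives half
the divergence from the ancestor, so the default intron divergence of
0.25 realizes pairwise intron identities near 77% — inside the 65–85%
band observed for real homoeologs — and the default exon divergence of
0.03 keeps exons above 95% identity. Identity here is computed over
gap-free aligned positions; indels are modelled on top of it.
Randomness is pre-drawn position-wise, so at a fixed seed raising a
divergence parameter adds substitutions without reshuffling existing
ones, and identical parameters give byte-identical output files.

What the simulator does **not** model: transition/transversion bias,
rate heterogeneity along the gene, homopolymer-associated indel
hotspots, paralogs elsewhere in the genome, and polymerase slippage
products. Passing tests on simulated families therefore demonstrate the
pipeline's internal correctness and its behavior under realistic
divergence levels, not performance against whole-genome off-target
landscapes.

```{r end-to-end}
fam <- simulateFamily(simulationParams(seed = 5, n_exons = 4))
res <- designPrimers(fam$copies, precomputedAlignment = fam$trueAlignment)
res$coverage
```

## Null-allele genotyping

Deletion-based null alleles lose their diagnostic PCR product because
the deletion removes a primer site (an intron, a terminal exon, or the
whole gene). `predictPresence()` scores an allele "present" only on a
STRONG product — faint mismatch-PCR bands do not count, matching how
diagnostic gels are read — and `classifyGenotype()` maps the
presence/absence pattern across the three loci to the conventional
eight type codes (wild type = 1, single nulls 2–4, double nulls 5–7,
triple null 8). Codes 5 and 6 correspond to double-null patterns never
observed in the reference germplasm; they are filled in by analogy and
flagged `inferred`.

## Numerical and design choices

- **Coordinates** are 1-based closed throughout the package (the native
  convention of the IRanges/Biostrings stack it is built on); BED output
  is converted to 0-based half-open by the exporter, and all TSV reports
  stay 1-based inclusive.
- **Junction window**: alignment columns within 5 columns of an
  exon/intron boundary are labelled JUNCTION — the same width as the
  3'-proximal window of the specificity model, so a junction anchor's
  discriminating region can straddle the boundary.
- **Ambiguity**: columns containing N are never discriminative; partial
  sites (target differs from some but not all off-targets) are reported
  only on request and never anchored.
- **Ties**: shortest Tm-satisfying primer wins; tiling ties break by
  margin, then start, then size. Repeated runs are identical.
- **Degenerate inputs**: identical copies produce an empty design with a
  warning, coverage 0; an empty-sequence allele is a whole-gene-deletion
  sentinel that is always "absent".

## Limitations

- Binding is gapless: bulged duplexes are not modelled. Indel
  discrimination still works because an off-target deletion shifts or
  destroys the binding site.
- Specificity is assessed only against the supplied homoeolog
  templates, not genome-wide.
- Band intensity is not predicted quantitatively; WEAK is a categorical
  verdict.
- The problem sizes used in the bundled tests (families of 4–11 exons,
  genes of 1–3 kb, tens of candidate pairs) match the scale of
  single-gene-family designs this tool targets.
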