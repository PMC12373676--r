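---
title: "sexCAPS: methods and design notes"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sexCAPS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r load}
library(sexCAPS)
```

# The problem

Dioecious plants such as *Cannabis sativa* cannot be sexed before
flowering by eye, yet growers and breeders usually need to act (cull,
cross, select) long before flowers appear. A DNA sex marker solves this:
a locus that differs between the X and Y chromosomes can be queried from
a seedling leaf punch.

sexCAPS implements an in-silico pipeline for discovering and validating
such markers of the **CAPS** type (Cleaved Amplified Polymorphic
Sequence): a single primer pair amplifies both the X and the Y copy of a
gametolog (an X/Y homolog pair), and a restriction enzyme cuts exactly
one of the two alleles. Females (XX) then show only the uncut band;
males (XY) show the uncut band from their X copy plus the cut fragments
from their Y copy. The same differential site supports a gel-free
TaqMan-style read-out with two allele-specific probes.

# Pipeline model

`runPipeline()` chains five stages. Each has a standalone exported API.

## 1. Comparative k-mer sieve (`buildKmerProfile`, `maleSpecificKmers`, `sieveTranscripts`)

Male-specific sequence is found without an assembly or reference: a
k-mer (default `k = 16`) is *male-specific* when it occurs in **every**
male sample's transcript set and in **no** female sample's set.
Transcripts are ranked by how many male-specific k-mers they carry.
`k = 16` is long enough that chance collisions across a
transcriptome-scale set are negligible (4^16 ≈ 4.3 × 10^9 possible
k-mers) and short enough to tolerate nearby SNPs. K-mers are
canonicalised over reverse complements so strandedness of the input does
not matter.

## 2. Expression filters (`strictTpmFilter`, `maleBiasTest`)

Y-linked genes in a dioecious species should be expressed in males and
absent in females. The *strict* filter requires mean male TPM above a
floor (default 10) and **zero** TPM in every female — presence/absence,
not a fold change. A male-bias table (log2 fold change with pseudocount,
Wilcoxon rank-sum p, Benjamini–Hochberg FDR) is always computed and
reported, but its FDR gate is only enforced when
`useBiasGate = TRUE`. The default is off for a statistical reason, not
an empirical one: an exact two-sided Wilcoxon test at 3 vs 3 samples can
never reach p below 2/choose(6,3) = 0.1, so an FDR ≤ 0.05 gate empties
any 3-vs-3 experiment regardless of the data. For Y-linked genes the
strict zero-in-females criterion subsumes the bias requirement anyway.

## 3. Gametolog pairing (`findCounterpart`, `alignPair`, `divergenceRank`)

A CAPS marker needs the X counterpart, because the same primers must
amplify both alleles. Each surviving transcript is searched against the
candidate X loci by local alignment; the best hit is accepted only when
it is near-identical and unambiguous. A hit that is *perfectly*
identical at full coverage is rejected (`rejected_female_identical`):
with no X/Y divergence there is nothing to cut differentially. Accepted
pairs are globally aligned (Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment`) and ranked by divergence — divergence
is the raw material for differential restriction sites.

`defaultScoring()` uses match +2, mismatch −3, gap opening 10, gap
extension 2 (a gap of length L costs `open + L * ext`). The opening
penalty is deliberately high relative to the mismatch cost: gametologs
diverge mostly by substitution, and with a cheap opening the aligner
will rewrite a short run of substitutions — precisely what an
allele-differential restriction site is — as an insertion/deletion
pair, which destroys the column-wise homology that site scanning and
probe design depend on.

## 4. CAPS design (`scanDifferentialSites`, `findConservedFlanks`, `designDegeneratePrimers`, `designAlleleProbes`, `designCapsCandidates`)

On the pair alignment, every enzyme in the panel (`defaultEnzymes()`,
twelve common six-cutters) is scanned on both strands for recognition
sites present in exactly one allele. Around each such site the nearest
conserved flanking windows are located and a single degenerate primer
pair is derived by IUPAC consensus over all alignment rows, subject to
length, degeneracy and melting-temperature constraints
(`primerConfig()`). Two allele-specific probes spanning the diagnostic
columns are designed for the TaqMan read-out (`probeConfig()`).

Inside `runPipeline()`, each sample's own copy of the paired transcripts
is threaded into the alignment as an extra row before design, so
cross-sample SNPs in the flanks become degenerate primer bases rather
than primer-binding failures — the in-silico equivalent of designing
primers on a multi-cultivar alignment.

## 5. Cohort validation and genotyping (`insilicoPCR`, `digest`, `callGenotype`, `simulateTaqman`)

Background X/Y divergence creates *chance* differential restriction
sites in addition to any fixed marker. These are genuine CAPS sites, but
unlike a fixed difference they can be toggled by a private SNP in a
single individual. So the pipeline does what a bench scientist does:
every designed candidate genotypes every input sample in silico, and the
reported marker is the best-ranked candidate whose calls agree most with
the known sample sexes. Per-candidate concordance is returned in the
`validation` table.

`callGenotype()` matches an observed band set against the candidate's
predicted XX and XY patterns within a size tolerance (default 10 bp,
i.e. gel resolution); anything that fits neither pattern is
`"ambiguous"`, never silently forced into a call.

# Worked example on the shipped fixture

The package ships a synthetic X/Y gametolog alignment
(`synthetic_cspds5_xy.aln.fa`) engineered so a published-style
degenerate primer pair gives a 419 bp amplicon on both alleles with a
Y-only EcoRI site:

```{r worked}
path <- system.file("extdata", "synthetic_cspds5_xy.aln.fa",
                    package = "sexCAPS")
aln <- readFastaRecords(path, gapped = TRUE)
x <- gsub("-", "", as.character(aln[[1]]))
y <- gsub("-", "", as.character(aln[[2]]))

fwd <- "GGAYTATCATCCAGAGAMTG"
rev <- "TACCATATTCTCATCAGARGC"
eco <- defaultEnzymes()[["EcoRI"]]

insilicoPCR(x, fwd, rev)$length   # 419
insilicoPCR(y, fwd, rev)$length   # 419
bands(digest(insilicoPCR(y, fwd, rev)$seq, eco))  # 157 262
pb <- predictGenotypeBands(insilicoPCR(x, fwd, rev)$seq,
                           insilicoPCR(y, fwd, rev)$seq, eco)
bands(pb$XX)
bands(pb$XY)
```

# End-to-end run on a simulated cohort

```{r pipeline}
pair <- generateGametologPair(length = 2000, divergence = 0.02, seed = 2)
coh <- generateCohort(pair, nMale = 3, nFemale = 3, snpRate = 0.001,
                      nDecoys = 20, seed = 2)
rep <- runPipeline(list(
  males = coh$samples[coh$sex == "male"],
  females = coh$samples[coh$sex == "female"],
  expression = coh$se))
rep$summary$n_candidates
rep$validation
rep$genotypes
```

# Synthetic data: scope and limits

All shipped sequence fixtures are synthetic and labelled as such in
their filenames (`synthetic_*`). They emulate the *arithmetic* of a real
assay — amplicon lengths, digestion band sizes, degenerate primer
binding, allele-specific probe placement — not the biology of any real
genome. The cohort generator plants one Y transcript with a single
differential restriction site, conserved primer flanks, decoy
transcripts and per-sample SNPs; wet-lab quantities (PCR efficiency,
gel mobility, fluorescence chemistry, real population diversity) are
out of scope and no claims are made about them.

# Conventions

* **Coordinates are 1-based closed intervals throughout** (alignment
  columns, site starts, amplicon spans; a cut position `c` means "cut
  after base c"). This is the R/Bioconductor idiom; mixing conventions
  inside one package invites off-by-one bugs.
* All randomised functions take an explicit `seed` and restore the
  caller's RNG state; every result shown here is reproducible.
* IUPAC matching is conservative: an `N` in a template never satisfies
  an enzyme recognition site (`forbidN = TRUE` in `digest()`), so
  ambiguous template bases cannot fabricate cut sites.

# Limitations

* In-silico PCR is exact IUPAC matching with full-length primer binding;
  it does not model mispriming, 3'-end sensitivity or thermodynamics.
* The Wilcoxon bias test is powerless at the smallest cohort sizes (see
  above); use larger cohorts if you enable `useBiasGate`.
* Cohort validation can only certify a marker against the samples you
  provide; population-level fixation requires a wider panel, as in any
  marker study.
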