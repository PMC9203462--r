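---
title: "Simulating anchor-based bisulfite sequencing: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating anchor-based bisulfite sequencing: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abbskit)
```

## The assay being modeled

Bisulfite treatment deaminates unmethylated cytosine to uracil (read as T)
while 5-methylcytosine (5mC) resists conversion. Whole-genome bisulfite
sequencing (WGBS) primes the converted single-stranded DNA with random
hexamers and therefore spends sequencing power uniformly. Anchor-based
bisulfite sequencing (ABBS) instead primes with a 5'-NNNNN-PPG-3' oligo
whose 3'-terminal base is 8-aza-7-deaza-2'-deoxyguanosine (PPG), a
guanosine analog with stabilized pairing to cytosine. After conversion the
only cytosines left on the template are methylated ones (plus rare
conversion failures), so productive extension starts almost exclusively at
5mC: the library is self-targeted to methylated regions while the read
bodies still report every surrounding cytosine at base resolution.

`abbskit` implements this chain end to end in silico: synthetic genomes and
methylomes, molecule realization, conversion, fragmentation, priming,
paired-end read generation with a truth sidecar, truth-based methylation
calling, and the downstream quantifications (conversion QC, strict-threshold
site calling, bin coverage, motif meta-profiles, read-position statistics,
subsampling sensitivity, correlation procedures, region overlaps).

## Generative models

### Genomes

`generate_genome()` emits first-order Markov sequences with a prescribed GC
fraction and a prescribed CpG observed/expected ratio (`cpg_enrichment`).
The dinucleotide joint distribution is balanced by iterative proportional
fitting so that the emitted base composition equals the target and the CpG
dinucleotide frequency equals `cpg_enrichment` times the product of the
observed base frequencies — exactly, not approximately, in expectation.

The two bundled model systems are:

* **`ecoli_dcm`** — 100 kb, GC 0.51, no CpG bias; every CCWGG site (W = A/T)
  carries 5mC at its second cytosine on both strands at level 1 (the Dcm
  methyltransferase pattern). `ecoli_dcm_minus` is the same genome with an
  empty methylome, mirroring the dcm- negative-control strain. Read mode
  2 x 38.
* **`mammalian_k562_like`** — 1 Mb, GC 0.41, CpG depleted to an
  observed/expected ratio of 0.25 (the genome-wide mammalian value is
  0.2–0.25), with 10 CpG islands of 1 kb placed on the most CpG-dense
  windows. Read mode 2 x 150.

Both presets carry a 10 kb fully unmethylated spike-in sequence
(`lambda_synthetic`) emulating the 1% unmethylated lambda DNA conversion
control; its share of the library is applied at the fragment-sampling level
(`spike_in_read_fraction`, default 0.01), which directly controls the QC
denominator.

### Methylomes

The mammalian methylome assigns each CpG dyad a level drawn from a Beta
mixture: `hypo_beta = (1, 10)` inside CpG islands, and outside islands
`hyper_beta = (10, 1)` with probability `hyper_fraction = 0.8` (else the
hypomethylated component). These defaults were chosen once to reproduce the
familiar somatic pattern — a strongly bimodal distribution with modes at 0
and 1, roughly three quarters of CpGs above 80%, a hypomethylated CGI
compartment, and a thin but non-empty band of intermediate levels (about
10% of sites between 20% and 80%), which keeps intermediate-level analyses
meaningful. Both strands of a dyad carry the same level; asymmetric CpG
methylation is not modeled. Non-CpG cytosines default to level 0, matching
the near-absence of non-CpG methylation in somatic bisulfite data; the
level is configurable (`noncpg_level`).

### Wet-lab chain

For each molecule the simulator realizes methylation per cytosine
(Bernoulli at the site's level), converts (an unmethylated C stays C with
probability `1 - conversion_efficiency`, default efficiency 0.996; a
methylated C converts with probability `inappropriate_conversion`, default
0), fragments to 200–300 nt, and primes:

* **ABBS**: anchors are retained cytosines with at least `min_extension`
  (30) template bases 5' of them and the five N bases on-template. A
  fragment with at least one eligible anchor is specifically primed with
  probability `p_specific` (0.8); otherwise it falls back to nonspecific
  priming (uniform position, random N block, the anchor base still read as
  G — it is the same physical primer). Each primer N base matches the
  complement of its template base with probability `p_anneal_match` (0.9,
  a phenomenological stand-in for annealing thermodynamics chosen to give a
  visible but imperfect read-start motif); mismatches are uniform.
* **WGBS**: a fully random position and a random hexamer under the same
  annealing model.

Read 1 is the synthesized strand read primer-first (PBAT orientation: the
complement of the converted template), so position 6 of an ABBS read 1 is
always G and positions 1–5 are primer-derived, not genomic. Read 2 is the
reverse complement of the synthesized strand, i.e. the converted template
sense. Products whose synthesized strand is shorter than the read length
are discarded and resampled; counts appear in the run report. PCR
duplication, adapters, quality degradation and mapping ambiguity are not
modeled.

Every emitted pair carries a truth record. Because nonspecific and WGBS
products have no anchor, the sidecar records both `anchor_pos` (-1 when
nonspecific) and `prime_pos` (always set): truth-based alignment needs the
priming position to place read 1 for every product, not only specific ones.

### Calling

`call_cytosines()` replaces a bisulfite aligner with truth-based alignment
and applies the standard extractor conventions: ignore 7 bases at each
mate's 5' end (covering the 6 primer bases plus one buffer), 5 at each 3'
end, count mate-overlapping template positions once with read 1 taking
precedence, classify context strand-aware as CpG/CHG/CHH, and emit
bedGraph-style (zero-based) and CX-style tables. All downstream thresholds
are strict inequalities — a site is methylated when its level is *above*
50% and confidently measured when its coverage is *above* the cutoff
(default 25) — mirroring the awk filters traditionally applied to Bismark
output. Boundary behavior at exactly 50% and exactly 25x is unit-tested.

A note on depth conventions: cytosine coverage is strand-specific (a
forward-strand C is observed only from OT templates), so the mean
per-cytosine coverage of a call table is half the raw base depth.
`pairs_for_depth()` sizes runs in per-cytosine coverage, the quantity the
coverage cutoffs act on.

## Numerical and design choices

* Coordinates are 0-based half-open, forward strand, throughout; a
  minus-strand cytosine is stored at the forward coordinate of its G.
* One root seed fans out to deterministic child streams per pipeline stage
  and batch (`derive_seed()`); fixed seed means byte-identical FASTQ,
  sidecar and reports.
* Subsampling is exact without replacement (`round(fraction * n)` pairs),
  giving deterministic test surfaces rather than Bernoulli thinning.
* Homogeneous-mode correlation bins sites on the WGBS axis (the X axis of
  the published scatter) into twenty 5%-wide bins and draws an equal number
  per bin; the axis is configurable, and when a bin cannot supply the
  requested 5000 sites the largest feasible equal count is used.
* CGI placement is deterministic given the genome: candidate windows are
  ranked by CpG count with above-median density preferred and leftmost
  ties-first, then chosen greedily without overlap.
* Trailing bins keep their true width and RPKM uses it.
* The per-molecule functions (`realize_and_convert()`, `prime_abbs()`, ...)
  define the contracts; `simulate_pairs()` is a vectorized byte-level engine
  implementing the same contracts for throughput. Under deterministic
  settings (perfect annealing and conversion, binary methylome) every
  engine read is reconstructed exactly from its truth record by the
  molecule-level path, and the test suite asserts this.

## Problem sizes used by the shipped analyses

The test suite and the acceptance script run everything at desk scale,
chosen so the full battery completes on a laptop-class single core: the
matched mammalian comparison uses the 1 Mb preset at ~40x per-cytosine
depth per protocol (~420,000 pairs each); the bacterial replicate
comparison uses the 100 kb preset at ~30x per replicate; the sensitivity
comparison uses a 300 kb mammalian genome with WGBS at ~25x and ABBS at
one tenth of that read count; conversion QC uses a 50 kb genome with
25,000 WGBS pairs (~10,000 spike cytosine observations). Unit tests use
smaller genomes (4–100 kb).

## What the simulation does and does not show

The simulator reproduces, and the tests verify, the mechanistic signatures
of the assay: specific ABBS reads start only at retained cytosines and
vanish in the dcm- control; the C-mC-W-G-G signature appears at the read-1
start; read coverage accumulates around CCWGG but not around the AASTT
control motif and not in dcm- samples; methylated 10 bp bins are
coverage-enriched under ABBS but not WGBS; per-site levels are unbiased for
WGBS and agree between matched ABBS and WGBS libraries at r >= 0.99 above
25x coverage; spike-in QC recovers the programmed conversion efficiency.

Two published observations are out of reach of this generative model, and
deliberately so — they depend on properties of real genomes the model does
not claim to have:

* **Genome-scale sensitivity gains at reduced read budgets.** In the
  simulator every fragment is primed (specifically or by fallback), so at a
  fixed read count ABBS redistributes coverage only locally, within a read
  length of anchors. With methylated CpGs quasi-uniform at one per ~74 bp,
  no region is far from an anchor and ABBS cannot concentrate coverage by
  the order of magnitude needed to beat a >25x cutoff at one tenth of the
  reads. The real assay's large sensitivity advantage rides on 5mC
  clustering in real genomes and on unprimed fragments dropping out of the
  library, neither of which is modeled here.
* **Elevated read-level 5mC prevalence in ABBS reads.** CpG levels are
  drawn independently site to site, so the read body upstream of an anchor
  has background methylation; in real methylomes neighboring CpGs are
  strongly correlated, which is what makes ABBS reads methylation-rich.

For the same counting-noise reason, replicate correlation of 10 bp bin
coverage at ~30x depth plateaus near r = 0.85 in simulation, whereas
deep-coverage real replicates reach 0.97: at desk-scale depth Poisson noise
per 10 bp bin is not negligible relative to the anchor-driven coverage
structure. The package reports these quantities honestly rather than tuning
the generator to force them.

## A minimal session

```{r example, eval = FALSE}
sc <- build_scenario("ecoli_dcm", seed = 7, genome_length = 40000L)
cfg <- sim_config(protocol = "ABBS", n_read_pairs = 20000, read_length = 38,
                  seed = 7)
pairs <- simulate_pairs(sc$genome, sc$methylome, cfg)
tab <- call_cytosines(pairs, sc$genome)
conversion_efficiency(tab, "lambda_synthetic")
sites <- call_methylated_sites(tab, stats_config())
track <- classify_bins(bin_coverage(pairs, sc$genome, 10L), sites)
```
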