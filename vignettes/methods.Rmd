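---
title: "Models and methods behind tfgpmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tfgpmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model this package implements, the
parameters that matter, the numerical conventions adopted where a
definition left room, and what the synthetic-data tests do and do not
establish.

## The genotype space

A binding-site genotype is a double-stranded DNA 8-mer: a sequence and
its reverse complement name the same molecule, so the space holds
(4⁸ − 4⁴)/2 + 4⁴ = 32,896 genotypes (the 4⁴ = 256 palindromic sites
have no partner to merge with). We name each pair by its
lexicographically smaller member; any fixed rule would do, this one is
reproducible and makes integer codes (base-4, A<C<G<T) order-compatible
with string order.

Edges of the space Ω join genotypes one small mutation apart under two
mutation classes:

* **point mutations** — 3 per position, 24 per site. In distance terms:
  the zero-offset gapless mismatch count against the other sequence or
  its reverse complement equals 1.
* **shift indels** — an insertion or deletion at either end that slides
  the fixed-width site window one base along the genome, 4 incoming
  bases × 2 directions = 8 per site. These are *not* captured by the
  mismatch distance (a one-base shift changes up to all 8 aligned
  positions), so the shift relation is a separate edge predicate: exact
  7-mer overlap after a one-base shift, again up to reverse
  complementation.

A site therefore has at most 32 neighbors; 96% attain the maximum, and
the deficit nodes are exactly those where canonicalization collapses
distinct raw mutants onto one node or onto the site itself (verified
node-by-node in the tests). Multi-step mutational distances are graph
distances in Ω — the single-step mismatch rule alone cannot produce
them because of the indel edges.

Ω at k = 8 has 32,896 nodes and 523,728 edges; its diameter is 8,
characteristic path length 4.3846, clustering coefficient 0.1229 and
degree assortativity 0.0059. One of these rounds differently from the
reference description (0.1229 → 0.123 vs a printed 0.122); the
difference is below the 0.001 tolerance we accept for all Ω statistics
and we report the computed value unchanged.

The site length k is a parameter (default 8). k = 4 gives a 136-node
space on which *every* statistic can be recomputed by brute force
(triple loops, Floyd–Warshall, explicit string surgery); the test suite
uses this to cross-check each implementation path exactly.

## Phenotypes, genotype networks, and their statistics

A TF's phenotype is defined by a strict E-score threshold: site s binds
TF t when E(t, s) > τ. Scores live in [−0.5, 0.5]; τ = 0.35 by default,
with a sensitivity grid conventionally inside (0.35, 0.45). Sites with
E = τ count as unbound — the threshold separates *specific* binding
from non-specific or absent binding.

The bound set induces a subgraph of Ω; its connected components are
sorted by size (ties broken by smallest member site) and the largest is
the dominant network. All statistics are computed on dominant networks
only; other components are retained for counting. Conventions adopted
where the formulas are 0/0:

* clustering: nodes of degree < 2 contribute 0 to the average;
* assortativity: a regular network returns NaN (not 0) — the variance
  term vanishes and reporting 0 would fake "uncorrelated";
* characteristic path length: averaged over unordered distinct pairs
  (identical to the ordered mean for an undirected graph; the
  convention reproduces the reference Ω value 4.385);
* single-node networks report diameter 0, L = 0, q = NaN and are
  flagged `degenerate`;
* route-factor target: the highest-affinity site of the dominant
  network; E-score ties go to the lexicographically smallest site.

## Internetwork measures

Overlap O_qp, mutation probabilities φ_qp (with the local spectrum
φ_q^local(i) = n_iq / k_i), global connectivity Φ_q = Σ_{p≠q} φ_qp, and
accessibility A_qp over the *external* boundary ∂S(G_p) (neighbors of
the set, minus the set — the exclusion makes A comparable to φ) are
straight implementations of their definitions, vectorized over a
membership matrix.

Two definitional choices deserve a note:

* **Bhattacharyya coefficient.** We normalize each local phenotype
  spectrum to sum to one and use the standard square-root form
  Σ_q √(p_q(i) p_q(j)). The raw spectra can sum above one when
  phenotypes overlap, and only the normalized sqrt form delivers the
  claimed [0, 1] range with 1 at identity. The literal product-sum is
  available via `sqrt_form = FALSE`. Shared neighbors of the two sites
  are excluded by default (the conservative variant); a spectrum with
  zero mass after exclusion yields NA and the pair is skipped and
  counted.
* **Phenotype network.** Two phenotypes are connected when their
  dominant networks share a genotype (*overlap*) or when a strictly
  non-neutral single mutation leads from one into the part of the other
  outside it (*adjacent*). Both flags are reported per pair.

Phenotype space covering asks what fraction of all phenotypes is found
within n mutations of a binding site. The *neutral* variant walks only
edges of the focal network (so it measures overlap); the *non-neutral*
variant takes only steps that leave the focal network — implemented as
BFS in Ω restricted to nodes outside the network, seeded from each
source's outside neighbors. The source itself counts as covered at
radius 0 by default (`count_self`), since the focal phenotype is
trivially present there; both conventions are available. Curves are
means ± sd over source sites and are monotone by construction.

## Null model

Binding sites are randomly reassigned to TFs with set sizes preserved
exactly, independently across TFs, sampling uniformly from all of Ω.
The sampling universe matters: under Ω-sampling the null expectation of
φ_qp is the phenotype frequency f_q = |S(G_q)|/|Ω| and pairwise
intersections follow the hypergeometric expectation ab/|Ω| — both are
verified by Monte-Carlo in the acceptance suite (200 replicates; the
reference analysis used 1000, and a 50-replicate summary agrees with a
400-replicate one within Monte-Carlo error in the tests). Restricting
the universe to empirically bound sites is available as a switch
(`universe = "bound"`) but changes the f_q equivalence. Replicate r
uses seed `seed + r`, so ensembles are reproducible and extensible.

## In-vivo diversity

Footprints (0-based half-open BED convention) are kept when at least
8 bp long and overlapping a promoter — 500 bp upstream of a TSS on the
gene's strand — by at least one base. Every 8-mer window of a retained
footprint is canonicalized (covering both strands without double
counting) and scored; for each TF, one qualifying window per footprint
is chosen uniformly at random under a caller-provided seed, so only
multi-hit footprints depend on the seed.

Shannon diversity D = −(1/8) Σᵢ Σⱼ p_ij log₂ p_ij (0·log 0 = 0) ranges
from 0 (monomorphic) to 2 bits (all alleles equally frequent at every
position). Genomic positions without a polymorphism record are treated
as monomorphic reference. A site is *polymorphic* when any of its
positions has a major-allele frequency below one, and per-TF diversity
is the mean D over polymorphic assigned sites (median available; the
summary statistic is not fixed by the reference description, mean is
the default).

Structure–diversity correlations are Spearman for diversity vs
dominant-network size, and partial Spearman — Pearson partial
correlation on rank-transformed variables, t-test on n − 3 df — for
path length, route factor and assortativity given size, since size
confounds all three.

Allele frequencies arrive either as a plain TSV (chrom, pos, A, C, G,
T) or from a VCF via VariantAnnotation (biallelic SNPs with an AF INFO
field; the reference allele receives 1 − AF).

## Synthetic data: the stated world

The generator's defaults are fixed commitments, not tuning knobs:

* E-scores decay linearly with **Ω graph distance** from a per-TF
  consensus: E = clamp(0.45 − 0.04·d + ε, −0.5, 0.5), ε ~ N(0, 0.02²).
  Graph distance (not Hamming) exercises the shift-indel structure —
  the nonstandard part of the mutation model. At τ = 0.35 the bound set
  is a fuzzy ball of radius 2–3: several hundred to about a thousand
  sites, inside the empirical range of real PBM genotype sets (mean
  374, max 1186). With noise off the set is an exact distance ball —
  connected, single network — giving closed-form end-to-end tests.
* Footprints are 8–40 bp, mean 16.56 bp (the empirical footprint-length
  statistics), one per synthetic promoter, each carrying a planted site
  from its TF's dominant network in a random strand orientation; decoy
  footprints that fail the length or promoter filters are added to
  exercise the filtering path.
* Per-TF mean diversity follows a linear model on the standardized
  ranks of dominant-network size and characteristic path length:
  intercept 1.0, coefficients 0.35 and 0.35, residual sd 0.35. These
  were chosen once so the planted partial correlation of diversity with
  path length given size is ≈ 0.5 — unambiguously detectable at 50 TFs,
  which is what the parameter-recovery criterion demands — and are
  recorded in the truth record of every draw. Per-site diversity
  scatters around the TF target (sd 0.15) and is realized as allele
  frequencies of the form (p, (1−p)/3, (1−p)/3, (1−p)/3) whose entropy
  is inverted numerically on a grid.

What a green synthetic test does establish: every pipeline stage
computes its definition correctly (oracle equality), respects its
invariants, is deterministic under seeds, and recovers planted effects
with the expected power. What it does not establish: agreement with
statistics of *real* PBM/footprint/polymorphism data — real E-score
landscapes are not distance balls, real footprints cluster and overlap,
and real allele frequencies are shaped by linkage and demography that
the generator deliberately omits. Real-data claims are therefore
supported only through the file-format pathway (`run_pipeline` on
CIS-BP/UniPROBE-style tables), not asserted by the test suite.

## Known limitations

* Distances are defined for equal-length sites only; arbitrary-gap
  alignments and IUPAC ambiguity codes are out of scope.
* The non-neutral covering variant recomputes multi-source BFS per
  source site; on networks of thousands of sites use the `sources`
  argument to sample.
* The VCF writer emits biallelic AF records and collapses minor-minor
  allele mass into ALT; it exists for round-trip testing, not as a
  general-purpose VCF emitter.
* Community detection on genotype networks and proteome-wide domain
  counting are intentionally not implemented.
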