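---
title: "Reconstructing gene sequence clusters from metagenomic reads: models and methods"
author: "gscem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene sequence clusters from metagenomic reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Shotgun metagenomes of environmental communities — deep-sea cold-seep
sediments are the motivating system — contain reads from functional marker
genes (*mcrA*, *dsrA*, *nifH*, *narG*, *nosZ*, SSU rRNA, ...) whose true
full-length sequences are mostly absent from reference databases.
Read-mapping profilers quantify only what the database already contains;
assemblers rarely recover complete low-abundance gene variants.  `gscem`
takes the third route, in the EMIRGE lineage: treat the community's gene
pool as a finite mixture of unknown full-length sequences, and estimate
both the sequences and their mixing proportions from the reads by
expectation–maximization, starting from whatever candidate references are
available.  The reconstructed units are called gene sequence clusters
(GSCs): full-length consensus sequences with relative abundances, playing
the role OTUs play in amplicon work but for an arbitrary functional gene.
Downstream, the package quantifies the GSCs' taxonomic and phylogenetic
diversity (Hill numbers, weighted UniFrac, MNTD) and the coupling between
genes and environmental gradients (Pearson, Mantel, PCoA).

## The mixture model

Let $K$ clusters have consensus sequences $c_1,\dots,c_K$, per-position
base-probability matrices $B_i \in [0,1]^{L_i\times 4}$ (each row a
distribution over A, C, G, T) and mixing priors $\pi$ with
$\sum_i \pi_i = 1$.  A read unit $u$ (a mate pair, or a lone mate — see
below) has likelihood under cluster $i$

$$P(u \mid i) \;=\; \prod_{t \in \text{aligned columns}} \;
  \sum_{x \in \{A,C,G,T\}} B_i[p_t, x]\; M(o_t \mid x, q_t)
  \;\times\; \gamma^{\#\text{gap columns}},$$

where $o_t$ is the observed base, $q_t$ its Phred quality,
$\varepsilon_t = 10^{-q_t/10}$ (clamped at 0.75 so $q = 0$ stays finite),
$M(o \mid x, q) = 1-\varepsilon$ when $o = x$ and $\varepsilon/3$
otherwise, and every inserted or deleted alignment column contributes the
fixed factor $\gamma = 10^{-3}$.  `N` bases are skipped.  This model, the
pseudocount below, and the initialization values are implementation
choices of this package, surfaced in `gscem_config()`; the reconstruction
thresholds (split, merge, depth) are the method's standard defaults.

**E step.** $z(u,i) \propto \pi_i P(u\mid i)$, normalized over the
clusters the unit aligns to; computed in log space.  Units whose total
mass underflows are excluded from that iteration.

**M step.** $\pi_i = \sum_u z(u,i) / U$ over the $U$ assigned units.
Position $t$ of cluster $i$ accumulates posterior-weighted, quality-damped
base counts $n_t[x] = \sum z(u,i)\,w(o,q,x)$ with $w = 1-\varepsilon$ on
agreement and $\varepsilon/3$ otherwise; the new row is
$(\alpha + n_t)/(4\alpha + \sum_x n_t[x])$ with pseudocount
$\alpha = 0.1$.  Positions with posterior-weighted depth below 1 keep
their previous row — there is no evidence to update them.  The consensus
is the per-row argmax, ties broken alphabetically (A < C < G < T) for
determinism.

**Read units.** A mate pair is one unit over exactly those clusters where
*both* mates align (likelihoods multiplied).  If no cluster receives both
mates, each aligned mate is its own unit.  This keeps the pairing
information when it exists without discarding reads whose mate falls off
the gene.

## Read recruitment

Mapping is internal: for every (read, cluster) pair sharing at least one
canonical 15-mer, a banded semi-global alignment is computed around the
most-voted seed diagonal (band half-width 15), on both strands, with the
read consumed end to end, free reference ends, and scoring match $+1$,
mismatch $-1$, gap $-2$.  All alignments with edit distance at most
`max_error_rate` (default 0.15) times the read length are retained, so
multi-mapping reads contribute to every plausible cluster.  Deterministic
tie-breaking (diagonal over deletion over insertion in the traceback;
smallest end column) makes the whole fit bit-reproducible.  Alignments
are cached per consensus string, so iterations that change nothing remap
nothing.

The same global-alignment scoring defines *identity* — identical columns
divided by total alignment columns — used both for clustering the
starting database and for merging reconstructed clusters.

## Starting database

`build_reference_db()` prepares an arbitrary FASTA: sequences shorter
than `min_length` (150 nt by default; the cutoff is a package default,
not a property of the method) are dropped, IUPAC ambiguity codes are
resolved deterministically to the alphabetically first compatible base
(R→A, Y→C, ..., N→A), and the survivors are clustered greedily
CD-HIT-style: longest first (ties by id), each sequence joining the
first representative it exceeds `cluster_identity` (0.97) with.
Deterministic resolution was chosen over seeded-random replacement so
that identical inputs give byte-identical databases with no seed
bookkeeping.

An optional pre-screen (`prescreen_reads()`) keeps only reads sharing at
least one canonical 21-mer with the database, rescuing the mate of any
passing read.  On error-free reads drawn from the database its recall is
exactly 1 for $k \le$ read length, so it is purely an accelerator.

## Structural moves: split, merge, prune

After each M step, in this order:

* **Split** (`-p 0.04 -v 0.1`): a position is a *variant* when its
  second-largest base probability exceeds 0.1; when the fraction of
  variant positions strictly exceeds 0.04, one new cluster is split out
  carrying the minor allele at every variant position.  Which minor
  alleles belong together is decided by *read linkage*: the strongest
  variant position anchors the minor haplotype, and alternating
  carrier-classification / allele-voting passes propagate the phase
  through reads spanning phased and unphased positions.  Naive
  per-position "take the second base" splitting produces complementary
  major/minor chimeras in balanced mixtures (each consensus a random
  mosaic of the two haplotypes — a stable EM local optimum we observed on
  about half of random simulations); phasing removes it.  The child's
  prior is the parent's times the mean minor-base probability over
  variant positions, taken from the parent, so prior mass is conserved.
  One split per cluster per iteration bounds growth.
* **Merge** (`-j 0.97`): cluster pairs are scanned in descending-prior
  order and merged when their consensus identity strictly exceeds 0.97;
  the higher-prior cluster survives (ties to the smaller id), priors add,
  and base-probability rows are prior-weighted averages over aligned
  columns (the survivor keeps its own coordinates).  A cluster created by
  a split in the same iteration is exempt until its parent's consensus
  has been re-estimated once; otherwise the child would be folded
  straight back into the still-mixed parent, whose consensus typically
  sits within 3% of both haplotypes.
* **Prune** (`-c 3`): clusters whose mean posterior-weighted depth
  (assigned read bases per consensus position) falls below 3 are removed
  and priors renormalized; `-c 0` disables pruning.  Depth-based pruning
  is our reading of the minimum-depth parameter; consensus masking was
  the alternative.  Fresh splits are exempt for the iteration of their
  creation, before their first mapping.

Initialization places probability 0.97 on the reference base and 0.01
elsewhere, with uniform priors.  Iteration stops early when an iteration
changes no consensus base, performs no structural move, and moves no
prior by more than $10^{-8}$ — the prior-stability condition is added on
top of the structural one so that mixing weights of similar clusters
converge before stopping; it can only delay the stop.  Both the raw
priors $\pi_i$ and the length-normalized relative abundances
$\pi'_i = (\pi_i/l_i)/\sum_k(\pi_k/l_k)$ are reported, since longer genes
attract proportionally more reads.

## Abundance and normalization

Per-sample counts $A_{s,i}$ are reads of sample $s$ whose *primary*
alignment (maximum posterior; ties to the smaller cluster id) is to
cluster $i$; posterior-fractional counting is available behind
`fractional = TRUE`.  Cross-sample normalization is

$$N_{s,i} = A_{s,i} \times \frac{r_{\max}}{r_s} \times \frac{l_{\max}}{l_i},$$

with $r_s$ the number of *input* clean reads of sample $s$ (individual
reads, not pairs — the equation corrects sequencing depth, which is a
property of the input, not of the mapping) and $l_i$ the cluster length.
For the deepest sample and the longest gene both factors are 1 and
$N = A$ exactly.

## Diversity

Taxonomic Hill numbers: $^qD = (\sum_i p_i^q)^{1/(1-q)}$ with the
$q \to 1$ limit $\exp(-\sum p_i \ln p_i)$; $q = 0$ is richness, $q = 2$
inverse Simpson.  Phylogenetic Hill numbers use the Chao–Chiu–Jost
branch formulation: with branch abundances $a_b$ (total relative
abundance of the tips descending from branch $b$) and mean base change
$\bar T = \sum_b L_b a_b$,

$$^qPD = \bar T \Big[\sum_b \tfrac{L_b}{\bar T} a_b^q\Big]^{1/(1-q)},$$

with the analogous $q = 1$ limit; zero-abundance branches are excluded.
This is the $\bar T \times {}^q\bar D$ convention: at $q = 0$ it reduces
to Faith's PD, and on a star tree with unit branches it equals $^qD$ for
every $q$ — two closed forms the test-suite asserts.  The convention is
stated here because the alternative ($^q\bar D$ alone, in units of
effective lineages rather than branch length) is equally defensible.

Weighted UniFrac uses the same branch abundances:
$d_{\text{raw}} = \sum_b L_b\,|a_b(A) - a_b(B)|$, with the normalized
form (default, matching the reference implementation's default) dividing
by $\sum_b L_b\,(a_b(A)+a_b(B))$.  The test-suite checks both forms
against a brute-force descendant-enumeration oracle and against
`phyloseq::UniFrac` to $10^{-9}$.  MNTD is the mean over present tips of
the patristic distance to the nearest co-occurring tip, unweighted by
default with abundance weighting behind a flag (the reference platform's
choice is not determinable).  Trees are consumed as newick — this package
never infers them — and a helper relabels tips from starting-database ids
to reconstructed cluster ids (splits become zero-length polytomies at
their parent's tip).

## Correlation and ordination

`pearson_matrix()` is `stats::cor` column-by-column; constant columns are
reported `NA`, not 0.  Environmental Euclidean distances z-score each
variable first by default (concentrations arrive in mixed units — mM,
µM); zero-variance columns are excluded with a warning.  The Mantel test
correlates lower-triangle entries, permutes one matrix's labels jointly,
and reports the one-sided $p = (1 + \#\{r_\pi \ge r_{\text{obs}}\})/(1 +
n_\pi)$ — with the $+1$ correction $p$ can never be 0, and on identical
matrices it attains its floor $1/(n_\pi+1)$ exactly.  Sidedness and the
correction are package choices.  PCoA wraps `stats::cmdscale` (classical
Gower double-centering); axis signs are fixed by making each axis's
largest-magnitude loading positive, and negative eigenvalues are reported
but excluded from the proportion-explained denominator (no Cailliez
correction — the common default).

## The synthetic-data generator

All validation runs on generated data with known truth, seeded and
bit-reproducible.  `simulate_templates()` substitutes an exact fraction
of positions of a random ancestor, so template-to-ancestor identity is
$1 - d$ by construction.  `simulate_reads()` draws a template per pair
from the abundance vector, a uniform fragment start, a normal insert
length (mean 300, sd 30, clamped into `[read_len, L]`), reverse
complements mate 2, applies independent per-base substitutions at the
nominal error rate, and emits constant quality characters; provenance of
every pair is recorded.  `simulate_layered_design()` emulates a sediment
core: monotone log-linear abundance trends across depth layers
(`up`/`down`/`flat`, spanning a chosen fold change), replicates per
layer, an environmental table (depth with two depth-covarying factors),
and a star phylogeny over the templates.

What the generator deliberately does *not* emulate: platform-specific
error and quality profiles, indel sequencing errors (substitution-only by
default, so consensus accuracy is tested separately from gap handling),
GC and fragmentation bias, chimeric fragments, and contaminant reads.
Tests passing on these fixtures therefore demonstrate the estimator's
correctness under its own model assumptions, not robustness to every
artifact of real libraries.

## Validation suite and problem sizes

The acceptance-style tests run the full stack at desk scale: mixture
recovery uses 5 templates of 1 kb at pairwise divergence ≥ 10% with
abundances (0.40, 0.30, 0.15, 0.10, 0.05) and 20,000 error-free 150-nt
pairs; the split fixture uses a 1-kb template and a 50-SNP variant at
50/50 with 2,000 pairs; the merge fixture two references at 0.98
identity with 1,500 pairs; the layered pipeline fixture 5 templates ×
4 layers × 2 replicates at 200–300 pairs per sample with 0.5% errors;
Mantel calibration uses 1,000 null simulations at 199 permutations.
These sizes were chosen as the smallest at which the estimator's
behaviour is unambiguous (depth ≫ the pruning threshold, binomial noise
≪ the tolerance being asserted).

The split fixture places its 50 SNPs at interior, pairwise non-adjacent
positions.  This is deliberate: under the linear gap scoring above, a run
of adjacent substitutions whose local pattern shift-matches the reference
(e.g. `GTG` → `TGA`) is *strictly better* explained by a 1-bp insertion
plus deletion (score 0) than by three mismatches (score −1), so the
aligner — correctly, per its scoring — emits gapped alignments whose
shifted columns vote the wrong alleles, and one or two consensus bases
can lock.  Similarly a variant at the extreme template end can sit on a
column whose posterior depth falls below 1 in one cluster, freezing its
row.  Spacing the planted SNPs isolates the split mechanism itself from
these two known, documented failure modes; see Limitations.

## Numerical choices, determinism, degenerate inputs

* $\varepsilon$ clamped at 0.75; likelihoods accumulated in logs;
  softmax with max-shift.
* All ties broken deterministically: alphabetical bases, lexicographic
  cluster ids, smallest diagonal/end column in the aligner.
* The EM itself consumes no randomness; a single seed drives the
  generators and the Mantel permutations, with per-stage seeds derived
  from it, so one integer reproduces an entire pipeline run
  (`manifest.tsv` records MD5 checksums of every output; reruns are
  byte-identical).
* Degenerate inputs fail loudly: empty databases, all-pruned cluster
  sets, all-zero abundance vectors, tips missing from trees, quality
  strings that disagree with their sequences.

## Limitations

* Adjacent-SNP runs can be re-scored as short indels under the linear
  gap model (above); affected consensus positions may retain the
  reference allele.
* Template ends have low simulated coverage; columns that never reach
  posterior depth 1 in a cluster keep stale probabilities.
* EM converges to a local optimum; linkage-phased splitting removes the
  chimera mode we observed, but pathological mixtures (e.g. three
  haplotypes at one locus in one iteration) may still need several
  split rounds, and no chimera-detection step exists.
* Merging compares consensuses only; two clusters at the identity
  threshold with genuinely distinct read support are kept separate only
  by the strict inequality.
* The depth parameter is interpreted as a pruning threshold; if the
  original semantics were consensus masking, low-depth behaviour
  differs.
* Hill and UniFrac computations assume the supplied tree covers every
  positive-abundance cluster; there is no placement of novel clusters
  onto a backbone tree.
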