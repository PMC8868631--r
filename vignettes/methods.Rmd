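---
title: "Tracing gene families across the tree of life: methods and design"
author: "m6APhylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing gene families across the tree of life: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6APhylo)
```

## The problem

The RNA N6-methyladenosine (m6A) modification system — writers such as
METTL3/METTL14, readers such as the YTH-domain proteins, erasers such as
FTO and ALKBH5 — is distributed very unevenly across the three domains
of life. Reconstructing how that distribution arose requires a chain of
inferences: find candidate homologues of each component in a panel of
taxa, remove redundancy, confirm the diagnostic catalytic motifs, align
and trim the family, build a supported gene tree, and reconcile it with
the species tree to decide which copies arose by speciation
(orthologues), duplication (paralogues) or horizontal transfer
(xenologues), and where the gene was gained or lost. m6APhylo
implements that chain as composable, tested functions, together with a
simulator that evolves gene families with *known* histories so every
inference stage can be scored against ground truth.

## The synthetic-evolution model

`simulateFamily()` runs a branchwise birth–death–transfer process along
a rooted species tree whose branch lengths double as time. A single
gain places one copy at the root; along every branch each copy draws
exponential waiting times to duplication (rate $\delta$), loss
($\lambda$) and transfer ($\tau$), all per unit branch length; at
speciation nodes copies enter both daughters. Transfers pick a
contemporaneous recipient branch uniformly at random. With
`transferScope = "distant"` donors and recipients are constrained to
branches lying inside a single supergroup, the two supergroups
non-sister, and the recipient terminal — exactly the configuration the
xenologue detector is specified to recover (one sporadic foreign tip
inside a distant clade, the pattern reported for, e.g., bacterial FTO
homologues). With equal birth and death rates the expected copy number
per tip is 1, which the tests verify by Monte Carlo.

Sequences evolve along the true gene tree under uniform replacement
over the 20 amino-acid alphabet: each site draws a Poisson number of
replacement events (rate = substitution rate × branch length), each
substituting one of the other 19 residues uniformly. Two tips separated
by path length $t$ then differ at an expected fraction
$\tfrac{19}{20}\left(1 - e^{-\frac{20}{19}t}\right)$ of sites — a
closed form the tests check by simulation, and the reason the default
distance correction is the matching 20-state Jukes–Cantor form (below).
Configured motif inserts (e.g. DPPW at a fixed position) are held
invariant, mimicking purifying selection on catalytic residues.

What the simulator does *not* emulate: indels (so no alignment
uncertainty), rate heterogeneity across sites and lineages, amino-acid
exchangeability structure (no BLOSUM-like process), domain
architecture, and gene conversion. Passing tests therefore demonstrate
correctness of the inference machinery under a clean substitution
process — not robustness to every artefact of real proteomes.

## Screening, clustering, filtering

`screenHomologs()` scores query–subject pairs by Smith–Waterman local
alignment (BLOSUM62, affine gaps) and converts scores to E-values with
the Karlin–Altschul formula $E = K m n e^{-\lambda S}$, with ungapped
K and $\lambda$ supplied by the scoring scheme rather than estimated
from data: at desk scale determinism matters more than absolute E-value
calibration, and the screening contract depends only on the cutoff
(default E < 0.05). Iterative profile refinement of the original
web-service searches is deliberately not reproduced.

`clusterRedundant()` removes near-duplicates by greedy longest-first
clustering at 98% identity, identity being identical residues over the
*shorter* sequence — the convention of the common greedy clustering
tools, which makes fragments cluster with their full-length parents.
Length ties break lexicographically by id so output is deterministic.
`filterByDomain()` retains a record only if all of its family's
required motif patterns match, with an explicit bypass set for families
whose diagnostic domain is genuinely absent in some species (the
ZC3H13-type exception).

## Alignment and the 30%/10% trimming rule

`buildMsa()` delegates progressive alignment (guide tree plus
profile–profile alignment with affine gaps) to MAFFT behind a stable
interface; its contracts — row order, content preservation, placement
of isolated insertions — are tested against the wrapper.
`trimColumns()` implements the explicit column-retention rule: a column
is kept iff at least 30% of its rows are non-gap letters *and* at least
10% of the letter pairs in the column are conserved. Design choices the
rule's wording leaves open, resolved here:

* "conserved" defaults to *identical* residues, the strictest
  defensible reading; `conserved = "positive"` (substitution-matrix
  score > 0) is available as a configuration switch.
* thresholds compare with ≥ ("at least"); a column with fewer than two
  letters has no pairs and fails the pair criterion by convention;
* `X` counts as a letter for coverage but never certifies conservation.

A brute-force per-column oracle (explicit pair enumeration) must agree
exactly on hundreds of random alignments; the rule is also idempotent
and monotone in both thresholds.

## Distances, neighbor joining, bootstrap, rooting

Maximum-likelihood tree inference with model selection is out of scope;
the package's trees come from neighbor joining over corrected
distances, which for additive inputs provably returns the generating
topology and branch lengths (asserted to 1e-9 on random additive
matrices). Numerical choices:

* default distance correction is the 20-state Jukes–Cantor form
  $d = -\tfrac{19}{20}\ln(1-\tfrac{20}{19}p)$ — the exact inverse of
  the simulator's substitution process; the plain Poisson correction
  $-\ln(1-p)$ and raw $p$-distances remain available.
* Q-matrix ties break by the lexicographically smallest taxon pair, so
  the topology is independent of input order and platform.
* negative NJ branch-length estimates are clamped to zero with the
  deficit moved to the sister edge, preserving all path lengths.
* saturated proportions only arise in bootstrap resamples and are
  truncated just below the correction's domain boundary there;
  user-facing distance calls raise an error instead.

`bootstrapSupport()` resamples columns with replacement and reports,
for each internal branch, the fraction of replicate NJ trees containing
the same bipartition. Supports are keyed by canonical splits, which
makes them invariant to rooting and tip order — `midpointRoot()` (the
default rooting; the underlying studies do not state theirs) and
`rootByReconciliation()` (duplication+loss-minimizing rooting, the
standard alternative when a species tree is available) both carry
supports over unchanged.

## Reconciliation, xenologues, gains and losses

`lcaReconcile()` maps every gene-tree node to the species-tree MRCA of
its descendants' species; a node is a duplication iff its mapping
equals a child's mapping, else a speciation. Pairs of copies are
orthologues or paralogues according to the event at their gene-tree
LCA.

`detectXenologs()` calls a tip a xenologue iff it belongs to a
different supergroup than all other members of its smallest enclosing
clade of at least three tips, that clade's support is at least 0.8 (a
configuration default — the threshold is not a claim about any
published analysis), and the donor supergroup (majority of the other
members) is *distantly related*: operationalised as the donor and
recipient supergroup clades not being sisters on the species tree, the
weakest rule that covers inter-domain transfers while ignoring
sister-group noise. Detection runs to a fixpoint: called tips are
excluded from other tips' clade contexts and the scan repeats, so
transfers stacked into the same region are peeled off one by one.
Two configurations are invisible to this per-tip rule by design: a
transferred lineage that then speciates or duplicates (two or more
foreign tips form their own clade), and a transfer nested inside an
earlier transferred lineage that lands the copy back in a concordant
context. The ground-truth comparators in the tests state this scope
explicitly. Flagged tips are pruned before reconciliation
(`reconcileFamily()`), so one transferred copy does not masquerade as
an ancient duplication, and xenolog-present cells are excluded from
gain placement so a transfer cannot drag a family's origin to the root.

`inferGainsLosses()` applies Dollo parsimony to the presence/absence
landscape: one gain at the MRCA of natively present taxa, candidate
losses at the maximal uniformly absent subtrees below it. Reported
losses are restricted to *lineage-specific* ones — absent subtrees with
at most one internal node (configurable) whose sister retains the gene;
terminal branches always qualify. The restriction exists to avoid
scoring patchy genome quality as deep ancestral losses, which is the
stated purpose of the rule in the underlying analysis; its exact scope
is not stated there, so the depth bound is a documented package choice.

## Motif classification

Catalytic motifs are literal position-set patterns, not probabilistic
profiles, because the evidence they encode is a four-residue consensus:
motif IV is `[DNSH]PP[WFY]` with the Dam-type `EPPV` and the
`NIPY`/`NLPY` variants registered. Class α vs β Rossmann-fold MTases
are separated by motif order (I before IV vs IV before I); the
AdoMet-binding motif I has no published consensus in this context, so
the default is a glycine-rich `[AG]x[AG]x[AG]`, config-overridable.
Group assignment maps NPPF/NPPY → Group I, NIPY/NLPY → Group II, and
NPPF with a PCIF1 family hint → Group III — the I/III split is partly
functional, not sequence-based, hence hint-dependent by necessity.
ALKB-family sites (HXD…H iron, N-Y-R-R cofactor) use spacing windows
that are configuration values, as the published spacings are
figure-derived and family-specific. The YTH aromatic cage check accepts
F/W/Y/L at the three cage columns by default; L is included because one
cage position is aliphatic in some prokaryotic homologues, and the set
is config-removable.

## Structure superposition

`superpose()` derives residue correspondence from a global sequence
alignment of the two chains, fits the optimal least-squares rotation by
the Kabsch algorithm (SVD with determinant correction — reflections are
forbidden), then runs up to five cycles rejecting pairs whose deviation
exceeds 2.0 standard deviations of the current per-pair deviations and
refitting, emulating the refinement behaviour of the common
visualization tools; both knobs are exposed because no published values
exist for them. Two numerical guards: numerically exact fits
(deviations below 1e-8 Å) skip rejection, and rejection never reduces
the correspondence below three pairs (the minimum for a defined
superposition — if a cycle would, the three best-fitting pairs are
kept). Each cycle is provably non-increasing in RMSD over retained
pairs, which the tests assert, along with agreement with an exhaustive
rotation-grid oracle on toy cases and with an independent reference
implementation. Only CA atoms are used: chain-level topology is what is
being compared. The comparisons against the published YTH/McrB/MJECL36
and Dam/RlmJ structures require the PDB coordinate files, which cannot
be redistributed; `inst/extdata/structures/README.txt` lists what to
download and where to put it.

## Problem sizes and reproducibility

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; identical configuration plus seed reproduces
pipeline artifacts byte for byte. The validation suite uses problem
sizes chosen to exercise each contract meaningfully while keeping a
full run interactive: a 16-tip panel (4 Bacteria, 2 Archaea, 4 SAR,
6 Amorphea) with 200 simulated families at $\delta = \lambda = 0.1$,
$\tau = 0.05$, 300-residue proteins (a typical MTase-domain scale) at
substitution rate 0.3 for the event-recovery checks; 500 random
alignments for the trimming oracle; 100 additive matrices for NJ;
100 bootstrap replicates on a 2000-column alignment for the support
sanity check. The bundled 88-taxon panel (17 Bacteria, 6 Archaea,
7 Discoba, 2 Metamonada, 14 SAR, 6 Archaeplastida, 36 Amorphea) is a
synthetic stand-in topology: the published panel's tree lives only in
supplementary material, so the panel ships as configurable input, not
as an asserted topology.

## Known limitations

* On true gene trees, event recovery is exact up to the documented
  undetectable configurations (multi-tip transferred clades, nested
  back-transfers, and families whose local donor context was erased by
  loss — the last can also produce rare spurious xenologue calls for
  orphaned tips whose sister supergroups lost the gene).
* From noisy sequences, duplication-node recovery is limited by NJ
  topology error; near-simultaneous duplications separated by very
  short internal branches are not resolvable at realistic sequence
  lengths, so recovery sits close to the 90% design target and its
  exact value fluctuates by a point or two with the simulation seed.
* The E-value model is ungapped Karlin–Altschul with fixed parameters;
  absolute E-values are not calibrated against any particular search
  engine, only the relative screening behaviour is.
* Reconciliation is parsimony-based; there is no
  duplication-transfer-loss likelihood model and no ancestral
  copy-number posterior.
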