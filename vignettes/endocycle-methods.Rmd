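---
title: "The endocycle model: cell cycles, holobionts and molecular interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The endocycle model: cell cycles, holobionts and molecular interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

endocycle simulates the evolution of an obligate endosymbiosis between two
simple cells: a host and its intracellular symbionts. The model couples
four levels of organization — genome, regulatory network, cell, and spatial
holobiont population — and three channels of molecular interference between
the partners: passive product leakage, evolvable signal-peptide targeting,
and endosymbiotic gene transfer. This vignette describes the model as
implemented, its parameters and their defaults, the numerical choices made
where the design was genuinely open, and what the bundled synthetic
fixtures do and do not demonstrate.

## Genomes and gene regulation

A genome is an ordered "beads-on-a-string" list of three bead kinds:
regulatory genes, binding sites, and passive household genes. The total
bead count is the genome size $L$; genes plus binding sites form the
regulatory repertoire $R$, so household beads number $L - R$. Household
beads never participate in regulation but cost replication time, which is
what makes genome streamlining selectively relevant.

A regulatory gene carries a type label (types 1–5 are the *core* types
g1–g5; labels above 5 denote evolved, non-core genes), a binding sequence
of $B$ bits (default $B = 20$), a 2-bit signal peptide, an integer
regulatory weight $w \in [-3, 3]$ and an activation threshold
$\theta \in [-2, 5]$. A binding site carries only a $B$-bit sequence. Both
ranges are clamped under mutation and configurable; the bit length is a
balance between graded binding affinities and exhaustive testability.
Positions are 1-based in this implementation, "upstream" means lower
positions, and replication proceeds from position 1 to $L$; a bead is
replicated once its position is at most the current fork.

The *regulatory region* of a gene is the maximal contiguous run of binding
sites immediately upstream of it, terminated by any gene bead (household
included) or the genome start. Contiguity makes structural mutations act
locally: deleting or relocating a single bead rewires at most two regions.

Expression is Boolean and stochastic. Each expressed gene contributes a
product with unnormalized binding mass

$$a = c \, s^{d} \times \text{copies},$$

where $d$ is the Hamming distance between product and site sequences,
$c = 10$ and $s = 0.5$ by default, and `copies` is the gene dosage (2 for
beads already passed by the replication fork, 1 otherwise; foreign
deliveries carry one copy each). Per timestep every binding site draws one
occupant from the categorical distribution with mass 1 for "unbound" and
$a_p$ for each product $p$ — so even a perfect-match product binds with
probability $10/11 \approx 0.91$, never certainly, and low-affinity
interactions fire rarely but twice as often at doubled dosage. Sites
sample independently given the pool; there is no product depletion. A gene
is expressed in the next step iff the summed weights of the products bound
in its region reach its threshold. Repression exists only through negative
weights; there is no dedicated repressor-site kind. Weights live on genes
(products), not sites — the model's rates mutate "regulatory weight" per
gene, and products act identically at every site they can bind.

## The cell cycle

The joint expression pattern of the five core types defines the cell-cycle
stage through a configurable stage table of four distinct 5-bit patterns
(defaults below). A cell tracks the ordered set of stages completed since
its last division. A decoded pattern that is the successor of the last
completed stage advances the cycle; any other match stalls it (there is no
regression), except M: decoding the M pattern either triggers division —
if G1, S and G2 were passed in order *and* the genome is fully replicated —
or kills the cell. This premature-mitosis rule is the model's central
selective force: regulation must keep M unreachable until replication has
finished.

While a cell is in S-phase its fork advances by $k$ beads per step, where
$k$ is set by local nutrients (below). Products live exactly one timestep;
expression state is inherited at division (daughters start with the
parent's final expression, a reset fork, and an empty stage history), so
evolved start-up behaviours are visible to selection. Both daughters
mutate independently.

The minimal cycle duration for a genome of size $L$ at replication speed
$k$ is $\tau_{\min} = \lceil L / k \rceil + 3$ (one step each for G1, G2
and M under the one-step-per-stage progression rule), and cell-cycle
efficiency is $e = \tau_{\min} / \tau$ for an observed duration $\tau$.
The formula is this package's own floor; $e$ values are comparable within
this implementation only.

## Mutation

At every division each daughter genome passes through, in fixed order:
per-bead structural operators (duplication, deletion, relocation — each
Bernoulli per bead of the pre-mutation list), per-genome innovations (a
fresh random binding site; a fresh gene with an unused type label, uniform
random sequence, uniform weight and threshold, and no signal peptide), and
per-element value mutations (sequence bit flips, signal-peptide bit flips,
±1 weight and threshold steps, clamped). Household beads undergo only the
structural operators. Duplications insert the copy immediately downstream
of the original; relocations and innovations insert at a uniform random
position. The operators sample the pre-mutation bead list independently,
so a bead hit by both duplication and deletion still leaves its copy —
this keeps the realized per-operator frequency exactly $L\mu$ at any rate,
which the Monte-Carlo oracle tests exploit at 100× inflated rates.

Event counts are drawn as binomials with uniformly sampled positions,
which is identical in law to per-bead Bernoulli draws and fast for the
million-division calibration checks. Default rates are the model's
standard values (per division): $\mu_B = 3.3\cdot10^{-5}$ per sequence
bit, $\mu_S = 1.0\cdot10^{-5}$ per signal-peptide bit,
$\mu_w = \mu_\theta = \mu_{dup} = \mu_{del} = \mu_{rel} = 1.67\cdot10^{-4}$,
$\mu_{b,in} = 1.67\cdot10^{-3}$ and $\mu_{r,in} = 1.67\cdot10^{-4}$ per
genome, and $\mu_t = 2.0\cdot10^{-5}$ per gene for transfer.

## Interference between host and symbiont

Three channels couple the partners' regulatory systems:

* **Leakage.** Every expressed gene leaks a one-copy product into each
  symbiont (from the host) or into the host (from each symbiont)
  independently with probability $l = 0.01$ per gene per symbiont per
  timestep. Influx into a symbiont is therefore proportional to the host's
  expressed-gene count, and influx into the host to the total across
  symbionts. Leaked products never re-leak onward.
* **Targeting.** The 2-bit signal peptide routes a product: `10` host
  only, `01` into every symbiont, `00` no relocation (it stays where it is
  encoded), `11` both compartments. In the bootstrap holobiont every gene
  carries its native tag (`10` on host genes, `01` on symbiont genes), so
  signaling has to evolve through peptide mutations.
* **Gene transfer.** A newly divided host can receive each gene bead of
  each of its symbionts with probability $\mu_t$ (and symmetrically for
  newly divided symbionts from the host); copy-and-paste and cut-and-paste
  are equally likely, the transferred unit is the naked gene bead, and
  insertion is uniform over the recipient. Transferring genes without
  their regulatory regions is what makes transferred genes slow to gain
  regulation.

Foreign products act like native products in every respect: they compete
for binding sites with their own affinity and dosage, and they *define*
the cell-cycle stage if they are bit-identical in sequence to a native
gene of the same core type — so once a partner's core genes have diverged
by even one bit, its products can no longer masquerade in the stage
pattern.

Knockout toggles mirror the assay design: disabling a signaling direction
drops cross-compartment deliveries in that direction while native-
compartment presence is untouched (treating the peptide as `00` instead
would also change native presence for `10`/`01` genes encoded in the
other compartment, which is why that alternative was rejected), and
disabling a leakage direction zeroes $l$ for it.

## Holobionts on a nutrient gradient

A holobiont is one host plus one or more symbionts on a single grid site.
The default grid is 45 × 110, toroidal horizontally and bounded
vertically, with 11 nutrient sectors of 10 rows each; sector influx is
linearly spaced from 10 (top) to 110 (bottom) so that the assay levels 30
and 90 are interior values. All cells of all holobionts in a site's 3 × 3
Moore neighbourhood share its influx: each cell receives
$A = \text{influx} / C$ where $C$ is the neighbourhood cell count, and
replicates $k = \lfloor A / \rho \rfloor$ beads per S-phase step with
$\rho = 5$. Sharing is instantaneous (no depletion state). Under
starvation ($A < \rho$) replication halts entirely; a guaranteed-progress
floor ($k \ge 1$) was tried first and rejected, because with it crowded
neighbourhoods kept replicating at full stall-proof speed, symbiont
division (which needs no free site, unlike host division) never paid a
nutrient price, and symbiont loads grew without bound on saturated
grids. Replication that stops when nutrients run out is what gives the
model's central feedback — more symbionts, less nutrient, slower cycles —
its teeth, and starved cells eventually fall to the premature-mitosis
rule, which is how overloaded holobionts die.

One population timestep is synchronous in state and sequential in
effects: nutrient shares are computed for every occupied site from the
step-start cell counts; each holobiont (visited in randomized order)
builds its foreign pools by targeting then leakage from step-start
expression states and runs one regulatory step for the host and every
symbiont; the resulting events are then applied — symbiont divisions in
place, host divisions into a uniformly chosen empty neighbouring site
(a divided-ready host stalls, frozen, until space frees; placement
conflicts are resolved by processing order), and deaths: premature
mitosis, symbiont loss (a holobiont dies with its host or when no
symbiont remains), and basal death with probability $\delta = 0.002$
per holobiont per step. Basal turnover is not
part of the biological model's statement; some background death is needed
so that space frees for competition, and $\delta$ may be set to 0. At
division, symbionts are distributed over the two daughters independently
with probability 1/2 each; a daughter receiving none is dead on arrival,
so holobionts must maintain at least two symbionts to divide safely.

Determinism: a run draws everything from R's global RNG stream, so
`set.seed()` before inoculation makes event logs bit-reproducible, and
snapshots capture `.Random.seed` so a restored run continues identically.
Event logging and genome archiving consume no randomness.

## The bootstrap holobiont

Evolution runs start from a primitive holobiont whose host and symbiont
genomes are identical (up to their native signal peptides): 64 beads, 50
of them household, and a 14-bead regulatory repertoire — the five core
genes and nine binding sites. The published description of this ancestor
fixes only those summary properties plus viability of the primitive
cycle, so the wiring here is an engineered fixture, tuned until an
isolated cell at rich nutrients (`n_influx = 90`) reliably completes full
cycles:

* **g2 and g5** are constitutively expressed (empty regions, threshold
  0); g5 sits at the very end of the genome so its product dosage doubles
  exactly when replication completes.
* **g4**, the completion gate, requires all three of its low-affinity g5
  sites (Hamming distances 5, 6 and 8) bound in one step
  ($w_5 = +2, \theta_4 = 5$). Before replication finishes this
  coincidence has probability $\approx 1.2\cdot10^{-3}$ per step; after
  the terminal g5 doubles it is $\approx 8$-fold more likely, so S-phase
  exit is coupled — softly, as in any dosage-readout — to replication
  completion.
* **g3**, the mitosis relay, fires only on the gate product (two
  perfect-match g4 sites, $\theta_3 = 3$); nothing else can activate it,
  so the M pattern strictly implies a gate firing one step earlier.
* **g1**, the restart reporter, fires on the relay product (four
  perfect-match g3 sites) and defines the daughters' G1 pattern.

The stage table readable from this trajectory is the package default:
G1 = 11001 (post-division step), S = 01001 (the long replicating phase),
G2 = 01011 (gate step), M = 01101 (relay step). Core sequences are placed
so that the only products able to reach a threshold of 3 (g3, g4) are at
least 12 bits from every site they must not bind, and the ever-present
clock product is 16 bits from the relay sites (two cross-bound clock
products would otherwise sum to the relay threshold and fake mitosis —
the one distance that is safety-critical).

Because checkpointing by dosage is probabilistic, the primitive cycle is
*stochastically* viable: across random seeds roughly 96% of isolated
cells complete five divisions without a premature-mitosis death at
`n_influx = 90`; the remainder die from a pre-completion gate coincidence
or idle after a missed restart window. This leakiness is a property of
the model (dosage readouts cannot be sharp when doubling is the only
signal), matches the ancestor's confinement to rich conditions, and is
why the viability test is judged across a panel of seeds. Populations
tolerate these losses easily; what matters for the ecology is that death
is rare per cycle, not absent.

Genomes serialize to a line-based text format (`#endocycle-genome v1`,
one bead per line) that round-trips bit-exactly; a header comment can
carry the canonical birth expression state, which the generator sets to
the freshly divided pattern (g2, g3, g5 on) — without it a cold-started
cell cannot reach the post-division G1 pattern.

## Assays

`clonal_growth_assay()` measures the equilibrium grid density $N$ of a
single genotype: a uniform-influx arena, clonal hosts and symbionts,
mutation frozen (clonality requires it), configurable interference
toggles, and $N$ averaged over the trailing 20% of the run.
`knockout_panel()` runs the six leakage/targeting knockouts against
baseline and reports $\Delta N$ with a Monte-Carlo standard error over
replicate seeds. `competition()` seeds two populations side by side at
equal densities, freezes mutation (a deliberate choice where the original
design is unstated — a flag reopens it) and runs to fixation or a step
cap. `reconstruct_ancestry()` computes most recent common ancestors of
the survivors — separately for host and symbiont lineages — from the
birth-event log by root-path intersection, and `export_lineage_newick()`
writes the holobiont birth forest as Newick with branch lengths in
timesteps (singleton chains collapsed).

The synthetic fixture suite (`make_test_fixtures()`) adds hand-wired
edge-case genomes: a household-only genome (never cycles, never dies), a
constitutive-M genome (dies immediately by the premature-mitosis rule),
and two interference toys — a "host control" holobiont whose symbiont
clock is natively silent and supplied by a dual-localized host gene, and
its "symbiont control" mirror image, where the host clock is silent and a
second symbiont clock copy is exported to the host. Knocking out the
respective signaling direction measurably suppresses their growth, which
anchors the knockout assay's sign conventions.

## Problem sizes and what the tests show

The test suite builds everything from code at deliberately small scales:
single-cell checks run 2,000-step horizons, population properties use
arenas between 4 × 4 and 15 × 15 for a few hundred steps, Monte-Carlo
calibrations use $10^4$–$10^6$ draws (mutation rates inflated 100× with a
linearity cross-check), and one full-scale run — the default
45 × 110 gradient with all interference channels on — goes to $10^4$
steps. These sizes were chosen so the whole suite completes comfortably
on a single CPU while keeping every statistical check at three-to-four
standard errors of its closed-form expectation.

One property of the primitive ancestor deserves emphasis: it has no
regulatory symbiont-number control. A symbiont's divisions stay inside
the holobiont while a host division only halves the count, so symbiont
numbers rise until nutrient scarcity stops replication; starved cells
eventually fall to the premature-mitosis rule, and the load relaxes.
Under default conditions a 10% inoculum of the bootstrap clone settles
within a few thousand steps into a sparse population (occupied fraction
a few percent, four to five symbionts per holobiont) concentrated in the
rich sectors — primitive holobionts survive, but only just, which is the
selective landscape the long evolution experiments act on. The
population loop is a single compiled pass per timestep (about a
microsecond per cell for regulation) with R-level work only at division
and death events, so a full-scale 10^4-step run takes on the order of a
minute.

Passing tests demonstrate that the simulator implements this model
faithfully and reproducibly; they do not show that any particular control
mechanism evolves. The published long-run outcomes (which coordination
strategy fixes in a replicate, genome-size trajectories, ancestor assay
values) emerge over $10^7$-timestep experiments on evolved genotypes that
are not available in machine-readable form; reproducing them is outside
this package's scope and the claims of its tests.

## Known limitations

* Boolean products with one-step lifetimes; no concentrations, decay
  constants or thermodynamic binding.
* The viability of the bootstrap fixture — and hence of early
  populations — is probabilistic; very poor nutrient sectors are
  population sinks by design.
* Cell-cycle efficiency $e$ uses this package's $\tau_{\min}$ floor and
  is not comparable across implementations.
* The event log records one lineage tree per run; competition between
  separately evolved populations must be assembled through
  `competition()` rather than by merging logs.
* Nutrient sharing has no depletion dynamics, holobionts do not move, and
  products do not diffuse between grid sites.
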