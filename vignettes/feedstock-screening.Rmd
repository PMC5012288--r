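---
title: "Screening microalgae as biodiesel feedstock: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening microalgae as biodiesel feedstock: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoscreen)
```

phycoscreen implements the quantitative core of a strain-level screening
workflow for microalgae as biodiesel feedstock: growth kinetics from batch
time series, fatty-acid (FAME) compositional profiles and the standard
biodiesel-quality indices with an ASTM cetane/iodine screen, Bray-Curtis
UPGMA clustering of profiles, static copper-toxicity bioassay statistics,
and a small 18S rRNA phylogenetics stage. This vignette records the models,
the defaults and the design choices that were genuinely open.

## Growth kinetics

Specific growth rate is the exponential-phase rate constant
$\mu = \ln(N_2/N_1)/\Delta t$ in d$^{-1}$ (input times are hours; the
factor 24 lives in one place), and generation time is
$T = 24\ln 2/\mu$ hours, so $\mu \cdot T = 24 \ln 2$ exactly. A culture
with $\mu \le 0$ has no doubling time and `generation_time()` treats that
as an error rather than returning infinity.

Field practice computes $\mu$ "over a period of exponential growth" without
saying how that period is chosen. `fit_exponential_window()` makes the
choice deterministic and auditable: it scans **every** contiguous window of
at least `min_points` (3) observations spanning at most `max_window_days`
(3 days — exponential growth in these batch cultures rarely lasts longer)
and keeps the window maximising $r^2$ of the least-squares line
$\ln N \sim t$, breaking ties towards the larger window and then the
earlier start. The scan is cheap (a seven-day daily series has under twenty
admissible windows) and reproduces a brute-force oracle exactly in the
tests. Constant curves are reported as $\mu = 0$ with $r^2$ shown as 0.
When a strain has both optical-density and cell-count readings, optical
density is used unless the caller switches `measure` — the data collection
protocol records both without stating which fed the reported rates.
Rounding (two decimals for $\mu$, one for hours) happens only in reports;
internal values keep full precision.

## FAME profiles and biodiesel indices

Fatty acids are named by the field's `C<X>:<Y>` shorthand (X acyl carbons,
Y double bonds), optionally with an omega qualifier `(n-z)` and a
`cis`/`trans` suffix. The parser canonicalises and round-trips; geometric
isomers are distinct species in profiles and clustering but identical for
every index formula, which depends only on chain length and unsaturation.

Profiles are compositional: GC-MS peak tables are normalised to wt% of
total identified FAME after removing the C19:0 internal standard (added for
absolute quantification; it never feeds the indices, which use relative
composition only). Peaks whose label does not parse are excluded with a
warning and the excluded fraction is reported — published relative-abundance
stacks normalise over identified FAMEs only. Whether such wt% values are
area-percent or standard-corrected mass-percent is generally not stated in
screening studies; area-percent is assumed here.

Writing $N_i$ for wt%, $M_i$ for the **methyl-ester** molecular mass
(the transesterified form the GC-MS actually measures; formula
$\mathrm{C}_{X+1}\mathrm{H}_{2X+2-2Y}\mathrm{O}_2$) and $D_i$ for double
bonds:

$$\mathrm{SV} = \sum_i \frac{560\,N_i}{M_i}, \qquad
  \mathrm{IV} = \sum_i \frac{254\,D_i N_i}{M_i},$$

$$\mathrm{DU} = \mathrm{MUFA} + 2\,\mathrm{PUFA}, \qquad
  \mathrm{LCSF} = 0.1\,N_{16:0} + 0.5\,N_{18:0} + N_{20:0} +
  1.5\,N_{22:0} + 2\,N_{24:0},$$

$$\mathrm{CFPP} = 3.1417\,\mathrm{LCSF} - 16.477\ (^\circ\mathrm{C}).$$

Two cetane-number estimators are provided because published screening
tables are not always consistent with a single one: the component-weighted
form $\mathrm{CN} = \sum_i (N_i/100)(-7.8 + 0.302\,M_i - 20\,D_i)$
(default) and the aggregate form
$\mathrm{CN} = 46.3 + 5458/\mathrm{SV} - 0.225\,\mathrm{IV}$, which
diverges from component-weighted values at high IV. The method used is
recorded in the result. Printed CN values in reference tables are therefore
treated as data, not as recomputation targets.

LCSF includes only the **saturated** C16–C24 species (the standard
definition); including unsaturated chains cannot reproduce the very low
LCSF observed for oleate-dominated strains. The ASTM screen applies
CN $\ge 47$ and IV $\le 120$ inclusively, on unrounded values; report
printing mimics table precision (integer CFPP, half away from zero).

## Profile clustering

Bray-Curtis dissimilarity
$\mathrm{BC}(p,q) = \sum_i |p_i - q_i| / \sum_i (p_i + q_i)$ feeds
average-linkage (UPGMA) clustering; merge heights are the merging pair's
dissimilarity (not halved — the cophenetic correlation compared across
studies is scale-invariant, so the height convention is immaterial there).
Exact ties resolve by lexicographic label order: labels are sorted before
clustering so reruns and relabelings agree. Dendrogram fidelity is the
Pearson correlation between original and cophenetic distances; it is 1
exactly on ultrametric inputs.

Node support resamples **fatty-acid species** (the columns of the strains
× acids table, its only exchangeable axis) with replacement, rebuilds the
dendrogram, and scores each original node by the percentage of replicates
containing the same leaf set. The published analogue restricted clustering
to strains sharing a phylotype with at least one other strain; that subset
rule is the caller's input filter, not hard-coded.

## Copper toxicity bioassays

The 72-h static assay measures chlorophyll-a fluorescence (taken as
proportional to biomass; no calibration curve) at 24-h intervals in
triplicate across copper concentrations 0.01–3.2 mg/L plus a control.
Per-replicate growth rates reuse the exponential-window fit restricted to
the assay window (0–72 h). Per concentration,
$\%I = (C - X)/C \times 100$ with $C$ the control mean and $X$ the
treatment mean; percent-of-control is the exact complement. Stimulation is
reported as negative $\%I$, not clipped. A concentration is flagged
no-growth when the mean rate is $\le 0$ or fluorescence fails to rise over
the assay, and is then pinned to $\%I = 100$. Between-strain comparisons
use the pooled-variance two-tailed Student's t-test; two exactly constant,
equal groups return $p = 1$ by convention. EC50 curve fitting is
deliberately out of scope — the assay reports $\%I$ per concentration.

## Phylogenetics stage

The stage consumes an already-aligned FASTA (alignment itself is out of
scope). Sequences with ungapped length $\le 400$ bp are excluded (strict
"greater than"). Alignment cleaning follows the classic block-filtering
parameterisation: gap columns removed (none allowed by default), a column
is conserved when its modal residue frequency strictly exceeds 50% and
flank-conserved at $\ge 85$%, runs of more than eight contiguous
non-conserved columns are rejected, blocks are trimmed to flank-conserved
boundaries, and blocks shorter than ten columns are dropped. Runs and
blocks are delimited in original coordinates, so a removed gap column ends
a block. Cleaning is idempotent and the kept-column map is returned.

Distances are p-distance by default (JC69 optional; the correction is
undefined at $p \ge 0.75$ and reported as `NaN` per pair) with pairwise
deletion of gaps. Trees are built by plain Saitou–Nei neighbour joining,
which is exact on additive matrices; the BioNJ variance-weighted variant
agrees on clean data and is not separately implemented. Negative branch
lengths, possible on noisy matrices, are clamped to zero with the deficit
moved to the sister branch, preserving tip-to-tip paths through the node.
Bootstrap resamples alignment columns (default $B = 1000$) and scores
bipartitions of the original tree.

Phylotypes are demarcated by single-linkage transitive closure of leaves
at patristic distance $\le$ 0.001 substitutions/site. "Branch lengths
$\le 0.001$" could also mean terminal branch lengths or cophenetic depth;
patristic distance is implemented because it is a proper leaf metric and
the only reading that makes the threshold a partition rule. Reproducing a
published 17-phylotype count requires the original sequences and aligner,
so it is an integration check, not a desk-scale test; the desk-scale
evidence is exact recovery on additive matrices and on long simulated
alignments.

## Synthetic data: what it emulates, and what it does not

The generator produces all four input kinds with the statistical structure
each stage assumes, so the pipeline and its parameter-recovery tests run
with no external data. Defaults mirror the study conditions: daily
sampling for seven days (growth), test concentrations 0.01, 0.1, 0.32,
1.0, 3.2 mg/L in triplicate (bioassay).

* **Growth** follows lag → logistic saturation with intrinsic rate
  `mu_true` and multiplicative lognormal noise (optical-density noise is
  scale-proportional). The logistic extension — the source protocol only
  documents exponential growth "up to three days" — exists so the
  window-selection logic has saturation to avoid. No variance information
  is published for these measurements, so the default `noise_cv` is a free
  parameter; 0.05 is used in the recovery tests as a realistic bench-top
  spectrophotometer CV.
* **FAME profiles**: each phylotype draws a Dirichlet base composition;
  member strains perturb it multiplicatively on the log scale and are
  renormalised — the standard compositional perturbation — with
  sub-streams derived per phylotype and strain so adding a strain never
  reshuffles the others.
* **Dose-response** rates follow the log-logistic (Hill) mean
  $\mu(c) = \mu_0/(1 + (c/\mathrm{EC50})^h)$. The source assay fits no
  curve; a monotone parametric family is simply needed to generate
  realistic panels, and the EC50 definition gives the exact
  $\%I = 50$ check. Rates below a floor (0.05 d$^{-1}$) produce flat
  fluorescence, emulating complete inhibition at the top concentration.
* **Alignments** evolve under an equal-rates (Jukes-Cantor) process on a
  random bifurcating tree scaled to a chosen root-to-tip expectation, with
  gap columns injected independently per column and optional tip
  duplication at patristic distance $5\times 10^{-4}$ (below the phylotype
  threshold). Adequacy is "NJ can recover the tree", not sequence realism:
  no rate heterogeneity, base-composition bias or indel process.

Passing recovery tests on these simulations shows the estimators are
correct under their own assumptions; it does not certify performance on
real data with instrument drift, unidentified peaks or alignment error.

## Numerical choices and problem sizes

Fixed seeds make every simulator byte-reproducible; derived sub-stream
seeds stay below $2^{31}$. Window ties use an $r^2$ epsilon of $10^{-12}$.
Test problem sizes are chosen so the whole suite runs in seconds: UPGMA
and NJ oracle equivalence up to 7 leaves (exhaustive behaviour is already
exercised there), topology recovery at 8 taxa × 5000 sites, dendrogram
bootstraps at $B \le 60$ in tests (the default for analyses remains
$B = 1000$).

## Worked example

```{r example, eval = FALSE}
sim <- simulate_fame_profiles(3, 3, within_phylotype_sd = 0.1, seed = 7)
growth <- data.frame(strain = rownames(sim$profiles),
                     mu = c(1.2, 1.1, 1.15, 0.7, 0.75, 0.72, 0.4, 0.45, 0.5))
screen_table(sim$profiles, growth)
d <- bray_curtis_matrix(sim$profiles)
cophenetic_correlation(upgma(d), d)
```

## Known limitations

Unidentified GC-MS peaks are excluded rather than modelled; absolute
quantification against the internal standard is exposed but unvalidated;
the bioassay stage does not model pH drift or metal speciation; the
phylogenetics stage offers no likelihood-based inference; and printed
cetane numbers from reference tables cannot be regenerated without knowing
which estimator produced them (see above).
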