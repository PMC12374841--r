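---
title: "graphddg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{graphddg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The prediction problem

Antibody function is driven by binding affinity for the antigen, and
engineering campaigns need to know how a point mutation shifts that affinity.
The quantity of interest is the change in binding free energy,

$$\Delta\Delta G \;=\; \Delta G_{\mathrm{WT}} - \Delta G_{\mathrm{Mut}},
\qquad \Delta G = RT\,\ln K_d,$$

in kcal/mol, with \(R = 1.9872\times10^{-3}\) kcal/(mol K). Under this sign
convention a mutation that weakens binding (raises \(K_d\)) has a negative
\(\Delta\Delta G\) and is destabilizing. `graphddg` predicts
\(\Delta\Delta G\) directly from the three-dimensional structures of the
wild-type and mutant complexes.

# Model

## Graphs

Structures are reduced to atomistic graphs: nodes are non-hydrogen atoms with
one-hot atom-type features (default element classes C, N, O, S, P, halogen,
metal, other; a richer typing table can be plugged in via a two-column file),
and edges connect atoms strictly less than 4 Angstrom apart, carrying a
one-hot intra/inter-binding-partner feature. The same strict `< 4` rule is
used everywhere a distance threshold appears: interface residues,
inter-partner contacts, and graph edges.

Three graph flavors are available:

* **mutation-site neighborhood** (`mutation_neighborhood_graph()`): the
  mutated residue's atoms, same-chain atoms within 4 A of them, and
  opposite-partner atoms within 4 A of that local set. "Same chain" is read
  literally: sibling chains of the same partner are excluded from the local
  neighborhood, while "binding partner" means all chains of the opposite
  partner. Each graph is computed from its own structure's coordinates (the
  wild-type footprint is not reused for the mutant).
* **full interface** (`interface_graph()`): all atoms of interface residues
  on both partners.
* **CDR neighborhood** (`cdr_neighborhood_graph()`): a three-stage dilation
  from a supplied CDR residue set, used for single-graph binding
  classification of CDR variant libraries.

Node order is deterministic (chain, residue, stored atom order), so
serialized graphs are reproducible.

## E(n)-equivariant convolution

Each EGC layer computes per-edge messages from invariant inputs,

$$m_{ij} = \phi_e\!\left(h_i, h_j, \lVert x_i - x_j\rVert^2, a_{ij}\right),$$

updates coordinates equivariantly,

$$x_i \leftarrow x_i + \operatorname{mean}_j\,(x_i - x_j)\,\phi_x(m_{ij}),$$

and updates node states as \(h_i \leftarrow h_i + \phi_h(h_i, \sum_j
m_{ij})\). Because scalar states see geometry only through squared distances,
predictions are invariant under rotations, translations and node
permutations to machine precision, while coordinates transform covariantly —
both properties are asserted by the test suite rather than assumed.

Design points that the layer definition leaves open, and how this package
resolves them:

* \(\phi_e\), \(\phi_x\), \(\phi_h\) are two-layer perceptrons of the hidden
  width with SiLU activations; \(\phi_x\) ends in a tanh (configurable via
  `coord_tanh`) so coordinate updates stay bounded.
* The coordinate aggregation uses the **mean** over neighbors, which keeps
  deep stacks stable on dense 4 A graphs.
* The node update carries a **residual connection** (`h + phi_h(...)`),
  matching the common reference implementation of this layer family; it
  speeds optimization and leaves the invariance argument unchanged.
* \(\phi_e\)'s first weight matrix is stored in row blocks (for \(h_i\),
  \(h_j\), \(d^2\), \(a_{ij}\)) so node-state blocks are projected once per
  node and gathered per edge. This is algebraically identical to the
  concatenated form and substantially faster on CPU.
* Initial node embeddings are a linear lift of the one-hot atom types;
  \(\phi_x\)'s output layer is initialized at a 1e-3 scale so early
  coordinate updates are gentle.

## Heads

For \(\Delta\Delta G\) regression the network is **Siamese**: the same EGC
stack embeds the wild-type and mutant graphs, each graph is pooled with a
per-dimension max over nodes, and a linear head reads the difference
(WT − Mut). Pooling happens *before* the subtraction because the two graphs
generally have different node counts. With the head bias off (the default),
`siamese_predict(m, g1, g2) == -siamese_predict(m, g2, g1)` exactly and a
graph against itself scores 0 — the sign convention of the label is built
into the architecture. With a bias \(b\), the two orderings sum to \(2b\).

For classification a single graph is pooled and passed through the linear
head plus a logistic; the loss switches to binary cross-entropy with logits.

## Training

Defaults follow the standard recipe for this architecture: Adam, learning
rate 0.001, batch size 32, weight decay 1e-16, edge dropout 0.2 (whole
undirected edges, dropped independently per training step, training only),
three EGC layers, hidden width 128. Per epoch the validation metric (Pearson
r for regression, ROC AUC for classification) is logged, and the returned
model is the checkpoint with the highest validation metric. Training is
bit-reproducible given `config$seed`: initialization, batch order and edge
dropout all flow from it.

The network is implemented on a small tape-based reverse-mode autodiff over
dense matrices (see `R/autodiff.R`). Gradients are verified against central
finite differences, and the layer forward pass against an independent naive
double-loop reference, in the test suite.

# The synthetic data generator

Real experimental \(\Delta\Delta G\) data (SKEMPI 2.0, AB-Bind) and
physics-based synthetic labels (FoldX-style exhaustive interface mutagenesis)
cannot be bundled or recomputed at desk scale, so the package ships a
generator that emulates their *shape*:

* **Complexes**: chains H and L (antibody partner) and A (antigen), default
  30 residues each, built on smooth random walks with 3.8 A CA spacing.
  Residues carry backbone pseudo-atoms (N, CA, C, O) plus 0-6 side-chain
  pseudo-atoms from a fixed per-amino-acid template; counts and radial
  extents scale with published residue volumes (`aa_volumes()`,
  `aa_sidechain_atoms()`). The antigen is docked against the middle of chain
  H by sliding it in until the closest approach sits in [3.2, 3.45] A —
  strictly inside the 4 A interface rule with several residues in range, and
  free of steric collapse. Since each 0.25 A step of the scan changes any
  pairwise distance by at most 0.25 A, the scan cannot jump over that
  window, and every generated complex has a genuine interface (asserted by
  brute force in the tests).
* **Mutations**: side chains are a pure function of (residue type, backbone
  anchor), so `apply_mutation()` rebuilds them exactly; backbones never
  move. Mutating a residue to itself reproduces the input bitwise.
* **Labels**: a deterministic FoldX-like oracle,
  `ddG = alpha_contact * (contacts(mut) - contacts(wt)) + beta_volume *
  (vol_mut - vol_wt) + N(0, noise_sd)`, with defaults
  `alpha_contact = 0.5` kcal/mol per contact and `beta_volume = 0.01`
  kcal/mol per cubic Angstrom. The contact term mirrors the fact that a bare
  contact-count-change baseline carries real signal for physics-based
  \(\Delta\Delta G\) labels; the volume term encodes the steric cost of
  size-changing substitutions. With `noise_sd = 0` the label is an exact
  function of graph-visible geometry, so a correctly implemented model can
  drive held-out correlation high — which is exactly what the acceptance
  suite exploits.

What the generator does **not** emulate: rotamer packing, hydrogens,
backbone relaxation, chemistry-specific interactions (H-bonds, salt
bridges), or the long-tailed label distributions of real FoldX scans. A
model that fits the oracle perfectly has demonstrated that the architecture,
graphs and training loop are correct — not that it predicts laboratory
\(\Delta\Delta G\).

# Curation layer

`filter_skempi()` reproduces the benchmark-construction rules for
SKEMPI-2.0-style tables: antibody-antigen rows only, single-point mutations,
numerically measured binders (qualifiers `<`, `>`, `~` count as imprecise;
`n.b.` or missing mutant Kd as non-binders), duplicate keys collapsed by
kinetic data first, then method rank (SPR > ITC > KinExA > FL > IASP > SP >
CSPRIA > ELISA > BI), then temperature rank (298 > 296 > 303 > 310 > 283 >
"298 (assumed)"), with input order breaking remaining ties; then
\(\Delta G\) from Eq. above and \(\Delta\Delta G = \Delta G_{\mathrm{WT}} -
\Delta G_{\mathrm{Mut}}\). Every removal stage is tabulated in a `report`
attribute and malformed rows are warned about, never silently dropped.

AB-Bind-style tables (`read_abbind()`) get the sign flipped into this
convention and non-binders carried at the −8 kcal/mol sentinel with a flag,
so they can be included or excluded downstream. `flag_non_binder()` uses the
strict −12.2 kcal/mol bound (the lowest experimentally observed value in
SKEMPI 2.0) to mark likely non-binding predictions.
`make_reverse_mutations()` augments a table with label-negated reverse
examples that are flagged train/validation-only; `assign_folds()` honors the
flag by never placing them in a test fold.

# Splits and dataset-design machinery

CD-HIT-style clustering is replaced by a documented deterministic greedy
leader clustering on length-binned strings (identity = matching positions /
length), ordered by descending length then lexicographically. This drops
CD-HIT's word-size heuristics but is exactly reproducible and is checked
against an independent brute-force reference. Antibody and antigen cluster
sets are merged by connected components (union-find) so no merged cluster
links to another through either similarity channel.

Fold assignment distributes whole clusters, largest first with seeded
tie-breaking, to the fold with the largest remaining deficit (80/10/10 or
k-fold), and never splits a cluster; a no-cutoff mode splits members at
random. When cluster granularity cannot hit the targets (one giant cluster),
a warning is emitted and assignment is best-effort. The affinity split sorts
by label — lowest 80% train, next 10% validation, top 10% test — with stable
tie handling; the thresholds it induces are dataset-specific quantiles, not
constants. Clonotype splitting groups by (V gene, J gene) and leader-clusters
fixed-length CDRH3 strings by Hamming distance, `<= floor((1 - cutoff) *
length)` — at 70% on 10-mers, an edit distance of up to 3.

Interface shells: interface residues (CA representatives) are projected onto
their best-fit principal-component plane through the interface centroid;
with R the maximum projected radius, the inner disc of radius \(R/\sqrt 2\)
has the same area as the outer annulus, and a mutation is "inner" iff its
projected radius is at most \(R/\sqrt 2\). The plane fit, centroid center,
max-radius normalization and CA representative are this package's
construction; degenerate (collinear) interfaces fall back to 3-D radial
distance with a logged message.

Diversity subsets: `select_subset()` fills from the largest categories first
(`min`) or round-robins one example per category (`max`), both seeded;
`diversity_profile()` tabulates antibody clusters, substitution types and
partner/shell locations. Label perturbations follow the robustness-protocol
conventions: `shuffle_labels()` permutes a seeded subset of train+validation
labels among itself and reports the *effective* changed share (equal labels
and permutation fixed points do not count); `add_gaussian_noise()` adds
seeded N(0, scale) draws. Test labels are never touched by either.

# Metrics

`metrics_report()` gives Pearson and Spearman correlations, RMSE, and the
standard deviation ratio `sdr = min(sd_true, sd_pred) / max(sd_true,
sd_pred)` using sample (n−1) standard deviations — the ratio is insensitive
to that choice when applied consistently. SDR diagnoses
regression-to-the-mean: a model can hold a high correlation while its
predictions collapse into a narrow band, and SDR falls toward 0 as that
happens. Constant vectors flag correlations as undefined rather than
propagating NaN; one zero standard deviation gives SDR 0. Classification
adds ROC AUC and average precision. `filtered_metrics()` implements the two
standard exclusions — |true| < 1 kcal/mol (small-effect mutations carry
little signal) and true ≤ −12.2 kcal/mol (below the measurable range) — and
reports the retained fraction.

# Problem sizes and numerical choices

The acceptance-style experiments in the test suite and `scripts/acceptance.R`
use a study setup the package treats as its standard desk-scale condition:
100 complexes x 20 interface mutations = 2,000 noise-free oracle-labeled
examples, cluster-disjoint 80/10/10 split, a scaled-down model (hidden 64,
3 layers) trained for 12 epochs with the default optimizer settings. On this
setup the clean run reaches held-out Pearson r ~ 0.98 (validation r crosses
0.9 around epoch 7, motivating the 12-epoch budget), and the 100%-shuffled
run collapses to |r| ~ 0. Epochs beyond ~15 buy little on the noise-free
oracle.

Other numerical decisions: distances are plain Euclidean with strict `<`
comparisons (a pair at exactly 4.0 A is *not* an edge/contact/interface);
altloc handling keeps the first-listed conformer; residue identity is
(chain, number, insertion code); ties in sorting and greedy assignments are
broken by stable input order or a seeded shuffle, never by unstable hash
order; all randomness is drawn through a seed-scoped RNG wrapper that
restores the caller's stream.

## What the label-shuffling control does and does not show here

The robustness protocol includes a full-shuffle control: permute 100% of the
train+validation labels and expect held-out correlation to vanish. On large
corpora that control works because hundreds of thousands of optimizer steps
on shuffled labels drive the network to input-independence. At this
package's desk scale it does **not** vanish: the oracle label is largely a
monotone function of the mutation's size change, an axis that a Siamese
max-pooled EGNN partially encodes even at random initialization, and
\(\le 30\) epochs on 2,000 examples (\(\le\) 1,500 steps) are far too few to
unlearn it. In our runs the shuffled-label held-out correlation wanders with
the checkpoint lottery while the prediction spread collapses (the expected
narrowing-distribution signature). The acceptance machinery computes and
reports the shuffled-run correlation honestly; treat it as a scale
diagnostic, not as evidence of label leakage.

# Known limitations

* The generator's pseudo-atoms have no chemistry; atom-type features reduce
  to element classes on fixtures (side-chain pseudo-atoms are all carbon).
* The exact atom-type vocabulary used with real structures is configurable
  but defaults to 8 element classes; a richer published scheme can be loaded
  from a file.
* CDR extraction and antibody numbering are out of scope: clustering
  operates on caller-supplied (already numbered/concatenated) strings.
* The greedy leader clustering is not bit-compatible with CD-HIT; it is a
  deterministic, testable stand-in implementing the same cutoff semantics.
* Training is CPU-bound R; it is sized for desk-scale studies (thousands of
  examples), not for million-mutation corpora.
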