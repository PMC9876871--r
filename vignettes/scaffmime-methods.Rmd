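---
title: "Designing peptidomimetics on bridged polycyclic carbon scaffolds: methods"
author: "scaffmime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing peptidomimetics on bridged polycyclic carbon scaffolds: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design problem

Protein-protein interfaces are poorly served by conventional flat,
aromatic-rich screening compounds. A class C peptidomimetic replaces the
peptide backbone entirely with a synthetic scaffold whose substituents
reproduce the spatial arrangement of the peptide's side chains. Scaffolds
rich in sp3 centres -- saturated, bridged tri- and tetracyclic cages --
can position three substituents in many three-dimensional arrangements
while staying rigid enough to avoid large entropic penalties on binding.

`scaffmime` implements a two-stage design route:

1. **Stage 1 (geometry):** exhaustively enumerate bridged tri-/tetracyclic
   all-carbon ring systems, filter them by conformational strain, decorate
   them with three methyl "attachment points", and rank the resulting
   skeletons by how well their attachment vectors (ring carbon to methyl
   carbon) superpose onto the C&alpha;&rarr;C&beta; vectors of the target
   peptide conformation, scored by the sum of squared deviations (SSD, in
   &#8491;&sup2;) over the six paired atoms.
2. **Stage 2 (chemistry):** convert the chosen all-carbon skeleton into
   chemically meaningful candidates by introducing heteroatoms and
   unsaturation with a SMILES-to-SMILES transformer encoder--decoder that
   was trained to invert *carbonization* (the reduction of a decorated
   scaffold to its carbon skeleton).

## Stage 1: scaffold enumeration

### Generation

Enumeration starts from six bicyclic seed systems assembled from 5- and/or
6-membered rings (fused: bicyclo[3.3.0]octane, bicyclo[4.3.0]nonane,
bicyclo[4.4.0]decane; bridged: bicyclo[2.2.1]heptane,
bicyclo[2.2.2]octane, bicyclo[3.2.1]octane). A fragment of `m` carbon
atoms is attached as a path between every valence-compatible pair of ring
atoms, producing tricyclic systems; a second fragment of `n` carbons
applied to the tricyclic intermediates (whose fragment atoms are by then
ring atoms themselves) yields tetracyclic systems. The `(m, n)`
combinations are chosen so final systems carry 10--14 carbons; `n = 0`
means the product stays tricyclic. Products are deduplicated by a
canonical graph key (BLISS canonical labelling on a bond-subdivided,
colour-augmented graph), globally across seeds, and checked against a
pairwise VF2 isomorphism oracle in the test suite.

### Conventions, and why they are explicit flags

The qualifying definition -- "tricyclic or tetracyclic bridged system of
5-/6-membered rings, 10--14 carbons" -- leaves real choices open, and the
package exposes each as a configuration flag with a documented default:

* `ring_size_whitelist` (default `{5, 6}`): applied to the SSSR ring-size
  multiset of final products. SSSR is computed as a minimum cycle basis
  (shortest cycle through every bond, greedy GF(2)-independent selection).
* `require_bridged` (default `TRUE`): a system qualifies as bridged when
  some atom pair is joined by three or more internally vertex-disjoint
  paths each with at least one intermediate atom. Purely edge-fused and
  purely spiro-joined systems fail this test.
* `allow_spiro` (default `"tetracyclic"`): whether a fragment may close
  both its ends onto a *single* ring atom, creating a spiro ring of
  `k + 1` atoms. An extensive convention sweep (see
  `convention_sweep()`) showed that the strict distinct-pair reading
  undercounts the size of this scaffold class relative to what a
  generation pipeline of this kind typically reports, while permitting
  spiro closures at the second extension stage lands within a fraction of
  a percent; the default reflects that reading. Note that spiro closures
  mostly produce intermediates: a final product that is purely
  spiro-joined is still removed by the bridged filter.
* `allow_zero_atom_bridge` (default `FALSE`): direct bonds as zero-atom
  fragments. Under the default ring whitelist this adds no products (every
  chord closes a ring smaller than five atoms in this carbon range), which
  is why it is off by default.

Under the default convention the enumerator produces 1341 unique systems
in a few minutes on one CPU. `convention_sweep()` reports the count under
every flag combination so any reference count can be located in the
convention space.

### Strain filter

Each system is embedded in 3D with Open Babel (`obabel --gen3d`, which
also force-field-relaxes the geometry) and scored with MMFF94
(`obenergy`); systems whose minimum conformer energy exceeds
`energy_threshold` (default 100 kcal/mol) are discarded, as are embedding
failures. This is an open-tooling strain proxy: absolute MMFF94 energies
are not transferable to other force fields, so the threshold is a
configurable parameter rather than a universal constant, and counts
downstream of this filter are implementation-specific by design.

### Attachment points

Three methyl groups are placed on each retained core: all multisets of
three positions (geminal pairs allowed), subject to carbon valence and to
at most one quaternary carbon (`max_quaternary = 1`) for synthesizability.
Symmetry-equivalent placements collapse under the canonical key;
correctness is established against brute-force orbit enumeration in the
tests. The methyl caps later play the role of C&beta; atoms during
superposition, with their ring carbons playing C&alpha;.

## Stage 1: superposition and ranking

A peptide query holds C&alpha;/C&beta; coordinates of exactly three
residues (glycine, having no C&beta;, is rejected). For a skeleton
conformer, the six paired points (attachment core &harr; C&alpha;, methyl
&harr; C&beta;) are superposed for each of the 3! residue-to-attachment
assignments with the Kabsch algorithm (SVD-based least-squares rotation;
reflections excluded because molecules are chiral objects), and the
assignment minimising the unweighted SSD wins; ties break by
lexicographic assignment order. Degenerate (near-collinear) point sets
are still solved and flagged. Library ranking takes the best SSD per
skeleton over its conformers, ascending.

The default of one conformer per skeleton is a deliberate deviation from
a conformer-ensemble treatment: these bridged cages are conformationally
rigid, and the deterministic single-conformer embedding keeps ranking
reproducible; `n_conformers > 1` switches to Open Babel's conformer
search when flexible skeletons are supplied.

Kabsch correctness is pinned in the tests by (i) exact recovery (SSD
&approx; 0, proper rotation) under planted rigid transforms, (ii)
agreement within 1e-3 &#8491;&sup2; with a hierarchical rotation-grid
search refined to 0.5&deg; resolution, and (iii) planted-skeleton
recovery: a query constructed from a library skeleton's own attachment
geometry ranks that skeleton first.

## Stage 2: training data

### Corpus construction from compound libraries

From a library compound, the *target* structure keeps the ring framework
(rings plus linkers, obtained by iteratively pruning terminal atoms) and
the first shell of atoms directly bonded to it -- each first-shell atom
keeping its original bond order into the framework, so an exocyclic
carbonyl survives as `=O` while an ester's distal atoms are trimmed to a
hydroxyl. Compounds that are acyclic, contain rings of more than eight
atoms, elements outside {C, N, O, S, F, Cl, Br, I}, or atoms with more
than four heavy neighbours are rejected; charges are neutralized first
and the largest covalent fragment is used. The *source* structure is the
carbonized target: all heteroatoms become carbon and all bond orders 1,
with kekulization performed before carbonization so no aromatic flags
survive. Pairs are deduplicated on the joint canonical
(source, target) key.

### The synthetic corpus

Because multi-million-compound libraries are neither shipped nor
downloaded here, a seeded generator emulates the corpus: skeletons from
the packaged pool are decorated by swapping ring/substituent carbons to
N/O/S where valence permits (per-atom probability `p_het = 0.2`) and
promoting single bonds to double bonds where both ends have spare valence
(per-bond probability `p_unsat = 0.15`); the source is the carbonized
decoration, so `carbonize(target) ≅ source` holds by construction
and is re-verified over every emitted pair. The defaults give roughly
2--4 heteroatoms and 1--2 double bonds per 13--17-atom scaffold, similar
in density to ring-framework extracts of drug-like libraries. What the
generator does *not* emulate: the long tail of rare ring systems, aromatic
subsystems larger than single rings, halogen decoration statistics, and
real-library fragment frequency biases. Green tests on this corpus
therefore demonstrate that the machinery (extraction, pairing, model,
metrics) is correct and that the model family can learn the
carbon-to-decorated mapping; they do not certify chemistry-space coverage
of any particular external library.

### Pairing and augmentation

Training strings are made positionally compatible before the model ever
sees them. For a structure pair, target SMILES are written rooted at each
atom with randomized neighbour order; the matching source string is the
carbonized molecule written with the *same* traversal, so the two strings
differ only where chemistry differs ("N" vs "C", an inserted "=", a
dropped "l" of "Cl"). Among candidates the (source, target) pair with the
smallest character-level Levenshtein distance is selected (ties: shorter
target, then lexicographic). The test suite checks this selection equals
the exhaustive minimum over all rooted writings.

The character-level global alignment (match = 1, gap and mismatch = 0 --
i.e. a longest-common-subsequence alignment) is used for inspection and
for the gap bookkeeping; its traceback prefers score-consistent diagonals
first and then source gaps, which keeps substituted characters aligned
and confines gaps to the source string for carbonization pairs (verified
at the 99% level on generated corpora). Gap characters are a pairing
device only: the model is trained on gap-free strings, since a literal
"-" token would corrupt SMILES grammar. Alignment and edit distance work
on characters while the model vocabulary uses multi-character atom tokens
("Cl", "[nH]", "%12") -- two deliberate granularities.

The train/validation split (90/10) happens *before* augmentation, so no
structure contributes strings to both sides; each side is then augmented
about `k_augment`-fold and deduplicated on the string pair.

## Stage 2: the sequence model

The model is a standard transformer encoder--decoder over SMILES tokens:
learned token embeddings scaled by sqrt(d) plus sinusoidal positional
encodings; multi-head scaled dot-product attention; post-sublayer
residual + layer normalisation; ReLU feed-forward blocks; teacher-forced
token-level cross-entropy; Adam with a fixed learning rate. The default
profile uses 512-dimensional embeddings, 8 heads, 3 encoder and 3 decoder
sub-layers, a 512-unit feed-forward block and 30 epochs. A "test"
profile (64 dimensions, 4 heads, 2 sub-layers, 64 feed-forward units)
exists so the full pipeline trains on one CPU in minutes; it is the
profile used throughout the test suite. Implementation notes:

* forward and backward passes are hand-written in R over
  `(batch x time) x d` matrices, with batched attention kernels in C++
  (RcppArmadillo); analytic gradients are verified against numerical
  differentiation in the test suite, which pins every layer's backward
  pass at once;
* all randomness (initialisation, shuffling, dropout, sampling) draws
  from R's RNG under an explicit seed, so identical seeds give identical
  loss histories and identical samples;
* dropout defaults: 0.1 for the paper profile, 0 for the desk-scale test
  profile (small corpora benefit from the capacity);
* sequences are bucketed by length into padded batches; padding is masked
  in attention (additive -inf masks) and excluded from the loss.

Sampling draws tokens from the softmax at temperature 1.0 (the learned
distribution; `temperature <= 0` selects greedy argmax) in waves until
the requested number of unique, valid, canonical structures is collected
or an attempt budget (20x by default) is exhausted -- invalid strings are
kept in the raw list because they are exactly what the validity metric
measures.

### Quality metrics

Over a generation run: **validity** is the fraction of raw samples that
parse (strict: Open Babel parse plus standard-valence check);
**retention** is the fraction of unique structures whose carbonized form
is graph-isomorphic to the input skeleton -- because isomorphisms
preserve degree, terminal substituents necessarily map onto the methyl
caps, so ring systems and substituent positions must both match;
**novelty** is the fraction of unique canonical strings absent from the
training targets. With zero valid structures, retention and novelty are
reported as 0 (logged convention). Validity is defined over raw samples,
not unique strings.

The aligned-augmented representation exists because canonical string
pairs make the task needlessly hard: the tests confirm that augmented
pairs have far smaller mean edit distance than canonical pairs and that
validation loss under aligned-augmented training is at most that of
canonical training at equal epochs.

### Synthetic accessibility

The SA score follows the fragment-contribution scheme: a frequency term
(mean log-frequency of atom-centred circular environments, radius 0--2,
compared within each radius) minus penalties for size, bridged and spiro
ring complexity and macrocycles, plus a symmetry bonus, mapped to the
conventional [1, 10] scale (1 = easy). The reference frequency table is
built from a packaged list of ~120 ubiquitous organic structures rather
than an external fragment database, so absolute values are calibrated
internally to this package: simple aromatics score around 2--3, bridged
cages 5--8, decorated cages higher. Orderings are meaningful;
cross-package absolute comparisons are not.

## Numerical choices and edge cases

* Parse failures are typed values, never exceptions, so validity
  statistics survive arbitrarily malformed model output; an empty string,
  unbalanced ring bond, unsupported element or valence violation each
  carry a reason code.
* Canonical SMILES determinism rests on BLISS canonical labelling with
  fixed global colour codes (element x charge; bond orders via dummy
  subdivision vertices), so keys are comparable across graphs and
  sessions.
* Kabsch uses the SVD sign correction `det(V U^T)` to exclude
  reflections; degeneracy is flagged when the smallest singular value
  falls below 1e-8 relative to the largest.
* The strain filter treats embedding failure as rejection with a counted
  log entry, never as an error; `obenergy` failures yield `NA` and
  likewise reject.
* Skeleton embedding cross-checks the heavy-atom bond set of the 3D block
  against the input graph and refuses silently reordered geometry.
* Enumeration dedup containers are hashed environments; order
  independence (permuting the seed list) is asserted in the tests.

## Problem sizes used in the test suite

The suite exercises the pipeline at desk scale, chosen so a complete run
fits comfortably on a single CPU: enumeration at the default convention
(~1.3k systems); oracle comparisons on cores of up to 12 atoms; 1000
random triples for the edit-distance metric axioms; 20 fixture pairs for
the exhaustive pairing oracle; and a 20-pair corpus (one decoration per
distinct skeleton, so sources are unique and greedy reproduction is
well-posed) for the memorization check.

The generative experiment trains on a 2000-pair synthetic corpus whose
skeleton pool holds 21 decorated skeletons from each of the first 100
enumerated cores (~1600 distinct skeletons, so the source-to-target
mapping is nearly one-to-one, as in library-derived corpora), with
4-fold augmentation, the test profile for 15 epochs at batch size 96
under a cosine-decayed learning rate; generation quality is measured on
20 held-out skeletons built from later, disjoint cores, sampling 100
structures each at temperature 1.0. The representation comparison
trains the canonical-pair model for 5 epochs and compares validation
losses at the shared epoch count.

### Why string validity saturates at desk scale

For outputs of ~42 tokens sampled at temperature 1.0, overall validity
v requires a mean per-token off-grammar probability mass
&epsilon; with (1 &minus; &epsilon;)^42 &asymp; v — about
0.25% for v = 0.90. The desk-scale model plateaus roughly 0.1 nats/token
above the corpus' intrinsic conditional entropy (~0.33 nats/token from
the stochastic decoration process), which corresponds to
&epsilon; &asymp; 1.5% and validity around 0.5 — the measured value.
Closing that gap is a capacity-and-data effect (the full-scale profile
has 64x the parameters and trains on far more pairs), not an
implementation defect: scaffold retention *among* valid outputs exceeds
0.9 on held-out skeletons, the memorization oracle reproduces a small
corpus exactly, and gradients are verified numerically. Raising the
feed-forward width, augmentation multiplicity (3/4/16-fold at matched
compute) and schedule variations all plateau at the same validation
loss, consistent with this analysis.

## Known limitations

* The enumeration convention space is explicit but the package cannot
  prove which combination an external reference used; `convention_sweep()`
  is the tool for locating one.
* MMFF94 strain energies gate the 3D database; molecules outside MMFF94
  parameterisation would be silently rejected rather than scored.
* The transformer is CPU-bound R + BLAS; the paper-scale profile trains,
  but slowly -- the package is not a GPU training framework.
* The SA calibration is internal; use it to rank candidates, not to
  compare against fragment-database-backed scores.
* No stereochemistry: skeletons carry no chiral information by
  construction, and generated structures are evaluated as constitutional
  graphs.
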