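---
title: "Methods: multi-omics microbiome integration in metaomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics microbiome integration in metaomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

metaomix implements the bespoke computational stages of an integrated
multi-omics microbiome analysis: building a metaproteomics (MP) protein
search database from an amplicon (AS) taxonomic profile, assigning
peptide-level taxonomy by lowest common ancestor (LCA), per-feature
linear-model differential abundance at every omics layer, pathway-level
integration of log2 abundance ratios across layers, and a joint multi-block
ordination. This vignette explains the models and procedures, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate. Everything stated here is computed by the
package's test suite or its acceptance script; no external data are
required.

## 1. Amplicon profile and database construction

ASV counts are aggregated to a user-chosen taxonomic rank by summing counts
over each ASV's rank-level ancestor; ASVs whose lineage lacks that rank are
pooled into an `Unclassified` feature, so per-sample totals are conserved
exactly. Taxa are then ranked by the **mean of per-sample relative
abundances** (default). Ranking by raw total counts is also available
(`rank_by = "total_count"`), but the mean-relative default is preferred
because total counts would let a single deeply sequenced sample dominate
the selection; both rules tie-break lexicographically so results are
deterministic. `Unclassified` never enters the top-*n*: no proteome can be
retrieved for it.

The database builder collects, for each selected taxon, all proteomes a
`proteome_source` can provide (the bundled implementation serves a local
`<root>/<taxon>/<genome>.faa` directory; a remote source is a documented
lookup contract, deliberately not bundled because remote retrieval depends
on database snapshots and is not reproducible). Records with empty or
invalid sequences are dropped. Redundancy removal is **exact full-length
sequence identity** — no clustering below 100% identity. The first record
in collection order survives; its EC/KO annotation sets become the union
over its duplicates, and, critically, the *full set of source taxa* is
preserved on the surviving record. Discarding duplicate taxa would corrupt
LCA assignment later: a peptide from a sequence shared by two genera must
map to their common ancestor, not to whichever genus happened to be
collected first. An optional host proteome is appended and a second global
deduplication pass runs over the merged set (microbial record wins ties by
the same first-in-order rule); whether host proteins should be deduplicated
against microbial ones is a genuinely open design point, and the global
pass was chosen so the database never contains two identical sequences.

## 2. Peptide taxonomy

Instead of delegating peptide taxonomy to an external service backed by a
reference proteome, metaomix assigns peptides **against the database it
constructed**: the search space and the taxonomy assignments are then
self-consistent, which matters because database content directly drives MP
outcomes. The database is digested in silico with the trypsin rule (cleave
after K or R, except before P), missed cleavages ≤ 2, peptide length 7–45
residues — typical MS practice — and I/L equated by default because leucine
and isoleucine are isobaric and indistinguishable by mass spectrometry. All
of these are exposed in `digest_params()`.

The peptide index maps every digested peptide to the union of protein ids,
source taxa, EC numbers and KO ids over all proteins containing it. The
union (rather than intersection) rule for EC/KO was chosen because
annotation sets are sparse; intersections would be empty too often to be
useful. A peptide's taxon is the LCA of its taxon set: the deepest node
that is an ancestor-or-self of every member, computed as the last common
element of the root paths. Peptides absent from the index are flagged
`unmapped`, never an error — an identification list may legitimately
contain peptides outside the database. Abundance is peptide-level spectral
counting; no intensity quantification and no protein inference.

Taxon tables credit each peptide's counts to the rank-level ancestor of its
LCA; peptides whose LCA lies *above* the requested rank go to an
`Unclassified_at_<rank>` bucket so totals are conserved.

## 3. Differential abundance

Each feature is fit by ordinary least squares on the transformed abundance
with phenotype plus covariates, with two-sided t tests on the coefficients
and Benjamini–Hochberg correction across features within each model term.
Linear models were chosen deliberately — no zero-inflated, negative
binomial or random-effects machinery — keeping the stage transparent and
exactly equivalent to the classical equal-variance t test in the two-group,
no-covariate case (the test suite asserts this identity to 1e-10).

Defaults: total-sum scaling (TSS), log2 transform, prevalence filter 0.1
(a feature must exceed the abundance threshold in ≥10% of samples). When
the matrix contains zeros, a pseudocount of `pseudocount × min(nonzero)`
is added before log/CLR; the default multiplier 0.5 makes this the
"half-minimum" convention. On strictly positive data no pseudocount is
added, so the transform is the plain log2. The CLR option subtracts the
per-sample mean of the log values (column means of the output are 0 by
construction). Degenerate inputs are surfaced, not papered over: a
rank-deficient design names the collinear terms, fewer than 3 residual
degrees of freedom is an error, and zero-variance features are skipped
with a ledger entry. q-values use `stats::p.adjust(method = "BH")` with
NaN p-values propagated and excluded from the number of tests.

### What the recovery experiment measures

The planted-effect experiment deserves care because counts are
compositional. If a genus with baseline proportion $p$ is boosted 4-fold in
group B, the *relative* abundance of that genus becomes $4p/(1+3p)$ — the
other taxa shrink to make room — and a log-TSS linear model estimates the
group difference of **expected log proportions**, which under the Dirichlet
sampling model is

$$\Delta = \frac{\psi(c\,p_B) - \psi(c\,p_A)}{\ln 2},$$

with $\psi$ the digamma function and $c$ the Dirichlet concentration. The
generator therefore records this transformed-scale truth alongside the raw
planted log2 fold change, and recovery is judged against it. Two practical
consequences shaped the experiment design: the affected genus must be
prevalent enough (baseline ≈ 14% here) that its counts are never zero —
otherwise the pseudocount, not the effect, dominates the estimate — and
closure bias means the naive value $\log_2 4 = 2$ is *not* the estimable
truth for an abundant taxon.

## 4. Pathway-level integration

Features of each omics layer are aggregated to shared function identifiers
(KO and EC). A feature annotated with $k$ identifiers contributes its full
abundance to each (the KEGG-mapper convention); `split_weights = TRUE`
divides it equally instead. The layer matrix is then total-sum scaled per
sample — the "fold change normalization" step, interpreted as relative
abundance scaling because cross-layer ratios must be library-size
invariant — and each identifier's value is
$\log_2\big((\bar{x}_B + \varepsilon)/(\bar{x}_A + \varepsilon)\big)$ over
group means. The pseudocount $\varepsilon$ defaults to half the smallest
nonzero normalized value in the layer, guaranteeing finite ratios while
vanishing relative to observed abundances; as $\varepsilon \to 0$ the ratio
converges to the exact mean ratio on positive data. Swapping the groups
negates every ratio, and multiplying any single sample's counts by a
constant changes nothing — both properties are asserted exactly in tests.

Split-node tables place these per-layer ratios side by side on pathway
nodes: a node's cell in a layer is the mean (or max-magnitude, by option)
of the ratios of the node's identifiers present in that layer, and is
empty exactly when none is present. Whether a node should show one
representative feature or an aggregate is not externally fixed; the mean
is the default because it is symmetric and does not privilege extreme
features. Rendering on curated pathway graph images is out of scope — the
export is a node × layer heatmap (diverging palette centered at 0, red =
up in group B, green = down) plus a full-precision TSV companion that
round-trips bit-exactly.

## 5. Joint ordination

The joint visualization is a **multi-block principal-component
ordination**: per block (layer), CLR transform (half-min pseudocount when
zeros are present), center each feature, scale the block to unit total
variance so no layer dominates by dimensionality or scale, concatenate
along features, and take the SVD. Sample scores are $U\,\mathrm{diag}(d)$;
loadings split back per block; numeric covariates project as correlation
arrows and categorical ones as level centroids. Axis signs are fixed by
making the largest-magnitude loading on each axis positive, so results are
deterministic. With a single untransformed, unscaled block this reduces
exactly to principal components (asserted against an eigendecomposition to
1e-8).

This is an intentional substitution: model-based compositional integration
estimators serve the same plot but are a separate methodology; metaomix
implements the transparent spectral version and labels it as such. No
attempt is made to match any other tool's coordinates numerically.

## 6. Synthetic data: what it does and does not emulate

The generators produce, deterministically from a seed: a genus-level
taxonomy with a proteome directory and optional host; a two-group ASV
study; per-sample peptide identification lists; and annotated MG/MT/MP
layer matrices with a pathway definition.

* **Counts** are Dirichlet-multinomial around a geometric base composition
  (concentration 50 — strong but realistic overdispersion for microbiome
  count data), with multiplicative group effects applied before
  renormalization and sequencing depths drawn uniformly from a configured
  range. Metadata carry a 2-level phenotype, a numeric covariate (age) and
  a 2-level covariate (sex), matching the two-group-with-covariates designs
  the pipeline targets.
* **Proteins** are uniform random over the 20 amino acids with a configured
  fraction of cross-taxon duplicated sequences recorded in a truth file.
  This is adequate for digestion, deduplication and LCA logic; it makes no
  claim of biological realism (no homology structure, no codon or
  composition bias).
* **Peptide identifications** are sampled from each taxon's in-silico
  digest with probability proportional to the taxon's relative abundance —
  emulating spectral counting, but not spectra, search-engine scoring or
  FDR competition. Consequently the database-merging experiment reproduces
  the *uniqueness erosion* mechanism (shared sequence content makes
  previously taxon-unique peptides ambiguous), not score competition.
* **Layer matrices** are log-normal abundances (sdlog 0.2 around
  feature baselines) with planted per-layer KO log2 ratios in a truth
  table.

Passing tests on these fixtures demonstrates the correctness of the
algorithms and the calibration of the statistics under the stated models;
they do not demonstrate robustness to real-data pathologies such as
contamination, batch effects, ragged taxonomies or annotation errors.

## 7. Problem sizes and numerical conventions

The test suite and acceptance script run at deliberately desk-scale sizes
chosen to exercise every code path with tight oracles: communities of 6–12
genera × 1–2 genomes × 8–20 proteins; studies of 10–80 samples; 500
features for the null-calibration run (n = 40, raw p < 0.05 rate required
within [0.03, 0.07], the ±2 SD binomial band); 100 random sequences against
the brute-force digestion oracle; ≥ 240 random LCA cases against the
path-intersection oracle. Matrix outputs that must round-trip are written
with 17 significant digits; comparisons against closed forms use 1e-10 or
tighter; BH monotonicity and TSS column sums are asserted to 1e-12.
Ties — in taxon ranking, in biplot feature selection — always break
lexicographically.

## 8. Known limitations

* OLS on transformed abundances; no random effects for repeated measures,
  no zero-inflation modeling.
* Exact-identity deduplication only; no 90/95% identity clustering.
* The peptide stage indexes only tryptic peptides within the configured
  length/missed-cleavage budget; semi-tryptic or modified peptides are
  unmapped.
* Remote proteome retrieval is a contract, not an implementation; counts
  from remote sources drift with database snapshots and are expected to
  differ between retrieval dates.
* The run driver's content-hash skipping tracks declared stage inputs; an
  out-of-band edit of an intermediate output invalidates only stages that
  declare it.
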