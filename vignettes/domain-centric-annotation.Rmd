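---
title: "Inferring and using domain-centric ontology annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and using domain-centric ontology annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcanno)
```

## The problem

Ontology annotation effort concentrates on full-length proteins, but
protein structural domains (SCOP superfamilies and families, Pfam and
InterPro entries) are the recurring functional units. `dcanno` transfers
ontology knowledge from proteins to domains statistically: a domain that
co-occurs with an ontology term across many proteins, far more often than
chance would allow, earns that term as an annotation. The package covers
the whole path — ontology ingestion, corpus counting, inference,
propagation — plus the downstream use of such tables: domain-based
ontology enrichment analysis.

## The model and its assumptions

### Correspondence matrix

The corpus is the set of proteins present in *both* inputs (annotated and
domain-assigned); call its size $N$. Both a protein's terms and its domains
are treated as presence/absence sets:

* a protein contributes at most 1 to any count no matter how many copies of
  a domain it carries — the model counts *proteins*, not domain instances;
* each protein's term set is closed under ontology ancestors *before*
  counting (the True Path Rule at protein level). Without this closure a
  parent term could end up with fewer annotated proteins than its child,
  which breaks the hypergeometric model and the downstream monotonicity of
  propagated scores.

The sufficient statistic is the correspondence matrix: for term $t$ and
domain $d$, the entry $k(t,d)$ counts proteins carrying both, with
marginals $K(t)$, $n(d)$ and the universe $N$.

### Inference

Each pair with $k \ge 1$ (pairs with $k = 0$ carry no evidence: their
one-sided p-value is 1 by construction, and skipping them only removes
needless multiple-testing burden) is tested with the one-sided Fisher's
exact test, $p = P(X \ge k)$ for
$X \sim \mathrm{Hypergeometric}(N, K, n)$, computed as an exact tail sum.
Benjamini–Hochberg adjustment runs jointly across all tested pairs of a
build (one ontology, one domain type), matching the single FDR reported per
annotation set. Pairs below the FDR threshold (default $10^{-3}$ — a
conservative choice for a reusable annotation resource; configurable)
become direct annotations.

Annotation strength is the hypergeometric z-score
$s = (k - \mu)/\sigma$ with $\mu = nK/N$ and
$\sigma^2 = n \frac{K}{N}\bigl(1-\frac{K}{N}\bigr)\frac{N-n}{N-1}$. This is
a deliberate design choice: the published method calls only for a
"hypergeometric distribution-based score" rescaled into 1–100, without a
formula, so the z-form was chosen as a strength measure distinct from the
p-value and well-defined for rescaling. The 1–100 **annotation score** is a
linear min–max rescale of $s$ over the significant direct records of the
build, *before* propagation.

Degenerate cases are pinned down so results are deterministic: $\sigma = 0$
(or $N < 2$) yields $s = 0$; if all significant strengths are equal the
rescale maps everything to 100 (a single significant record is maximal
support, not minimal).

### Propagation

Annotations propagate to all ancestors in the ontology DAG. Only `is_a`
edges are followed by default: it is the one universally safe true-path
relation; `part_of` can be opted in (`use_part_of = TRUE`) where a curator
judges it transitive for their ontology. An ancestor's score is the
maximum over the domain's annotated descendants — support is never
understated, and scores are non-decreasing towards the root. A propagated
record also needs p and FDR fields; it aggregates the *strongest support*
among the descendants it summarises (minimum p, minimum FDR, maximum $s$).
Aggregating component-wise rather than copying one "best" record keeps
propagation idempotent — re-propagating a closed table is a no-op — and
preserves the per-record invariant $p \le \mathrm{FDR}$, since a minimum
of FDRs is never below the minimum of the matching p-values.

### Enrichment

Enrichment of a user domain list reuses the same two statistics. The
universe defaults to all reference-annotated domains of the matched type —
the standard enrichment convention — and a user-supplied background
overrides it. Only terms annotating at least one usable input domain are
tested (documented, deterministic multiple-testing family $m$;
`test_all_terms = TRUE` switches to the full reference). Results are sorted
by FDR ascending, ties by z descending, then term id, and reported with
overlap counts and member domains. One boundary convention:
`fdr_threshold = 1` disables the FDR filter and reports every tested term.
This matters for degenerate inputs where the input equals the universe
(every FDR is then exactly 1) — such as the packaged worked example, whose
mini reference is reconstructed from printed member lists and therefore
contains no domains beyond them.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `fdr_threshold` | `infer_annotations` | 1e-3 | BH FDR below which a pair becomes a direct annotation |
| `min_k` | `infer_annotations` | 1 | smallest overlap entering the test set |
| `min_K`, `min_n` | `infer_annotations` | 0 (off) | optional marginal filters per term/domain |
| `evidence_exclude` | `read_gaf` | none | GAF evidence codes to drop (e.g. `IEA`); all codes kept by default since the right choice is corpus-dependent |
| `use_part_of` | `parse_obo` | FALSE | follow `part_of` in addition to `is_a` |
| `fdr_threshold` | `enrich_domains` | 0.05 | reporting cut-off for enriched terms |
| `min_overlap` | `enrich_domains` | 1 | smallest reported overlap |
| `top_n` | reporting | 5 | terms carried into the dot-plot data |

All rates and probabilities are unitless; counts are numbers of proteins
(build) or domains (enrichment).

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` describes a corpus with known ground truth: by default
500 proteins, 20 domains each carried independently with prevalence 0.15,
a depth-3/branching-2 ontology tree (15 terms, 8 leaves), three planted
(domain, leaf-term) pairs at within-carrier rate 0.9 against background
0.05, and unplanted leaves attached at base rate 0.05. These defaults are
the package's validation conditions; they are deliberately a *moderate*
signal (90% vs 5%) at a realistic curated-corpus size, not an easy extreme.
Planted terms are required to be leaves so ancestor propagation is itself
observable against truth. All draws flow from one seeded generator;
identical seeds give byte-identical corpora.

The generator emulates presence/absence architecture and planted
co-occurrence only. It does **not** model domain co-occurrence correlation
(real domains travel in architectures), annotation depth bias, evidence
codes beyond a constant, term correlation beyond the DAG, or protein
families sharing ancestry. Passing recovery tests therefore demonstrates
that the statistical machinery detects planted signal at the stated rates
and sizes — not that annotations inferred from any real corpus are correct
at the same rates.

Proteins that draw no ontology term are dropped (they are outside the
"annotated corpus" by definition), so the effective $N$ of a synthetic
build is below `n_proteins`; with the defaults, roughly 250–300 of 500.

## Numerical and degenerate-input choices

* Exact tail sums for Fisher p-values — never a normal approximation.
* Obsolete OBO terms are dropped with their edges; `alt_id`s resolve to
  primary ids so corpora using superseded identifiers are not lost; cyclic
  `is_a` input is rejected with one offending cycle listed.
* Multiple ontology roots (e.g. the three GO namespaces in one file) are
  kept as separate sub-DAGs; no artificial super-root is invented.
* Ties in enrichment ordering break by z, then lexicographic term id;
  all written tables have deterministic row order, and every writer is
  atomic (write-to-temp, rename), so failed runs leave no partial files and
  repeated runs are byte-identical.
* Empty tested sets and empty significant sets yield empty tables with a
  warning, not errors; an input list disjoint from the reference universe
  is an error (it almost always signals the wrong domain type).

## Problem sizes used in validation

The shipped test-and-acceptance workload uses corpora of up to 500 proteins
across 20 seeds, exhaustive Fisher-oracle comparison for every admissible
configuration with $N \le 25$, 1000 random vectors for BH
permutation-invariance, and 200 random DAG/table instances for the
propagation invariants. These sizes give tight, reproducible checks of
every code path; nothing in the implementation is specific to them, and
the algorithms are polynomial in corpus size (the matrix build is the
dominant cost, linear in the number of protein–term–domain co-occurrences).

## Known limitations

* Only `is_a` (optionally `part_of`) edges are interpreted; OWL axioms,
  cross-ontology bridges and other relations are out of scope.
* The annotation-score formula is this package's documented choice of a
  hypergeometric-based score; published resources built with other score
  definitions will not be numerically reproduced.
* No protein-identifier mapping is attempted: GAF accessions and the
  domain-assignment accessions must already agree.
* Enrichment p-values inherit the reference table's quality; a reference
  carrying memberships only (like the packaged example) supports overlap
  and membership reporting, while its p/z values are degenerate.
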