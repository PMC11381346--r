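---
title: "Sketch-based genome search over navigable small-world graphs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketch-based genome search over navigable small-world graphs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sketchnav)
```

## The problem

Placing a newly assembled microbial genome means finding its best matches in
a reference collection and reading taxonomic rank off the genome-aggregate
identity to those matches: average nucleotide identity (ANI, species
boundary conventionally 95%) and average amino-acid identity (AAI, genus
roughly 65%, family roughly 52%). Reference collections have grown to
hundreds of thousands of species representatives, so the classical
all-versus-all strategy — align or sketch the query against every database
genome — is linear in the database and has become the bottleneck of
metagenome-scale studies.

`sketchnav` combines two sub-linear primitives. Each genome is summarised by
a fixed-size k-mer sketch whose register collisions estimate a Jaccard-type
similarity, and the sketches are organised into a hierarchical navigable
small world (HNSW) graph that is searched greedily, so a best-match query
costs a number of distance evaluations that grows like $\log N$ rather than
$N$. Estimated similarities convert to ANI/AAI proxies through the Mash
equation, and a three-step nucleotide → proteome → universal-gene escalation
keeps accuracy for queries of any novelty.

## Similarities, sketches and their estimators

For k-mer supports $A, B$ the Jaccard similarity is
$J = |A \cap B| / |A \cup B|$. For abundance-weighted k-mer sets with
normalised weights $w(x) = \mathrm{count}(x)/\mathrm{total}$, the
probability Jaccard index is

$$J_P = \sum_{x:\,w_A(x)w_B(x)>0}
  \Big(\sum_y \max\big(\tfrac{w_A(y)}{w_A(x)}, \tfrac{w_B(y)}{w_B(x)}\big)\Big)^{-1},$$

which discounts neither k-mer multiplicity nor genome-size differences and
is therefore the default for incomplete or repeat-rich genomes. Both
$1 - J$ and $1 - J_P$ are metrics, which the graph construction relies on.
`j_exact()` and `jp_exact()` evaluate both exactly (the inner sum of $J_P$
is rearranged by sorting the union on $w_A/w_B$ into prefix sums plus a
binary search, $O(U \log U)$) and serve as the oracles every estimator is
tested against.

Five sketching algorithms produce `m`-register summaries:

* **ProbMinHash3a** (default, weighted): element $x$ conceptually draws one
  $\mathrm{Exp}(w(x))$ value per register and each register keeps the
  minimising element, so two sketches collide per register with probability
  exactly $J_P$ and the register-match estimator has mean squared error
  $J_P(1-J_P)/m$. The implementation generates each element's draws in
  ascending order (order-statistic spacings over an incremental
  Fisher–Yates permutation) and stops as soon as the running value exceeds
  the largest current register minimum, tracked by a max segment tree —
  distributionally identical to the naive scheme, but near-linear in
  practice.
* **SuperMinHash** (unweighted): element values $j + U$ over a random
  permutation of registers; collision probability is exactly $J$ with
  sub-MinHash variance at no extra hash cost.
* **One-permutation hashing** with two densification rules: one hash pass
  bins every element; empty bins borrow either through 2-universal
  re-hashing of (bin, attempt) (*optimal*) or by fixed-direction rotation
  with the borrowed value re-randomised by the rotation offset (*faster*).
* **SetSketch**: register $i$ keeps
  $\max_d \mathrm{clamp}(1 + \lfloor \log_b (1/X_{d,i}) \rfloor,\,0,\,q+1)$
  with $X_{d,i} \sim \mathrm{Exp}(a)$, i.e.
  $P(K_i \le k) = e^{-n a b^{-k}}$ — a base-$b$ interpolation between
  MinHash ($b \to 1$) and HyperLogLog ($b = 2$). Sketches of unions are
  element-wise maxima, so partial databases merge losslessly.

SetSketch supports two joint estimators. The *LSH* estimator inverts the
expected fraction $D$ of equal registers; summing the joint register CDF
over the geometric grid and collapsing the sum to its $b \to 1$ integral
form gives, for an equal split of the exclusive mass and $r = 1/b$,

$$E[D] = 1 + \tfrac{2}{\ln b}\,\ln\!\big(J + (1-J)\tfrac{1+r}{2}\big)
\quad\Longrightarrow\quad
\hat J = \frac{2\,b^{(D-1)/2} - 1 - r}{1 - r}.$$

The *JMLE* (default) first estimates each sketch's cardinality with
$\hat n = m(1-1/b) / (\ln b \cdot a \sum_i b^{-K_i})$ (the base-$b$
analogue of the HyperLogLog raw estimator) and then maximises the exact
joint likelihood of the register pairs over the shared cardinality $c$ by
golden-section search, $\hat J = c/(\hat n_A + \hat n_B - c)$. The
per-register Shannon entropy of the sketch,

$$H(b) = \frac{1}{\ln 2\,\ln b}\Big(\big(1-\tfrac1b\big)
  + \int_0^1 z^{1/(b-1)}\,\frac{(1-z)\ln(1-z)}{z\ln z}\,dz\Big),$$

is evaluated by adaptive quadrature; at $b = 2$ it reproduces the classic
HyperLogLog register entropy (2.83 bits, cross-checked in the tests against
the Shannon entropy of the register distribution computed directly), and at
the default $b = 1.001$ the package computes 12.24 bits, i.e. an
entropy-optimal code would shave 23.5% off uncompressed 16-bit registers.

```{r entropy}
setsketch_entropy_per_register(2)       # HyperLogLog limit
setsketch_entropy_per_register(1.001)   # default base
```

### From similarity to identity: the Mash equation

$$\mathrm{ANI} \approx 1 + \frac{1}{k} \ln \frac{2J}{1+J}$$

maps a Jaccard-type similarity at k-mer size $k$ to an identity fraction;
`mash_transform()`/`mash_inverse()` implement the two directions and
round-trip to 1e-12. Inverting at $k = 16$ shows why the pipeline switches
levels where it does: 78% ANI corresponds to $J = 0.015$, i.e. a sketch
distance of 0.9850 — beyond it, nucleotide k-mer evidence is a few dozen
shared k-mers per ten thousand and rank order becomes unreliable, so the
search escalates to amino-acid k-mers, whose slower divergence keeps the
signal alive down to family-level relatedness.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `m` | 12000 | registers per sketch; estimator SD is $\sqrt{J(1-J)/m}$ (48000 recommended for fungal-size genomes) |
| `k` (nt) | 16 | nucleotide k-mer length (21 for fungal genomes; capped at 26 so packed tokens stay exact doubles) |
| `k` (aa) | 7 | proteome k-mer length (5 for universal-gene sets; capped at 12) |
| `b, a, q` | 1.001, 20, 65534 | SetSketch base, rate and truncation; $P(K \le 0) = e^{-20}$, no saturation below ~1e9 tokens, registers fit 16 bits |
| `M` | 24 | max neighbours per layer (2M at layer 0); 20–200 is the useful range |
| `ef_construct` | 1000 | insertion beam width; quality/speed dial of the graph |
| `ef_search` | max(K, 64) | query beam width; recall is non-decreasing in it |
| `mL` | $1/\ln M$ | level multiplier of the geometric layer assignment |

## The HNSW index

Nodes are inserted in database order. A node draws its top level from a
geometric distribution (`floor(-log(u) * mL)`), descends greedily from the
entry point through the layers above it, and in each of its own layers runs
a beam search of width `ef_construct`, selects up to `M` (`2M` at layer 0)
neighbours with the keep-if-closer-to-the-target-than-to-any-kept-neighbour
heuristic (nearest-first fill as fallback), and finally *reverse-updates*
the selected neighbours, re-pruning any list that exceeds its cap. Queries
run the same descent without the reverse update, so they never modify the
graph and cost $O(\log N)$ distance evaluations; the package counts the
evaluations (`attr(hits, "n_dist_evals")`) and the test suite checks the
growth over databases of 250–4000 genomes (ratio ~2.2 between the extremes,
where a linear scan would give 16).

Determinism is part of the contract: all hash randomness is derived from
the recorded seed; level draws are keyed to (seed, node ordinal) so adding
genomes after reloading a dumped database reproduces the single-session
build bit-for-bit; every tie anywhere is broken by (distance, genome id)
with C-locale id ordering. `knn_query()` with `ef_search >= n` evaluates
every node directly — an exhaustive beam on a connected graph visits all
nodes anyway, and implementing it as a scan makes the pooled-split
equivalence guarantee exact regardless of graph connectivity.

Databases persist as four coupled text/binary artifacts (`manifest.json`,
`ids.tsv`, `sketches.bin`, `graph.bin`, little-endian, versioned); the
round trip is byte-exact and a manifest/sketch size disagreement is a hard
load error.

## The three-step pipeline

`request()` searches the nucleotide graph first and accepts the result if
the best distance is within 0.9850; otherwise it searches the
whole-proteome graph (k = 7), escalating past 0.9720 to the universal-gene
graph (k = 5). Hits carry the ANI/AAI proxy of their own level's k; hits
beyond the level cutoff are flagged rather than dropped. Suggestions follow
the threshold rules — same species if the top-1 ANI proxy is at least 0.95;
same genus (new species) if at least 5 of the top 10 AAI proxies reach 0.65
(votes over a user-supplied taxonomy table when present, a flagged count of
qualifying hits otherwise); same family (new genus) if the top 5 all reach
0.52 — and are emitted as evidence, never as authoritative taxonomy. A
viral flag skips the nucleotide level entirely, since sparse viral
databases make nucleotide graphs unreliable. `pipeline_thresholds()`
self-checks at construction that the Mash inversion of 78% ANI at k = 16
reproduces the 0.9850 cutoff and refuses inconsistent configurations.

For collections too large for one machine, `split_build()` partitions the
genomes uniformly at random into independently built databases and
`split_request()` pools per-piece top-`k` lists, re-sorts and truncates;
with per-piece `k >= K` (enforced) and exhaustive per-piece beams the
pooled top-`K` equals the unsplit ranking exactly, which the tests assert
as set-and-order equality.

## What the synthetic generator emulates — and what it does not

`generate_genome()` / `mutate_genome()` produce i.i.d. genomes and
substitution-only mutants, so a mutant's expected ANI is analytically
$1 - \mathrm{rate}$ and every benchmark has a closed-form truth;
completeness removes random contiguous blocks (MAG-style fragmentation)
rather than random sites. `synth_genome_collection()` arranges group
parents on a random-attachment tree (each parent is a mutated copy of a
randomly chosen earlier parent, default rate 0.05, group members at 0.015),
so inter-group distances form a navigable gradient rather than a flat
plateau — the property that makes real taxonomic databases searchable by
proximity graphs in the first place. Proteome relatedness is generated
directly by sequence sharing (`derive_proteome()`, aa-Jaccard ≈
$f/(2-f)$ for share $f$) because gene prediction is out of scope.

The generator deliberately omits indels, rearrangements, horizontal
transfer, repeat structure and compositional bias. Passing tests therefore
demonstrate the correctness of the estimators, the graph and the pipeline
logic under known truth — not the field accuracy of k-mer identity proxies
on real genomes, which depends on exactly the omitted features.

## Numerical choices and degenerate inputs

* K-mer tokens are packed integers (2 bits/base, base-20 for amino acids)
  capped at $k \le 26$ / $k \le 12$ so every token and register value is an
  exactly representable double in R; register contents are the top 52 bits
  of a 64-bit token hash (spurious collision probability $m \cdot 2^{-52}$).
* Comparing sketches that differ in any of algorithm, `m`, `k`, alphabet,
  seed or SetSketch constants is a hard error, never a silent answer.
* Empty k-mer multisets (every sequence shorter than `k`, or all windows
  masked) are well-defined at extraction, refuse to sketch, and are skipped
  with a warning and recorded in the manifest at database build.
* The entropy quadrature uses `integrate()` at rel.tol 1e-10 / abs.tol 1e-6;
  the integrand extends continuously to 0 at the left endpoint and has an
  integrable logarithmic singularity at the right one.
* JMLE maximises the profile likelihood by 80 golden-section iterations and
  compares the interior optimum against both boundaries; identical register
  vectors short-circuit to distance 0 for both SetSketch estimators.
* Brute-force oracles and graph queries can return different top-1 genomes
  when two database entries are closer to each other than one register-noise
  SE; the consistency tests count such swaps as ties (within $3\sqrt{d(1-d)/m}$)
  rather than disagreements.

The test suite runs its heavy benchmarks at deliberately modest sizes —
1000- and 4000-genome collections of 2 kb genomes at m = 1024, and m = 2048
with 200 seed replicates for the error-law checks — chosen so the whole
suite completes in minutes while keeping every statistical band
(3 standard errors throughout) meaningful.

## Known limitations

* Gene prediction and universal-gene extraction are upstream of the
  package: proteome and universal-gene FASTA inputs must be provided.
* The genus/family vote degrades gracefully without taxonomy labels but is
  then a count of qualifying hits, flagged as such.
* Sketch databases are held in memory; memory-mapped storage is out of
  scope.
* The layer-occupancy decay observed for very large real databases is
  steeper than $1/\ln M$ level assignment predicts; `mL` is exposed as a
  parameter rather than tuned.

## A worked example

```{r example, eval = FALSE}
coll <- synth_genome_collection(n_groups = 20, group_size = 10,
                                genome_length = 2000, seed = 1)
p <- sketch_params(m = 1024, k = 16, seed = 1)
db <- sketch_db(lapply(coll$records, sketch_genome, params = p))
g <- hnsw_build(db, hnsw_params(M = 16, ef_construct = 200, seed = 1))

query <- mutate_genome(coll$records[[1]], rate = 0.03, seed = 99)
knn_query(g, sketch_genome(query, p), K = 5)

rep <- request(g, list(query), K = 10)
rep$suggestions
```
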