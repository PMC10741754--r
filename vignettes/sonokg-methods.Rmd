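---
title: "From narrative ultrasound reports to completed knowledge graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From narrative ultrasound reports to completed knowledge graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sonokg` converts the free-text findings of ultrasound reports into
entity–relation triples and repairs the subject entities that report writers
habitually omit. This vignette documents the model behind each stage, the
parameters that matter, the places where the design was genuinely open and
which choice this package makes, and what the synthetic test corpora do and
do not demonstrate.

## 1. Text structuring: clauses, concepts, term networks

Finding blocks are long sentences made of short clauses, one finding each.
`segment_report()` splits at clause delimiters (period, comma, semicolon,
plus their full-width forms, configurable via `clause_splitter()`) and
tokenizes each clause with a pluggable backend. The default backend splits
on whitespace, which is exact for the package's English-like synthetic
corpus; word segmentation for languages without spaces is deliberately
delegated — register any `function(clause) tokens` as the tokenizer.

Each token becomes a *concept* `(surface, normalized, tag)`.
Normalization is lowercasing plus an optional user lemma table (e.g.
`intrahepatic → liver`); it is deterministic, so one surface always maps to
one normalized form within a run. The tag comes from the domain lexicon when
the normalized token (or a multi-word span — spans are merged greedily by
longest lexicon match before tagging, so "right liver" and "substantial
echo" are single concepts) is a lexicon entry, otherwise from a
part-of-speech backend; a backend failure degrades to `"unk"` rather than
aborting a batch run. The bundled `pos_tagger_english()` is a small
closed-class plus suffix heuristic: adequate for synthetic corpora and demos,
not a substitute for a trained tagger on clinical text.

The *term network* links concepts at token distance 1 **within a clause**.
Whether adjacency should cross clause boundaries was an open choice; we
confine it because the point of clause splitting is to isolate findings, and
the extraction rules below never need cross-clause adjacency. Punctuation
does not become concepts — delimiters act purely as boundaries. Edge count
is therefore exactly `sum(max(0, clause_length - 1))`, which the tests check
against brute-force pair enumeration.

## 2. Rule-based extraction and the simple knowledge graph

Extraction matches short tag patterns over the rule-relevant concepts of
each clause. The four default rules are:

| pattern            | emissions                              |
|--------------------|----------------------------------------|
| `(organ, verb, adj)` | `(organ, <verb>, adj)`               |
| `(organ, adj)`       | `(organ, show, adj)`                 |
| `(organ, verb)`      | `(organ, status, verb)`              |
| `(organ, n, adj)`    | `(organ, has, n)`, `(n, show, adj)`  |

Three policies make these rules cover real finding clauses; all are
documented behaviour of `match_rules()` and are fixed by the worked liver
example the package reproduces in its tests:

* **Anchoring and tail chaining.** The scanner walks a clause left to right
  and keeps the most recent entity-capable concept as *anchor*. Longer
  patterns are tried before shorter ones; after a match the scanner
  re-anchors on the last entity of the matched span, so attribute chains
  emit `{liver, has, blood vessel}`, `{blood vessel, has, structure}`,
  `{structure, show, clear}` from a single clause. Anchors never cross
  clause boundaries.
* **Which tags may head a triple.** Rules containing a verb or a noun slot
  accept either `organ` or plain-noun (`n`) heads — parenchymal structures
  such as "substantial echo" head findings of their own — while the
  two-concept rules require an `organ` head. That asymmetry is what forces a
  clause-initial `(n, adj)` group ("surface uneven") into a placeholder
  triple instead of promoting the attribute noun to subject.
* **Placeholder emission.** When a matchable group appears before any
  possible head in its clause, the triple is emitted with head `"@"`. For
  clause-initial `(n, adj)` groups two renderings are defensible:
  `(@, surface, uneven)` — the attribute noun as relation, the form in which
  omitted-head findings are conventionally tabulated — or the strict rule-4
  pair `(@, has, surface)`, `(surface, show, uneven)`. The package defaults
  to the former and exposes `skg_config(surface_relation = FALSE)` for the
  latter; completion only repairs the former into `(liver, surface, uneven)`
  style facts, which is why it is the default.

Two-element facts ("the liver has no normalcy") are kept triadic as
`(organ, status, <predicate>)` so every downstream consumer sees uniform
triples; `default_rules(verb_fact_relation = "show")` restores the literal
rule-table relation if preferred.

The resulting *simple knowledge graph* (SKG) is a tibble of triples with
report and clause provenance; entity and relation vocabularies are always
derived projections, never stored state.

## 3. Synonym elimination

Report adjectives vary freely ("rough", "unsmooth", "uneven"). Word vectors
are trained on the tokenized corpus with skip-gram and negative sampling
(`train_embeddings()`); skip-gram versus CBOW was an open choice and
skip-gram is the default because it behaves better at the small corpus sizes
this package targets. Training is single-threaded and driven entirely by R's
RNG, so a seed fixes the vectors bit-for-bit. A deterministic count-based
alternative (`method = "ppmi_svd"`) exists for settings where stochastic
training is unwanted. Defaults: `dim = 16`, `window = 2`, `epochs = 15`,
`negative = 5`, linearly decayed learning rate from 0.05.

`build_synonym_table()` groups candidate terms whose cosine similarity to a
group anchor reaches a threshold. Anchors are visited in decreasing corpus
frequency; the canonical term of a group is its most frequent member (the
habitual spelling is the natural category name), ties broken
lexicographically — the tie-break is ours. The threshold default of **0.55**
is a package choice: published synonym examples in this domain admit members
down to ≈0.59 cosine similarity, so the default sits just below that while
staying well above the similarity of unrelated attribute terms in our
corpora; it is exposed everywhere. `normalize_skg()` rewrites heads,
relations and tails to canonical terms; it is idempotent and preserves
triple count and provenance.

## 4. The completion model

### Translation on relation hyperplanes

Facts are embedded by giving each relation a hyperplane with unit normal
`w_r` and an in-space translation `d_r`. With the projection
`x⊥ = x − (w_rᵀ x) w_r`, a fact `(h, r, t)` scores

    f_r(h, t) = || h⊥ + d_r − t⊥ ||²

— zero exactly when the projected head translates onto the projected tail.
Lower is better throughout. Projecting before translating lets many heads
share one tail (they may differ freely along the normal), which is exactly
the many-to-one structure of findings ("has" links one organ to many parts).

Training (`kg_train()`) minimises the margin-ranking loss
`max(0, γ + f(positive) − f(corrupted))` by SGD, corrupting the head or tail
uniformly at random. After every update hyperplane normals are renormalised
to unit length and entity vectors are projected back into the unit ball.
Defaults — margin `γ = 1`, one negative per positive, learning rate 0.01,
`σ = 1`, dimension 16 — are package choices (no published values exist for
them); all are arguments. Placeholder-headed triples are inference targets
and are rejected from training. A fixed seed reproduces the loss trace and
the final model exactly.

### The proximity kernel and its direction

Writers omit the entity they have just mentioned, so a good candidate head
is one *near* the tail in embedding space. The kernel

    k(e_i, e_j) = exp( − ||e_i − e_j||² / (2σ²) )

is 1 at distance zero and decays with the classic slow–fast–slow Gaussian
profile; `σ` sets the radius inside which an entity still counts as near.
The combined completion score multiplies the translation residual by a
kernel term, and here the design was genuinely ambiguous: with a *decaying*
kernel, multiplying makes far-away candidates look better under an argmin,
which inverts the stated motivation, whereas dividing by the kernel (equivalently,
multiplying by a kernel that grows with distance) penalises them. Both
combinations are implemented; `kgcm_score()` defaults to the literal product
form, while `complete_entity()` defaults to `combine = "divide"` because
that is the direction under which proximity helps — on fixtures where a
distractor head shares the true head's projection (identical translation
score) but sits farther from the tail, only the divide direction
consistently picks the true head, and it is what makes proximity-aware
completion dominate the plain translation score in the package's tests.

### Candidate policy

`complete_entity()` replaces each `@` with the argmin-scoring candidate.
The default candidate set is the entities already mentioned earlier in the
same report — the writer can only omit what was introduced — falling back to
the model vocabulary when the report offers none; `"global"` uses the whole
vocabulary directly. Whether candidates should be report-scoped or
corpus-wide is not settled by any published description; report-scoped is
the default because it mirrors the omission mechanism and shrinks the search
space. Ties break by earlier first mention, then lexicographically.
Unresolvable placeholders (no scoreable candidate, out-of-vocabulary
relation or tail) are left as `@` and reported with a warning, never an
error.

## 5. Ontology export

`to_ontology()` maps each SKG triple to exactly one ontology element under a
configurable policy: part-of (`has`) triples become `rdfs:subClassOf` axioms
with the tail as child (`portal_vein ⊑ liver`), attribute display (`show`,
`status`) types the tail as a named individual of the head class, and every
other relation becomes an object-property fact. The mapping generalises a
single published worked example and is therefore exposed as
`ontology_mapping()`; cardinality restrictions are deliberately not
generated. Identifiers are sanitised to IRI-safe form (spaces become `_`)
with a logged message; `has`-cycles are rejected with the offending path.
Serialisation (RDF/XML via a canonical writer, Turtle) orders everything
deterministically, so serialize → parse → serialize is byte-stable, and
parse-back is tested for graph isomorphism. GraphML export (via igraph)
collapses duplicate triples into one edge with a multiplicity attribute.

## 6. Evaluation

`score_triples()` does set-based matching in three modes — whole triples,
heads only, tails only — because published precision/recall figures in this
area are ambiguous about whether triples or per-slot entities were counted;
both are one call away. Zero denominators yield 0, not errors, so tiny
fixtures evaluate cleanly. The domain-extraction index

    η = (v / baseline) · (v / n)

compares a method extracting `n` domains of which `v` are valid against a
fixed-inventory reference whose valid-domain count is the `baseline`; a
fixed five-organ text-matching reference scores exactly 1 by construction
(`extraction_index(5, 5, 5)`). "Valid" is operationalised as: the domain
(a connected component of the report's entity graph) contains an organ from
the supplied inventory — a deterministic stand-in for the expert judgement
used with clinical corpora.

## 7. The synthetic corpora, and what the tests show

`report_grammar()` emulates the structure of abdominal-routine finding
blocks: five-plus organ domains (liver — always present — right liver,
gallbladder, pancreas, spleen, kidney), an intro clause per organ,
attribute-part clauses with adjectives drawn from planted synonym sets, a
feature-echo clause pair, and head omission applied to follow-on clauses
with probability `omission` (default 0.3, a mid-range habit strength; 0 and
1 are used as degenerate controls in tests). Gold term networks, SKGs,
completed SKGs and omission lists are derived template-by-template,
independently of the extraction code, so extraction and completion can be
scored exactly.

What the synthetic corpus does **not** emulate: real segmentation ambiguity
(tokens are whitespace-separable by construction), misspellings and
abbreviations, tagger errors (every content word is lexicon-covered),
cross-report entity ambiguity, and any language-specific morphology. Passing
tests therefore demonstrate the correctness of the algorithms under clean
annotation, not end-to-end accuracy on hospital text.

`generate_planted_kg()` builds embedding geometry with known ground truth:
random unit normals, in-hyperplane translations of norm 0.3, root entities
in a ball of radius 0.4, and derived entities placed so every fact satisfies
the translation identity up to an on-hyperplane noise of bounded norm
(default 0.05, so scores are bounded by `noise²`). Fifty entities under four
exact translations support about forty distinct derived facts, so the
400-triple corpus is a multiset of repeated observations — the same way a
report corpus repeats common findings. With `confusable > 0` the generator
adds distractor heads sharing a true head's projection but displaced along
the normal, the configuration that separates proximity-aware completion from
the plain translation score.

## 8. Numerical choices and problem sizes

* Floating-point identities (projection idempotence, orthogonality, score
  oracles) are asserted at 1e-9; unit-norm constraints at 1e-6 after
  training, matching the update-then-renormalise scheme.
* Degenerate inputs: empty text segments to an empty network; an empty SKG
  extracts, exports and evaluates without error; zero-epoch training returns
  the seeded initialisation; cosine similarity on a zero vector and
  non-positive bandwidths are errors.
* Test problem sizes were chosen as the smallest at which the stochastic
  stages are stably in their asymptotic regime: synonym recovery uses 20
  reports × 10 seeds; head-recovery uses 30–40 reports × 5 seeds and the
  50-entity planted graph with 150 training epochs; matcher/score oracle
  equivalence uses 1000 random instances each.
* All stochastic stages consume R's RNG only, so a single seed argument
  reproduces any run, and pipeline outputs are stamped with a hash of their
  full configuration.

## 9. Known limitations

* The rule matcher is greedy and first-match; clauses engineered with
  interleaved rule patterns can shadow an alternative parse. Real finding
  clauses are short enough that this has not been observed outside
  adversarial constructions.
* Completion can only choose candidates the embedding knows; relations or
  tails that never occur outside placeholder triples are unresolvable by
  construction (they are reported, not guessed).
* The shipped tagger is a heuristic; serious use on clinical text requires a
  trained tagger behind the backend interface, and for Chinese reports a
  word segmenter registered as the tokenizer.
* The ontology export covers subclass axioms, typed individuals and object
  property facts; cardinality restrictions and reasoning are out of scope.
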