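# sonokg

Knowledge graphs from narrative ultrasound reports.

Radiology and ultrasound findings are written as free text: long sentences,
one clause per finding, attribute–value phrasing, and a writing habit that
names an organ once and then drops it from follow-on clauses ("The liver is
abnormal, … surface uneven"). `sonokg` turns such text into computable
knowledge graphs and repairs the dropped subjects:

1. **Structuring** — each report is split into clauses, every term is
   annotated with a tag (custom lexicon tag such as `organ`, or a
   part-of-speech fallback) and linked to its neighbours in a *term network*.
2. **Extraction** — tag-sequence rules over the term network emit
   `(entity, relation, entity)` triples into a *simple knowledge graph*
   (SKG). The four default rules are
   `(organ, verb, adj)`, `(organ, adj)`, `(organ, verb)` and
   `(organ, n, adj)`; a clause whose finding has no subject yields a triple
   with the placeholder head `@`.
3. **Synonym elimination** — skip-gram word vectors trained on the corpus
   group cosine-similar attribute terms; each group is rewritten to its most
   frequent member.
4. **Completion (KGCM)** — triples are embedded with a
   hyperplane-translation model (each relation *r* has a unit normal `w_r`
   and translation `d_r`; a fact scores
   `f_r(h,t) = ||h⊥ + d_r − t⊥||²` with `x⊥ = x − (w_rᵀx) w_r`).
   The completion score additionally weights candidates by a Gaussian
   proximity kernel `k(h,t) = exp(−||h−t||² / 2σ²)` over head–tail distance,
   and every `@` head is replaced by the candidate entity (by default, an
   entity already mentioned earlier in the same report) with the best score.
5. **Representation & evaluation** — SKGs serialise to RDF/XML, Turtle and
   GraphML (`has` becomes `rdfs:subClassOf`, attribute display becomes typed
   individuals); predictions are scored with precision/recall/F1 and the
   domain-extraction index `η = (v / baseline) · (v / n)`.

Clinical corpora are rarely shareable, so the package ships a synthetic
report generator (`report_grammar()`, `generate_reports()`) that emulates
this report structure — including head omission and planted synonym sets —
together with gold annotations, plus `generate_planted_kg()` for embedding
geometry with known ground truth.

## Worked example

The passage below is the kind of finding block this pipeline targets; note
the two clauses without subjects ("surface uneven", "show nodule shape").

```r
library(sonokg)

lex <- tag_lexicon(
  c("liver", "right liver", "has no normalcy", "shows", "shrink",
    "surface", "uneven", "substantial echo", "thickens", "nonuniform",
    "show", "nodule shape", "blood vessel", "structure", "clear"),
  c("organ", "organ", "verb", "verb", "adj", "n", "adj", "n", "verb", "adj",
    "verb", "n", "n", "n", "adj"),
  lemmas = c(intrahepatic = "liver")
)

txt <- paste(
  "The liver has no normalcy, the right liver shows shrink, surface uneven,",
  "the substantial echo thickens nonuniform, show nodule shape,",
  "intrahepatic blood vessel structure show clear."
)

x <- extract_skg(txt, lex)
x
#> <skg: 8 triples (2 placeholder heads), 11 entities, 6 relations>
#> # A tibble: 8 × 6
#>   head             relation tail            placeholder report_id sentence_index
#>   <chr>            <chr>    <chr>           <lgl>       <chr>              <int>
#> 1 liver            status   has no normalcy FALSE       r1                     0
#> 2 right liver      shows    shrink          FALSE       r1                     1
#> 3 @                surface  uneven          TRUE        r1                     2
#> 4 substantial echo thickens nonuniform      FALSE       r1                     3
#> 5 @                show     nodule shape    TRUE        r1                     4
#> 6 liver            has      blood vessel    FALSE       r1                     5
#> 7 blood vessel     has      structure       FALSE       r1                     5
#> 8 structure        show     clear           FALSE       r1                     5
```

Rows 3 and 5 record findings whose subject the writer omitted. Train the
embedding on a corpus that uses the same finding vocabulary (here the
synthetic corpus) and complete them:

```r
g <- report_grammar(omission = 0.3)
reports <- generate_reports(g, n = 60, seed = 42)
train <- dplyr::bind_rows(
  lapply(reports$gold_completed, tibble::as_tibble),
  list(tibble::as_tibble(x[!x$placeholder, ]))
)
model <- kg_train(train, dim = 16, sigma = 1, epochs = 100, lr = 0.02, seed = 7)
done  <- complete_entity(x, model)
done[done$completed, c("head", "relation", "tail")]
#> # A tibble: 2 x 3
#>   head             relation tail
#>   <chr>            <chr>    <chr>
#> 1 liver            surface  uneven
#> 2 substantial echo show     nodule shape
```

The uneven surface is re-attached to the liver and the nodular pattern to
the parenchymal echo — exactly the repairs a reader makes mentally. Export
and evaluation then take one call each:

```r
writeLines(serialize_ontology(to_ontology(done), "turtle"))
score_triples(done, done)          # P = R = F1 = 1 against itself
extraction_index(n = 5, v = 5, baseline = 5)
#> [1] 1
```

A thin command-line front end (`exec/sonokg`) exposes the same stages as
`extract`, `complete`, `export`, `eval` and `simulate` subcommands.

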