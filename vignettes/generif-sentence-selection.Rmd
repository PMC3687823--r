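---
title: "Selecting GeneRIF sentences: models, features, and study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting GeneRIF sentences: models, features, and study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task

A GeneRIF links an NCBI Gene identifier to one sentence of a MEDLINE
citation that states novel gene function. Treated as text categorization,
the unit is the sentence: given a citation's title and abstract, label
each sentence GeneRIF-positive or not, and surface the top three
candidates by classifier confidence for a curator to accept or reject.
Two empirical regularities drive everything in this package: positive
sentences concentrate at the **title** (position 1) and at the **last
sentences** of the abstract, and they tend to sit in the **Results** and
**Conclusions** rhetorical zones. The package therefore couples positional
features with an automatic discourse labeler, and treats lexical features
as secondary.

## Sentence model and segmentation

A citation is one row of a tibble; its sentences are rows of a second
tibble keyed by `(citation_id, position)`. The title is always position 1
and abstract sentences follow in order, so positions are the contiguous
sequence `1..N`. Segmentation is a deterministic rule: a boundary is
terminal punctuation followed by whitespace, unless the preceding word is
on a protected-abbreviation list ("e.g.", "i.e.", "vs.", "Fig.", "et
al.", ...) or is a single initial. A rule-based splitter was chosen over
a statistical or service-backed one so that segmentation is reproducible
and testable offline; multi-paragraph abstracts are concatenated with a
single space before splitting. Structured-abstract section ranges read
from XML are computed chunk-wise with the same splitter; a labeled chunk
that does not end in terminal punctuation could in principle merge with
its successor, which we accept as a documented edge case rather than
mutate the text.

## Gene mentions and normalization

The dictionary collects official symbols, official names and synonyms,
adds punctuation variants for single-dash names (dash to space, dash
removed), removes surface forms ending in *disease*, *syndrome* or
*susceptibility* (case-insensitively), collapses duplicates so one surface
form carries every candidate gene identifier, and sorts longest-first so
matching finds "cortexin 2" before "cortexin". Matching is greedy
leftmost-longest at token boundaries (a token boundary is a transition
between word and non-word characters; offsets are 0-based half-open),
case-insensitive except for surface forms on a shipped, editable homonym
list, which must match exactly — this is what keeps "He was tired" from
matching the gene symbol WAS. Before matching, parenthetical abbreviation
definitions are resolved with the Schwartz–Hearst character-alignment rule
and later uses of the short form are rewritten to the long form, so the
dictionary only ever has to know canonical names.

Ambiguous mentions (one surface form, several genes) are resolved two
ways. Officialness ranking prefers the candidate whose route into the
dictionary was most official (symbol = 0, name = 1, synonym = 2), with
remaining ties broken on the smallest gene identifier — numerically when
all candidates parse as numbers, lexicographically otherwise — purely for
determinism. Profile disambiguation builds, per gene, a tf–idf vector
(idf = log(N/df) across genes) over the lowercased, stop-word-filtered
tokens of texts associated with that gene, and picks the candidate whose
profile has the largest cosine similarity to the mention's sentence
context. Cosine over tf–idf was chosen because it is the standard
scale-invariant choice; richer profile channels (MeSH terms, concept
identifiers, extracted relations) are an extension point, not implemented,
because they would require external annotation services. The context
window is the mention's sentence only by default (`window = 0`), exposed
as a knob since the right width is genuinely unknown; ties and missing
profiles fall back to officialness.

## Discourse zoning

Gold rhetorical annotation of GeneRIF corpora is scarce, but a quarter of
MEDLINE abstracts carry section headings. Those headings are distilled
into sentence labels: every sentence inherits the canonical label of its
enclosing section through a shipped heading-normalization table
(AIM/AIMS/PURPOSE/OBJECTIVES → Objective, CONCLUSION → Conclusions, ...).
The table is our own construction — no published mapping exists — and
citations with headings outside it are skipped entirely rather than
guessed at. Two labelers are trained on the distilled labels, both over
bag-of-words plus the two positional features:

- a **one-vs-rest boosted-tree ensemble** (one binary gradient-boosted
  scorer per label; 40 rounds, depth 4, learning rate 0.3 by default).
  Prediction takes the highest-scoring label, abstaining to `Unknown`
  when no scorer reaches the 0.5 posterior threshold — abstention is a
  legitimate outcome for sentences that fit no zone. Ties break by the
  fixed label order Background, Objective, Methods, Results, Conclusions.
- a **linear-chain sequence model**: Laplace-smoothed multinomial token
  emissions per label, a position-bucket emission channel, and
  maximum-likelihood label-transition weights including start/end
  transitions, decoded per abstract with the Viterbi algorithm. Emissions
  are smoothed but transitions deliberately are not: a transition never
  seen in training has weight −∞ and is never decoded, so predicted
  sequences cannot violate the canonical section order; if no feasible
  path exists the decoder falls back to per-sentence argmax. The model is
  decomposable and trained in closed form, which makes it fast and
  exactly reproducible; it never abstains.

The title is not a trainable class: position 1 is always labeled Title
with confidence 1 at prediction time.

## Features and selection

Feature blocks are assembled into one wide matrix keyed by
`(citation_id, position)`:

- `pos`: the sentence number (title = 1); `posf`: total sentences minus
  sentence number (last sentence = 0), so `pos + posf = N` always.
- `text`: lowercased, stop-word-filtered unigram or bigram counts. Counts
  rather than binary indicators were chosen (the alternative is exposed in
  the configuration) since counts carry strictly more information.
- `gene`: three columns — mention count, distinct resolved genes, binary
  presence. The encoding is deliberately a superset of any single choice;
  learners ignore what they do not need.
- `dis` / `disg`: a one-hot over the seven labels (five zones, Title,
  Unknown), from the ensemble or the sequence labeler respectively
  (mutually exclusive in one configuration), or from gold annotation, in
  which case the 6-way gold vocabulary's "Purpose" folds into Objective so
  a single encoding path serves both sources.
- `go`: a Gene Ontology term density — maximal non-overlapping GO-term
  token matches found greedily longest-first, scoring the sum of squared
  matched-token counts divided by sentence token count. The quadratic
  numerator rewards long, specific term matches; the denominator makes the
  score invariant under sentence self-concatenation. This is a
  self-contained density, and its scale is *not* comparable to external
  GO-evidence scorers built on curated categorizers.

Four standard learners are wrapped behind one surface: Gaussian Naive
Bayes, a linear-kernel SVM whose confidences come from a logistic
calibration of the decision margin fitted on training folds, a single
CART decision tree, and AdaBoost.M1 with tree base learners (10 rounds,
unrestricted depth by default; confidence is the alpha-weighted positive
vote share). Zero-variance columns are dropped at fit time and recorded.
Evaluation reports precision, recall and F = 2PR/(P+R) on the positive
class only; with no positive predictions, precision — and hence F — is
defined as 0 and a message is emitted. Macro-averaging was rejected
because the negative class is uninteresting here. `rank_top3()` orders a
citation's sentences by confidence, ties toward the earlier sentence.

## Citation filtering

The automatable rules of the dataset-construction pipeline are
implemented in order: drop citations without an abstract; drop citations
whose MeSH headings denote a non-human organism — implemented as "a
heading from the shipped non-human list is present and Humans is absent",
our own predicate since no exact one is published; keep citations with at
least one gene mention; drop review-typed citations mentioning three or
more distinct genes; keep only Journal Article, Meta-Analysis, and Review
publication types. The report reconciles exactly (input = survivors + sum
removed) and re-running on survivors removes nothing. Journal screening
is separate: a journal is accepted when strictly fewer than 40% of its
citations contain a model-species term (whole-token, case-insensitive
over title + abstract); the journal-descriptor preselection step requires
a proprietary resource and is therefore an input (a journal list), not a
computation. Two rules that require human judgment — "is the basic
biology of the gene the point of the article" and single-patient case
reports — are out of scope by design.

## Synthetic study conditions

The generator defines the conditions every end-to-end test runs under,
and its defaults were fixed by analysis before any test was run:

- **400 training / 150 testing citations**, echoing the scale of a
  realistically curatable corpus.
- Section lengths Background 1, Objective 1, Methods 1, Results 1–2,
  Conclusions 1–2, giving 6–8 sentences per citation.
- Positive placement by position-class odds `w/(1+w)`: title 19 (p =
  0.95), last two sentences 9 (p = 0.90), body 1/19 (p = 0.05). With
  these lengths the expected positive fraction is ≈ 0.42, matching the
  class balance of manually annotated GeneRIF corpora, and the
  Bayes-achievable F for a title-plus-final-sentences rule is ≈ 0.9 —
  high enough that a correct implementation passes the recovery checks
  with margin, and low enough that the problem is not vacuous.
- Section-specific vocabularies are disjoint, so discourse is learnable;
  one signal token per sentence comes from a positive or negative
  vocabulary, with an overlap knob (0 = disjoint, 1 = identical) whose
  only effect is to erase the lexical class signal — raising it can only
  degrade a classifier that sees the signal channel.
- A toy eight-gene inventory plants dash names (variant generation), an
  ambiguous synonym shared by two genes with disjoint context
  vocabularies (profile disambiguation), a homonym symbol, and
  parenthetical abbreviation definitions (30% of eligible citations).
- Gold discourse uses the 6-way annotation vocabulary (with Purpose), so
  the Purpose → Objective fold is exercised.

What the generator does **not** emulate: real lexical variety, anaphora
(the gene named in the title but referenced indirectly later — a known
failure mode of gene features on real text), abstracts that do not follow
the canonical section order, OCR/encoding noise, and the long tail of
real gene nomenclature. Passing the recovery checks therefore
demonstrates that the pipeline's machinery is correct and that the
features carry the signal they are designed to carry — not that these F
values transfer to real MEDLINE text, where published results are
substantially lower.

## Numerical choices and degenerate inputs

Percentages in class-balance reports are rounded to two decimals.
Confusion-derived measures follow the zero conventions above. The
sequence decoder breaks emission ties toward the earlier label in the
canonical order (via `which.max`). Gaussian Naive Bayes on one-hot
columns can meet within-class zero variance; columns constant across the
whole training matrix are dropped, and the remaining zero-variance cases
are left to the fitting library's density conventions, which our oracle
tests pin down on non-degenerate tables. Empty abstracts segment to the
title alone; all-stop-word sentences produce empty text vectors; matching
on an empty dictionary or empty sentence set returns a typed empty
result.

## Problem sizes

The shipped tests train the discourse labelers on a few hundred to 2,000
structured abstracts and the selector on 400/150 citations; these sizes
were chosen as the smallest at which the recovery properties are stable
across seeds, and they keep any single check within a few minutes on one
CPU. Corpus size, boosting rounds, and every probability in the generator
are configuration, not constants, so larger studies are a matter of
changing one call.

## Known limitations

- The dictionary matcher is exact after abbreviation expansion; it will
  not find misspellings or unseen morphological variants, and variant
  generation covers only single-dash names.
- Gene profiles here are token-level only; disambiguation quality on real
  text would depend on richer profiles.
- The heading-normalization table covers common English headings only;
  unmapped headings skip the citation by design.
- The sequence labeler's hard transition constraint is a feature on
  canonical abstracts and a limitation on non-canonical ones (it will
  force a canonical-order reading).
- The GO density is a stand-in with its own scale; treat it as a feature,
  not as an interoperable GO-evidence score.
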