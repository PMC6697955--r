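---
title: "Mapping anatomical mentions to the Tree of Human Body Parts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping anatomical mentions to the Tree of Human Body Parts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thbpmap)
```

## The problem

Discharge summaries are dictated free text. The named entities they contain
— "colonoscopy", "HEENT", "legs bilaterally", "mitral valve" — refer to, or
are strongly related to, human body parts, but rarely name them in a
canonical form. `thbpmap` maps such *anatomical related entities* onto a
compact, position-based ontology, the **Tree of Human Body Parts (THBP)**:
nine top-level regions (head, neck, chest, abdomen, pelvis, back, hip,
extremity, trunk), each with organ and tissue sublayers. Position-based
organization mirrors clinical practice: a patient with chest pain routes to
organs near the chest, whatever physiological system they belong to, and
the layout matches how hospital departments are arranged.

Two conventions shape the packaged tree. First, parts are placed by
*position*, not function: "carotid artery" sits under neck, and tissues
distributed across the whole body (nerve, blood, bone, vein, artery,
muscle, skin) are children of trunk, the "stem" of the body. Second, a
mention maps to the *lowest* applicable layer: "mitral valve" belongs to
the heart, which is itself a sublayer of the chest, so the answer is heart,
not chest.

The tree below the nine regions is hand-authored. It covers every part and
alias the mapping conventions require (heart, lung, colon, trachea, eye,
ear, nose, throat, kidney, vein, the extremities, the abdomen alias chain
abd/abdn/peritoneal cavity/..., and so on) plus a modest, clearly
inspectable expansion of common organs — the file is
`inst/extdata/thbp.json`, a flat JSON array of
`{id, formal_name, aliases, parent}` records chosen for diff-ability.
Completeness relative to any external release is not claimed.

## The mapping cascade

`map_mention()` runs three stages and records which one answered:

1. **Normalization.** The surface is lowercased, tokenized on
   non-alphanumeric boundaries, stopword-filtered, singularized and
   Porter-stemmed (`stem_and_clean()`). Positional words (left, right,
   bilateral(ly), upper, lower, proximal, distal, ...) are split off and
   remembered (`strip_positional()`). Abbreviations are expanded from the
   mention's coreference chain first, then from a global dictionary
   (`expand_abbreviation()`).
2. **Direct string match.** The core (or each expansion) is looked up in
   the stemmed alias index; failing exact lookup, containment is tried —
   ontology terms occurring inside the mention as whole tokens ("left eye"
   includes "eye") or as a character substring of a token ("colonoscopy"
   includes "colon"). Multi-part abbreviations yield several parts: HEENT
   maps to head, eye, ear, nose *and* throat.
3. **Knowledge-base fallback.** If string matching fails ("sigmoidoscopy"
   shares no substring with "colon"), the term's explanation text is
   fetched from a knowledge source, every THBP term occurring in it
   becomes a candidate, and the candidates are scored (below); the argmax
   is the answer.

Finally the positional words are re-attached: "legs bilaterally" →
core "legs" → lower extremity → **"bilateral lower extremity"**.

The baseline system (`baseline_map()`, `method = "baseline"` in
`map_corpus()`) is stage 2 applied to the raw stemmed surface alone — no
positional splitting, no expansion, no fallback. Because the full
cascade's direct stage is a superset of the baseline matcher, any mention
the baseline solves keeps the same parts under the full pipeline; the
fallback is only ever consulted on direct-match failure.

## Candidate scoring

Explanation prose is preprocessed by the *same* pipeline as mentions, so
offsets are 0-based positions in the stopword-free stemmed stream. For a
candidate part $n$ with occurrence offsets $o_1 < \dots < o_F$:

* **Distance.** $D(n)$ defaults to the mean offset
  $\bar o$ (`distance_mode = "mean_offset"`); the first offset and the
  occurrence rank are available as alternatives because the informal
  description ("average distance from the onset") and the formal gloss
  ("number of strings from the beginning") of this quantity differ — the
  package makes the choice explicit and configurable rather than silent.
  With $\max(D)$ the largest $D$ over the explanation's candidates,

  $$f(D(n)) = \begin{cases}
  \cos\!\big(D(n)\,\tfrac{\pi}{2}/\max(D)\big) & \max(D) > 1\\
  1 & \max(D) = 1\\
  0 & \max(D) = 0
  \end{cases}$$

  so a candidate at the onset scores 1 and the last-matched candidate
  scores 0. Two numerical notes: (i) one printed form of the combined
  score multiplies instead of divides by $\max(D)$, which escapes
  $[0,1]$ and contradicts the branch cases; the bounded form above is
  used throughout. (ii) mean offsets can give $0 < \max(D) < 1$, a case
  the branch table does not define; the cosine branch is extended there
  continuously. $\max(D) = 0$ means every candidate sits at offset 0;
  all distance scores vanish and ranking degenerates to the frequency
  term, which is the documented behaviour.

* **Frequency.** $f(F(n)) = 2.5 \times F(n)$ for the *first-appearing*
  candidate (minimal earliest offset; an offset tie goes to the candidate
  earlier in text order), $F(n)$ otherwise. The first occurrence of an
  anatomical term in an encyclopedia lead is strongly indicative, hence
  the boost; 2.5 is shipped as the default operating point alongside the
  coefficients below and is not re-estimated here.

* **Combined.** $\mathrm{Score}(n) = a\,f(D(n)) + b\,f(F(n))$ with
  defaults $a = 15$, $b = 1$. `algorithm = "distance"` and
  `"frequency"` rank by a single term, and the combined ranking reduces
  to them in the limits $a \to 0$ / $b \to 0$ (verified in the test
  suite against an independently coded enumeration scorer,
  `reference_argmax()`).

Exact score ties (absolute tolerance $10^{-9}$) default to the **deeper
node**, consistent with the lowest-layer mapping convention;
`earliest_occurrence` and `lexicographic` are alternatives. A final
lexicographic key keeps the ordering fully deterministic.

## Normalization details and open choices

* **Stopwords before positionals.** Stopword removal runs first, then
  positional splitting; the order is not observable for the packaged
  vocabularies (they are disjoint) but is fixed and documented.
* **Positional protection.** A positional token is never stripped out of
  a span that matches an ontology alias: "lower extremity" survives
  whole, and in "right lower extremity" only "right" is split off. This
  generalizes protection from "the full sequence is an alias" to "any
  alias span", which is what multi-word part names require.
* **Singularization.** Regular plurals collapse under Porter stemming
  ("extremities" and "extremity" both stem to `extrem`). Irregulars
  (feet/foot) and s-final nouns whose "-es" plurals the stemmer cannot
  reunite with their singulars (pancreas, uterus, pelvis, esophagus) are
  handled by an explicit table applied before stemming.
* **Stemming both sides.** Aliases are indexed after the same stemming
  applied to text; without this, matches between inflected text and the
  dictionary simply do not fire.
* **Coreference rule.** Within a chain, a member counts as the full form
  of an abbreviation when the abbreviation's letters are the member's
  word initials in order, or a prefix of the member. Document-local
  evidence beats the global dictionary. No word-sense disambiguation of
  ambiguous abbreviations is attempted.
* **Precedence.** A core that resolves directly wins over any
  expansions; the knowledge base is queried with the normalized core
  first, then the raw surface; only the top-ranked candidate becomes the
  mapping. Positionals are re-attached to knowledge-base-derived parts
  too, for uniformity.

## Knowledge sources

`kb_fixture()` reads explanations from a directory of plain-text files
(slug-named, with an optional `index.tsv`); `kb_live()` can query a
Wikipedia-style REST summary endpoint for the lead extract, treating
disambiguation pages as misses and distinguishing transport errors from
ordinary misses. Only the lead section is scored — explanation leads
concentrate the defining anatomical context, and page bodies drift.
Everything packaged and tested runs offline against fixture sources;
live-encyclopedia results are inherently unstable over time and are not
part of any claim.

## The synthetic benchmark

`generate_corpus()` builds mention/gold/knowledge-base triples that
exercise every cascade branch: direct mentions (formal names, aliases,
naive plurals, positional-prefixed forms, ~45% of the non-noise corpus),
dictionary abbreviations (~15%), knowledge-base-only pseudo-terms backed
by planted explanations (~40%), plus a `noise` fraction with no
knowledge-base entry whose gold label is "unmatched". Planted
explanations (`generate_explanation()`) place candidate parts at exact
offsets in a filler stream whose words are checked against the ontology,
and each plant is verified by `reference_argmax()` — a specification
whose distractor would win is rejected, never adjusted. Everything is
reproducible byte-for-byte from the seed.

What the generator does *not* emulate: clinical prose style, misspellings,
ambiguous abbreviations, special-character forms like "cad/chf" or
"hf-cells" (the tokenizer splits them into two tokens, which is
documented behaviour, not a correction), and real encyclopedia text whose
candidate structure is far messier. Perfect scores on the benchmark
therefore demonstrate that the machinery is sound — every solvable
mention is solved and the scorer agrees with its independent reference —
not that any particular accuracy would be reached on real discharge
summaries, whose gold corpus is access-restricted.

Problem sizes used by the packaged checks: 1,000 explanations for the
scorer/reference agreement, a 500-mention corpus for cascade soundness,
200 mentions (10% noise, ≥30% knowledge-base-only) for the
stage-ordering benchmark, and 100 mentions at zero noise for the
exact-solvability check, where the full cascade reaches F1 = 100% and
the baseline and normalization-only variants fall strictly below it, in
that order.

## Evaluation convention

`evaluate_mappings()` micro-averages over (mention, part) pairs, which
handles multi-part abbreviations gracefully: HEENT contributes five gold
pairs. Unmatched predictions assert nothing (they cost recall, not
precision). Matching is by part id, so "left extremity" and "extremity"
agree unless `strict_labels = TRUE`. These denominators are a documented
convention of this package, not a reproduction claim about any external
evaluation.

## Known limitations

* The tree below the nine regions is a curated subset; rare organs fall
  back to their region or to the knowledge base.
* One mention maps to one part per route; genuinely multi-site entities
  ("renal vein") resolve to a single answer by the longest-alias /
  deepest-node preference.
* Context is ignored: "right lower lobe" cannot be disambiguated between
  lung and liver without reading the surrounding sentence.
* The live knowledge source depends on current page content and is
  excluded from all tests.
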