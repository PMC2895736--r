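---
title: "Cleaning UMLS-style lexicons for concept recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning UMLS-style lexicons for concept recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umlstidy)
```

## The model

A concept-term table maps concept identifiers to surface strings. umlstidy
treats lexicon cleaning as two sets of deterministic, term-local rules plus a
global guard:

1. **Rewrite rules** (ids `"1"`–`"9"`) look at one term and emit zero or more
   candidate variants. They never modify the original term.
2. **Suppression rules** (ids `"S1"`–`"S8"`) look at one term and return a
   verdict with the trigger text that caused it.
3. The **guard** is the only global step: a candidate is admitted only if its
   normalized form is new across the whole lexicon. Candidates already
   present under the same concept are `skipped_duplicate`; present under a
   different concept, `skipped_homonym` (a generated homonym — logged,
   because admitting it would silently conflate two concepts); normalizing to
   the empty string, `skipped_empty`.

One normal form is shared by deduplication, the guard, and the recognizer:
characters in the class `[\p{P}*/@+=<>]` are replaced by a space (not
deleted), the string is lowercased, and whitespace is squeezed. Replacing
punctuation by spaces rather than deleting it is forced by strings like
`10*9/L`, which must become the three tokens `10 9 l` (deleting would fuse
them into one unmatchable token). Word counts, by contrast, are taken on the
*raw* string split at whitespace, so `insulin-like` is one word — this is
what makes the five-word length rule spare reasonable hyphenated names while
catching genuinely long rubrics.

### Rule inventory and parameters

| id | rule | key conditions |
|----|------|----------------|
| 1 | syntactic inversion | exactly one `", "`, no preposition/conjunction in the term |
| 2 | possessives | `'s` (either apostrophe) at a word end |
| 3 | short/long form | terminal parenthetical as short form, Schwartz–Hearst match |
| 4 | angular brackets | remove every `<…>` span |
| 5 | semantic type | terminal `(X)` where X names a semantic type |
| 6–9 | begin/end `()`/`[]` | balanced-depth group at term boundary; chemical exclusion |
| S1 | short token | after stopword removal, nothing left or only 1-char/arabic/roman tokens |
| S2 | dosages | number + unit (`%`, gram-, liter-family); `mg` deliberately excluded |
| S3 | at-sign | term contains `@` |
| S4 | EC numbers | case-sensitive `EC` + 2–4 dot-separated digit or `-` fields |
| S5 | classification | `NEC` positionally, or "unclassified"-family substrings |
| S6 | underspecification | `NOS` positionally, or "unspecified"-family substrings |
| S7 | miscellaneous | other/unknown/obsolete/deprecated/miscellaneous/no, positionally |
| S8 | words > 5 | more than five raw words; chemical exclusion |

Rule 3 implements the Schwartz–Hearst pairing: the short form must be 2–10
characters, at most two words, contain a letter, and start alphanumerically;
its characters are matched right-to-left inside a window of
`min(|SF| + 5, |SF| × 2)` words, the first character at a word start; both
the long and the short form are emitted. The pairing is deliberately
permissive — it reproduces known-incorrect pairs like `"Polibar Rapid (P/P)"`
— so rule 3 (and the qualifier-stripping rule 4) flag their output events
`review = TRUE`.

The **chemical exclusion** applies to rules 6–9 and S8: for concepts whose
semantic types map into the "Chemicals &amp; Drugs" semantic group, brackets
and length are chemically meaningful (`(S)-ibuprofen`, long systematic
names), so those rules never fire on them.

Two profiles bundle the rules: `recommended` (1–5, S1–S7) keeps only the
transformations judged safe; `full` adds the noisier bracket and length
rules.

### Pipeline order and idempotence

`apply_rules()` deduplicates within concepts (first record per normalized key
wins, preserving source order), computes per-concept chemical flags, runs the
rewrite rules in id order over the *original* terms only, then runs the
suppression rules in id order over originals and survivors alike. A
suppressed term is attributed to the **first** matching rule in id order, so
per-rule suppression counts are a partition, not independent tallies.

One design decision departs from a naive "rewrite, then suppress" order: a
candidate that an enabled suppression rule would remove is never admitted in
the first place; it is logged as `skipped_suppressed` with the would-be
suppressing rule in the `via` column. Without this, the pipeline would not be
idempotent — re-running it would regenerate the suppressed candidate (e.g.
rule 3 re-creating the short form `"P/P"` after S1 removed it), and the
second run would again report work done. With the filter, re-running the
recommended profile on its own output adds 0 and suppresses 0 terms, which
the test suite asserts on the bundled example lexicon.

The conservation identity `|output| = |input| + added − suppressed` holds on
every run and is checked in the acceptance tests.

### The recognizer

`build_index()` / `annotate()` implement a deliberately small dictionary
tagger: documents are tokenized with the shared normal form, and every
indexed token sequence occurring contiguously is reported — including terms
nested inside longer matches and overlapping matches ("largest match off").
Matching is token-exact, never substring, so "nose" cannot fire inside
"diagnosed". One match row is emitted per (occurrence, owning record), which
makes per-concept and per-string statistics exact even for homonymous keys.
The contract is equivalence with a brute-force quadratic scan, which the
tests enforce across 100 random fixtures.

## The fixture generator

`generate_lexicon()` builds a synthetic concept table from a seed: for each
rule, a term from a template that triggers exactly that rule, built from
nonsense consonant-vowel words that are globally unique across the fixture
and screened against the stopword, preposition, and keyword lists;
distractor terms that trigger nothing; engineered duplicate and homonym
collisions for the guard; and "Chemicals &amp; Drugs"-typed decoy copies of
the bracket/length templates, which must stay untouched. Ground truth records
the expected action per term. `generate_corpus()` plants chosen terms (with
case/hyphen surface variation) a known number of times among filler words
prefixed `zq`, a prefix absent from all lexicon words; it errors if any
lexicon key could occur by accident, so planted counts are exact by
construction, not approximately.

Template interactions needed care: a term like `"Word1 word2 (w)"` built for
the end-parenthesis rule can accidentally satisfy the Schwartz–Hearst pairing
too, so the rule-8 template uses a three-word parenthetical (never a valid
short form), and the templates for rules 3 and 5 are typed into the chemical
group so the bracket rules' exclusion keeps them single-rule. The semantic
type used by the rule-5 template is chosen so its initial differs from the
term's, blocking the abbreviation pairing.

**Realism and limits.** The generator makes structure, not language: terms
are pronounceable nonsense, one term per concept (plus engineered
collisions), and every rule fires exactly once per planted term. It cannot
measure real-world yield or precision — on a real UMLS release terms trigger
multiple rules at once, homonym rates are much higher, and rules 3/4 produce
genuinely wrong variants that only manual review catches. The fixtures
validate *bookkeeping* (guard outcomes, conservation, delta counts,
recognizer correctness), while the 50 bundled worked examples validate the
*linguistics* of each rule on real vocabulary strings. Scale is also modest
by design: fixture lexicons stay under ~50 terms and corpora under ~500
tokens so the quadratic oracle stays fast; the package code itself is
linear-ish in terms × rules and has no such limit.

## Numerical and resource choices

- There are no floating-point computations in the pipeline; all statistics
  are integer counts, and `homonym_pct` is the only derived ratio
  (100 × homonyms / (added + homonyms), defined as 0 when the denominator
  is 0). No tolerances are needed anywhere; tests use exact equality.
- The bundled stopword list is the 133-word PubMed list; it includes "no" and
  "while", which is why `"WHILE"` is suppressible as a term but `"no"` alone
  is excluded from whole-term keyword suppression (S7) — "No" is a legitimate
  abbreviation-like string, while "no complications" is a rubric.
- The bundled semantic-type name list is a 134-name snapshot of the UMLS
  Semantic Network type names circa 2007; "Instrument" is deliberately absent
  (it is not a semantic type), which is why `"Controls (Instrument)"` is left
  to the generic end-parenthesis rule rather than the semantic-type rule.
  Both lists, plus the preposition list and the dosage unit set, can be
  replaced per run through `rule_config()` or the YAML config.
- `mg` is excluded from the dosage units on purpose: strings like
  `"tablet 500 mg"` name a presentation strength that is often the only
  distinguishing term of a clinical-drug concept.
- Field positions in concept tables are declared by the `dialect` argument
  (`mrconso`: 18 fields, or `reduced`: 5 fields), never sniffed; malformed
  rows fail with their line number. Surviving original rows are written back
  byte-identically from the raw input line, so a read–apply–write round trip
  never reformats untouched data.

## Open questions resolved during implementation

- *What does "token" mean for the short-token rule?* Normalized tokens for
  the stopword/fragment tests, but raw whitespace words for the length rule
  S8 — the worked examples force this split (`10*9/L` must suppress as three
  fragments; `insulin-like growth factor binding` must count four words).
- *When is suppression attributed if several rules match?* First matching
  rule in id order; the report partitions suppressed terms.
- *Are generated homonyms errors?* No — they are expected output, logged
  with the colliding concept and reported as a per-rule homonym percentage,
  but excluded from the lexicon so matching never conflates concepts.
- *Is the empty-string candidate an error?* No — rules that strip a whole
  term (e.g. `<only>`) simply yield no candidate.

## Limitations

- Rules are English-centric (possessives, keyword lists); the default filter
  keeps only `ENG` rows.
- Rule 3 inherits Schwartz–Hearst's known false pairings; its output is
  flagged for review rather than auto-trusted.
- The semantic-type and semantic-group resources are bundled snapshots; for a
  current UMLS release, pass the release's own MRSTY and semantic-group
  files.
- The recognizer is an evaluation tool, not a production tagger: no
  tokenizer customization, no abbreviation disambiguation, and quadratic
  worst-case behavior is accepted in the oracle used for testing.
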