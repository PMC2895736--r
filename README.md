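# umlstidy

Rewrite and suppression rules for UMLS-style biomedical lexicons.

## The problem

Biomedical concept recognition — finding mentions of controlled-vocabulary
concepts in free text — usually starts from a terminological resource such as
the UMLS Metathesaurus. Those resources were built for human coders, not for
text mining, so many of their term strings never occur in prose ("Failure,
Renal"; "Chondria &lt;beetle&gt;"; "[D]Respiratory abnormalities"), while
others match text they should not (the stopword "WHILE" as a concept term,
dosage strings like "Oxygen 2%", bare classification rubrics like "Other").
Using such a lexicon as-is hurts both recall (natural variants are missing)
and precision (junk terms match everywhere).

umlstidy cleans a concept-term table in two directions:

- **Nine rewrite rules** generate natural variants from existing terms:
  syntactic inversion of comma-inverted phrases, possessive stripping,
  abbreviation short-form/long-form extraction via the Schwartz–Hearst
  character-matching algorithm, removal of angular-bracket qualifiers,
  removal of terminal semantic-type tags, and removal of begin/end
  parenthetical and square-bracket groups (the latter four skipped for
  concepts in the "Chemicals &amp; Drugs" semantic group, where brackets are
  chemically meaningful).
- **Eight suppression rules** remove terms judged harmful for matching:
  stopword/fragment-only terms, dosages, at-signs, EC enzyme numbers,
  NEC/classification rubrics, NOS/underspecification rubrics, miscellaneous
  keyword rubrics ("Other …", "unknown …"), and terms longer than five words
  (again sparing chemicals, whose names are legitimately long).

Every generated candidate passes a **guard**: it is dropped if it duplicates
an existing term of the same concept, dropped and logged if it collides with
a term of a *different* concept (a generated homonym), dropped if it
normalizes to nothing, and dropped if an enabled suppression rule would
immediately remove it again. The guard makes the pipeline idempotent: running
it on its own output changes nothing.

A small recognizer (case- and punctuation-insensitive token-sequence lookup,
largest-match off) and a before/after delta report let you measure what each
rule contributes on a corpus.

## Worked example

Individual rules are plain functions:

```r
library(umlstidy)

rw_syntactic_inversion("Failure, Renal")
#> [1] "Renal Failure"

rw_short_long_form("Selective Serotonin Reuptake Inhibitors (SSRIs)")
#> [1] "Selective Serotonin Reuptake Inhibitors"
#> [2] "SSRIs"

sp_dosages("Oxygen 2%")
#> $suppressed
#> [1] TRUE
#> $trigger
#> [1] "2%"
```

The full pipeline runs over a concept table (pipe-delimited; either the
18-field MRCONSO layout or the bundled 5-field reduced dialect). The package
ships a 36-concept example lexicon:

```r
g <- golden_fixture()
lexicon <- as_lexicon(read_concept_table(g$concept_table, dialect = "reduced"))
semmap  <- read_semantic_types(g$semantic_types, g$semantic_groups)

outcome <- apply_rules(lexicon, semmap, rule_config("recommended"))
outcome
#> <rule_outcome> 36 terms out (12 added, 12 suppressed, 0 homonym collisions)

outcome$report[outcome$report$added + outcome$report$suppressed > 0,
               c("rule_id", "rule", "added", "suppressed")]
#>    rule_id rule                   added suppressed
#>  1 1       syntactic_inversion        3          0
#>  2 2       possessives                2          0
#>  3 3       short_long_form            3          0
#>  4 4       angular_brackets           2          0
#>  5 5       semantic_type              2          0
#>  6 S1      short_token                0          2
#>  7 S2      dosages                    0          1
#>  8 S3      at_sign                    0          1
#>  9 S4      ec_numbers                 0          2
#> 10 S5      any_classification         0          2
#> 11 S6      any_underspecification     0          2
#> 12 S7      miscellaneous              0          2
```

The generated variants immediately pay off in matching — neither
"renal failure" nor "SSRIs" exists in the raw table:

```r
index <- build_index(outcome$lexicon)
annotate("Patient in renal failure; SSRIs were continued.", index)[,
  c("token_start", "token_end", "key", "concept_id", "provenance")]
#>   token_start token_end key           concept_id provenance
#> 1           3         5 renal failure C0000001   generated
#> 2           5         6 ssris         C0000004   generated
```

Two profiles are built in: `"recommended"` (rewrite rules 1–5 plus
suppression rules S1–S7 — the conservative set) and `"full"` (all 17 rules,
including the bracket-stripping rules 6–9 and the five-word length cutoff S8,
which are noisier). `rule_config()` / `rule_config_from_yaml()` select
profiles, individual rules, and replacement resource lists (stopwords,
semantic-type names, prepositions, dosage units).

A command-line wrapper with `apply`, `delta`, and `profiles` subcommands is
installed at `system.file("cli", "umlstidy.R", package = "umlstidy")`.

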