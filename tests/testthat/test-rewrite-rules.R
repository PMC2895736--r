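test_that("syntactic inversion flips exactly-one-comma terms without prepositions", {
  expect_identical(rw_syntactic_inversion("Failure, Renal"), "Renal Failure")
  expect_identical(rw_syntactic_inversion("Anemia, NOS"), "NOS Anemia")
  # two commas, prepositions/conjunctions, or no comma: nothing generated
  expect_length(rw_syntactic_inversion("Failure, Renal, Acute"), 0L)
  expect_length(rw_syntactic_inversion("Bandages, and dressings"), 0L)
  expect_length(rw_syntactic_inversion("Pain, of head"), 0L)
  expect_length(rw_syntactic_inversion("Renal Failure"), 0L)
})

test_that("possessive rule strips 's at word ends, both apostrophes", {
  expect_identical(rw_possessives("Alzheimer's disease"), "Alzheimer disease")
  expect_identical(rw_possessives("Crohn's"), "Crohn")
  expect_identical(rw_possessives("Alzheimer’s disease"),
                   "Alzheimer disease")
  # mid-word apostropheless or no possessive: nothing generated
  expect_length(rw_possessives("disease"), 0L)
  expect_length(rw_possessives("it's sick's"), 1L)
})

test_that("short/long-form pairing emits both forms when the match holds", {
  expect_setequal(
    rw_short_long_form("Selective Serotonin Reuptake Inhibitors (SSRIs)"),
    c("Selective Serotonin Reuptake Inhibitors", "SSRIs"))
  # the known-incorrect pairing is still generated by design
  expect_setequal(rw_short_long_form("Polibar Rapid (P/P)"),
                  c("Polibar Rapid", "P/P"))
})

test_that("short/long-form pairing rejects non-abbreviation parentheticals", {
  # first letters differ
  expect_length(rw_short_long_form("treatment of pain (MI)"), 0L)
  # short form longer than 10 characters / more than 2 words
  expect_length(rw_short_long_form("pain (chronic ongoing misery)"), 0L)
  # short form must contain a letter
  expect_length(rw_short_long_form("score between (1;2)"), 0L)
  # no parenthetical at the end
  expect_length(rw_short_long_form("plain term"), 0L)
})

test_that("angular bracket spans are removed wherever they occur", {
  expect_identical(rw_angular_brackets("Chondria <beetle>"), "Chondria")
  expect_identical(rw_angular_brackets("every <integer> weeks"), "every weeks")
  # a term that is nothing but a bracketed span collapses to empty: dropped
  expect_length(rw_angular_brackets("<only>"), 0L)
  expect_length(rw_angular_brackets("no brackets"), 0L)
})

test_that("semantic-type rule strips only terminal parentheticals naming a type", {
  expect_identical(rw_semantic_type("Surgical intervention (finding)"),
                   "Surgical intervention")
  expect_identical(
    rw_semantic_type("Heart (Body Part, Organ, or Organ Component)"), "Heart")
  # "Instrument" is not in the bundled type list: not stripped by this rule
  expect_length(rw_semantic_type("Controls (Instrument)"), 0L)
  expect_length(rw_semantic_type("Surgical (finding) intervention"), 0L)
})

test_that("begin/end bracket rules strip balanced groups with depth tracking", {
  expect_identical(rw_begin_parentheses("(protein) methionine-R-sulfoxide reductase"),
                   "methionine-R-sulfoxide reductase")
  expect_identical(rw_begin_parentheses("(2-5')oligo(A) synthetase activity"),
                   "oligo(A) synthetase activity")
  expect_identical(rw_begin_brackets("[D]Respiratory abnormalities"),
                   "Respiratory abnormalities")
  expect_identical(
    rw_begin_brackets("[pyruvate dehydrogenase (lipoamide)] phosphatase activity"),
    "phosphatase activity")
  expect_identical(rw_end_parentheses("t(3;6)(p13;q25)"), "t(3;6)")
  expect_identical(rw_end_parentheses("Controls (Instrument)"), "Controls")
  expect_identical(rw_end_brackets("Abstracts [Publication Type]"), "Abstracts")
  expect_identical(rw_end_brackets("Shigella flexneri 2a [II:3,4]"),
                   "Shigella flexneri 2a")
  # unbalanced groups are left alone
  expect_length(rw_end_parentheses("broken (paren"), 0L)
  expect_length(rw_begin_brackets("[broken term"), 0L)
})

test_that("bracket rules and only bracket rules honor the chemical exclusion", {
  chem_cases <- list(
    function(ch) rw_begin_parentheses("(S)-ibuprofen", ch),
    function(ch) rw_begin_brackets("[S]-ibuprofen", ch),
    function(ch) rw_end_parentheses("ibuprofen (racemic)", ch),
    function(ch) rw_end_brackets("ibuprofen [racemic]", ch)
  )
  for (f in chem_cases) {
    expect_gt(length(f(FALSE)), 0L)
    expect_length(f(TRUE), 0L)
  }
})

test_that("rewrite rules never emit the unchanged input or empty strings", {
  inputs <- c("Failure, Renal", "Alzheimer's disease", "<only>", "(x)",
              "Polibar Rapid (P/P)", "t(3;6)(p13;q25)", "plain")
  for (rid in as.character(1:9)) {
    for (t in inputs) {
      out <- run_rewrite(rid, t)
      expect_false(any(out == t), info = paste(rid, t))
      expect_false(any(!nzchar(trimws(out))), info = paste(rid, t))
    }
  }
})
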