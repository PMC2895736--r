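test_that("profiles expose the conservative and the full rule sets", {
  p <- rule_profiles()
  expect_setequal(p$recommended, c(as.character(1:5), paste0("S", 1:7)))
  expect_setequal(p$full, c(as.character(1:9), paste0("S", 1:8)))
})

test_that("rule_config validates rule ids and profile names", {
  cfg <- rule_config("recommended")
  expect_s3_class(cfg, "rule_config")
  expect_error(rule_config(rules = c("1", "S99")))
  expect_error(rule_config("aggressive"))
})

test_that("yaml configuration round-trips profile, rules and resources", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("profile: full",
               "rules: ['1', '2', 'S1']",
               "keep_homonyms: true"), path)
  cfg <- rule_config_from_yaml(path)
  expect_setequal(cfg$rules, c("1", "2", "S1"))
  expect_true(cfg$keep_homonyms)
  # a missing resource file fails up front, before any lexicon work
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("profile: full",
               "resources:",
               "  stopwords: /nonexistent/stopwords.txt"), bad)
  expect_error(rule_config_from_yaml(bad))
})

test_that("the duplicate guard distinguishes duplicates, homonyms and empties", {
  path <- tempfile(fileext = ".psv")
  writeLines(c("C1|ENG|S1|N|renal failure|",
               "C2|ENG|S2|N|heart attack|"), path)
  lex <- as_lexicon(read_concept_table(path, "reduced"))
  # same concept, same key: duplicate
  expect_identical(guard_candidate("Renal Failure", "C1", lex),
                   "skipped_duplicate")
  # other concept already owns the key: homonym
  expect_identical(guard_candidate("HEART ATTACK", "C1", lex),
                   "skipped_homonym")
  # normalizes to nothing: empty
  expect_identical(guard_candidate("***", "C1", lex), "skipped_empty")
  # novel key: added, and the index now knows it
  expect_identical(guard_candidate("kidney shutdown", "C1", lex), "added")
  expect_identical(guard_candidate("kidney shutdown", "C1", lex),
                   "skipped_duplicate")
  expect_identical(guard_candidate("Kidney  Shutdown", "C2", lex),
                   "skipped_homonym")
})

test_that("engineered collisions land in the ground-truth guard outcome", {
  spec <- fixture_spec(seed = 11L, homonym_collisions = 2L,
                       duplicate_collisions = 2L)
  fx <- generate_lexicon(spec)
  lex <- as_lexicon(read_concept_table(fx$concept_table, "reduced"))
  sm <- read_semantic_types(fx$semantic_types, fx$semantic_groups)
  out <- apply_rules(lex, sm, rule_config("full"))
  gt <- fx$ground_truth
  planted <- gt[gt$expected_action != "none", , drop = FALSE]
  for (i in seq_len(nrow(planted))) {
    row <- planted[i, ]
    if (row$expected_action == "added") {
      gen <- lexicon_records(out$lexicon)
      gen <- gen[gen$provenance == "generated" &
                   gen$concept_id == row$concept_id, , drop = FALSE]
      wanted <- strsplit(row$expected_text, ";", fixed = TRUE)[[1]]
      expect_true(all(wanted %in% gen$text),
                  info = paste(row$category, row$text))
    } else if (row$expected_action == "suppressed") {
      expect_true(row$string_id %in% out$suppressed$string_id,
                  info = row$text)
    } else {
      ev <- out$events
      hit <- ev[ev$concept_id == row$concept_id &
                  ev$action == row$expected_action, , drop = FALSE]
      expect_gt(nrow(hit), 0L)
    }
  }
})

test_that("record conservation holds: output = input + added - suppressed", {
  for (seed in c(1L, 5L, 23L)) {
    fx <- generate_lexicon(fixture_spec(seed = seed))
    lex <- as_lexicon(read_concept_table(fx$concept_table, "reduced"))
    sm <- read_semantic_types(fx$semantic_types, fx$semantic_groups)
    n_in <- nrow(lexicon_records(lex))
    out <- apply_rules(lex, sm, rule_config("full"))
    n_out <- nrow(lexicon_records(out$lexicon))
    expect_identical(n_out,
                     n_in + sum(out$report$added) - sum(out$report$suppressed))
    expect_identical(nrow(out$suppressed), sum(out$report$suppressed))
  }
})

test_that("the engine is deterministic", {
  g <- golden_setup()
  a <- apply_rules(g$lexicon, g$semmap, rule_config("full"))
  b <- apply_rules(g$lexicon, g$semmap, rule_config("full"))
  expect_identical(lexicon_records(a$lexicon), lexicon_records(b$lexicon))
  expect_identical(a$report, b$report)
  expect_identical(a$events, b$events)
})

test_that("suppression is attributed to the first matching rule in id order", {
  path <- tempfile(fileext = ".psv")
  # matches S6 (", NOS") and S7 would never see it; also 6 words matches S8
  writeLines("C1|ENG|S1|N|Other unspecified disorders of the back|", path)
  lex <- as_lexicon(read_concept_table(path, "reduced"))
  out <- apply_rules(lex, config = rule_config("full"))
  expect_identical(out$suppressed$suppressed_by, "S6")
})

test_that("single-rule deltas sum to the recommended-profile report", {
  g <- golden_setup()
  full <- apply_rules(g$lexicon, g$semmap, rule_config("recommended"))
  for (rid in rule_profiles()$recommended) {
    solo <- single_rule_delta(g$lexicon, g$semmap, rule_id = rid)
    row <- full$report[full$report$rule_id == rid, ]
    if (startsWith(rid, "S")) {
      # alone, a suppression rule sees terms that earlier rules claimed in
      # the combined run, so it suppresses at least as many
      expect_gte(solo$suppressed, row$suppressed)
    } else {
      # a rewrite rule alone has no suppression filter, so it adds at least
      # as many terms as in the combined run
      expect_gte(solo$added, row$added)
    }
  }
})

test_that("events carry review flags for the uncertain rules", {
  g <- golden_setup()
  out <- apply_rules(g$lexicon, g$semmap, rule_config("recommended"))
  ev <- out$events
  added <- ev[ev$action == "added", , drop = FALSE]
  expect_true(all(added$review[added$rule_id %in% c("3", "4")]))
  expect_false(any(added$review[!(added$rule_id %in% c("3", "4"))]))
})
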