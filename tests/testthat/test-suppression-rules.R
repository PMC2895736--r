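test_that("short-token rule suppresses stopword-only and fragment-only terms", {
  expect_true(run_suppression("S1", "10*9/L"))
  expect_true(run_suppression("S1", "WHILE"))      # stopword, case-blind
  expect_true(run_suppression("S1", "A IV 7"))     # single char + roman + arabic
  expect_true(run_suppression("S1", "of the"))     # nothing left after stopwords
  expect_false(run_suppression("S1", "protein X")) # "protein" survives
  expect_false(run_suppression("S1", "Renal failure"))
})

test_that("dosage rule fires on number-unit pairs but not bare vitamins", {
  expect_true(run_suppression("S2", "Oxygen 2%"))
  expect_true(run_suppression("S2", "Paracetamol 500 gram"))
  expect_true(run_suppression("S2", "saline 0.9 ml"))
  expect_true(run_suppression("S2", "ethanol 70 percent"))
  expect_false(run_suppression("S2", "Vitamin B12"))   # no free-standing number
  expect_false(run_suppression("S2", "tablet 500 mg")) # mg deliberately excluded
  expect_false(run_suppression("S2", "route 66 miles"))
})

test_that("at-sign rule suppresses any term containing @", {
  expect_true(run_suppression("S3", "ADHESIVE @@ BANDAGE"))
  expect_true(run_suppression("S3", "a@b"))
  expect_false(run_suppression("S3", "bandage"))
})

test_that("EC-number rule is case-sensitive and accepts dash wildcards", {
  expect_true(run_suppression("S4", "EC 2.7.1.112"))
  expect_true(run_suppression("S4", "EC 2.7.1.-"))
  expect_true(run_suppression("S4", "kinase EC 2.7.1.112 activity"))
  expect_false(run_suppression("S4", "ECG 2.7"))
  expect_false(run_suppression("S4", "ec 2.7.1.112"))   # lowercase: kept
  expect_false(run_suppression("S4", "EC 2"))           # too few fields
})

test_that("classification rule catches NEC codes and classification phrases", {
  expect_true(run_suppression("S5", "Unclassified sequences"))
  expect_true(run_suppression("S5", "Injury, NEC"))
  expect_true(run_suppression("S5", "Injury (NEC)"))
  expect_true(run_suppression("S5", "fracture without mention of complication"))
  expect_true(run_suppression("S5", "Injuries not elsewhere classified"))
  expect_false(run_suppression("S5", "NECROSIS"))       # substring of a word
  expect_false(run_suppression("S5", "nec plus ultra")) # wrong position/case
})

test_that("underspecification rule catches NOS codes and unspecified phrases", {
  expect_true(run_suppression("S6", "Other and unspecified leukaemia"))
  expect_true(run_suppression("S6", "Anemia, NOS"))
  expect_true(run_suppression("S6", "Anemia [NOS]"))
  expect_true(run_suppression("S6", "site not specified"))
  expect_true(run_suppression("S6", "Asthma, not otherwise specified"))
  expect_false(run_suppression("S6", "DIAGNOSIS"))
  expect_false(run_suppression("S6", "nosocomial infection"))
})

test_that("miscellaneous keywords suppress positionally, 'no' only with a space", {
  expect_true(run_suppression("S7", "Other"))
  expect_true(run_suppression("S7", "Other diseases"))
  expect_true(run_suppression("S7", "unknown substance"))
  expect_true(run_suppression("S7", "deprecated concept"))
  expect_true(run_suppression("S7", "disorders, other"))
  expect_true(run_suppression("S7", "no complications"))
  expect_false(run_suppression("S7", "Mother"))      # not at a keyword position
  expect_false(run_suppression("S7", "no"))          # bare "no" is kept
  expect_false(run_suppression("S7", "nosebleed"))
})

test_that("long-term rule counts raw whitespace words and spares chemicals", {
  expect_true(run_suppression("S8", "Head and Neck Squamous Cell Carcinoma"))
  expect_true(run_suppression("S8",
    "insulin-like growth factor binding protein 1"))
  expect_false(run_suppression("S8", "insulin-like growth factor binding"))
  expect_false(run_suppression("S8",
    "Head and Neck Squamous Cell Carcinoma", in_chem_group = TRUE))
})

test_that("suppression verdicts report the matched trigger text", {
  expect_match(sp_dosages("Oxygen 2%")$trigger, "2%", fixed = TRUE)
  expect_match(sp_ec_number("EC 2.7.1.112")$trigger, "EC 2.7.1.112",
               fixed = TRUE)
  expect_identical(sp_at_sign("bandage")$trigger, "")
})

test_that("random alphabetic multiword terms are only ever hit by the length rule", {
  # fuzz property: terms of 2-5 plain lowercase letter words contain no
  # dosage, code, bracket, or keyword trigger, so S2-S7 must all keep them
  set.seed(421)
  alpha <- function() paste(sample(letters[1:20], sample(3:8, 1),
                                   replace = TRUE), collapse = "")
  for (i in 1:50) {
    words <- replicate(sample(2:5, 1), alpha())
    term <- paste(words, collapse = " ")
    for (rid in c("S2", "S3", "S4", "S5", "S6")) {
      expect_false(run_suppression(rid, term), info = paste(rid, term))
    }
  }
})
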