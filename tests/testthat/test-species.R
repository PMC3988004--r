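test_that("canonical species naming is deterministic and order-independent", {
  expect_identical(canonicalSpeciesName(c("PER", "CRY1"), "nucleus"),
                   canonicalSpeciesName(c("CRY1", "PER"), "nucleus"))
  expect_identical(canonicalSpeciesName(c("B", "A"), "cytoplasm"), "A:B_cyt")
})

test_that("complex enumeration matches the brute-force subset oracle", {
  rules <- defaultChronoBindingRules("interaction")
  # add the non-CHRONO contacts needed for higher-order complexes
  rules <- makeBindingRules(rbind(rules, data.frame(
    partnerA = c("BMAL1", "BMAL1", "PER2"),
    partnerB = c("PER2", "CRY2", "CRY2"),
    allowed = c(TRUE, TRUE, TRUE))))
  base_sets <- list(
    c("BMAL1", "PER2", "CRY2", "DEC2"),
    c("BMAL1", "PER1", "PER2", "CRY1", "CRY2", "DEC1"),
    c("PER1", "CRY1"),
    c("BMAL1", "PER2", "CRY2"))
  for (base in base_sets) for (ms in 2:4) {
    got <- enumerateChronoComplexes(base, rules, maxSize = ms)
    expect_identical(sort(got$name),
                     bruteForceChronoComplexes(base, rules, ms),
                     info = sprintf("base={%s}, maxSize=%d",
                                    paste(base, collapse = ","), ms))
  }
})

test_that("binding-assay partners give exactly four heterodimers", {
  rules <- defaultChronoBindingRules("interaction")
  got <- enumerateChronoComplexes(
    c("BMAL1", "PER2", "CRY2", "DEC2"), rules, maxSize = 2)
  expect_equal(nrow(got), 4)
  expect_true(all(vapply(got$constituents, function(x)
    "CHRONO" %in% x && length(x) == 2, logical(1))))
})

test_that("forbidden partners never appear in generated complexes", {
  rules <- defaultChronoBindingRules("interaction")
  got <- enumerateChronoComplexes(
    c("BMAL1", "PER1", "PER2", "CRY1", "CRY2", "DEC1", "DEC2"),
    rules, maxSize = 2)
  all_members <- unlist(got$constituents)
  expect_false(any(c("PER1", "CRY1", "DEC1") %in% all_members))
})

test_that("enumeration handles the empty base set and unknown monomers", {
  rules <- defaultChronoBindingRules("interaction")
  expect_equal(nrow(enumerateChronoComplexes(character(0), rules, 3)), 0)
  expect_error(enumerateChronoComplexes(c("NOTAPROTEIN"), rules, 2),
               "do not cover|unknown")
})

test_that("conflicting binding rules are rejected", {
  expect_error(makeBindingRules(data.frame(
    partnerA = c("CHRONO", "PER2"), partnerB = c("PER2", "CHRONO"),
    allowed = c(TRUE, FALSE))), "conflicting")
})
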