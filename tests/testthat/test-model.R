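test_that("reduced model passes its structural invariants", {
  m <- buildReducedModel()
  expect_true(validObject(m))
  expect_true("Chrono_mRNA" %in% speciesNames(m))
  expect_true("A:CHRONO:PER_nuc" %in% speciesNames(m))
  # every E-box gene lists the CHRONO sequestration channel
  for (tr in m@transcription)
    if (tr$type == "ebox")
      expect_true("CHRONO:PER_nuc" %in% tr$channels, info = tr$gene)
  expect_true(conservationAudit(m))
})

test_that("disabling CHRONO removes exactly the CHRONO-containing species", {
  m1 <- buildReducedModel()
  m0 <- buildReducedModel(list(chrono_enabled = FALSE))
  chrono_species <- speciesNames(m1)[vapply(
    m1@species$constituents, function(x) "CHRONO" %in% x, logical(1))]
  chrono_species <- union(chrono_species, "Chrono_mRNA")
  expect_setequal(setdiff(speciesNames(m1), speciesNames(m0)),
                  chrono_species)
  expect_equal(nrow(m1@species) - nrow(m0@species), length(chrono_species))
})

test_that("Chrono mRNA decay is tied to the Per2 decay parameter", {
  m <- buildReducedModel()
  decay_of <- function(mrna) {
    hits <- Filter(function(r)
      identical(names(r$reactants), mrna) && length(r$products) == 0,
      m@reactions)
    vapply(hits, `[[`, character(1), "rate")
  }
  expect_identical(decay_of("Chrono_mRNA"), decay_of("Per2_mRNA"))
})

test_that("missing parameter keys are reported by name", {
  pf <- withr::local_tempfile(fileext = ".yaml")
  writeLines("v_per1: 1.0", pf)
  expect_error(buildReducedModel(list(parameter_file = pf)),
               "missing required keys.*v_per2")
})

test_that("model JSON serialization round-trips", {
  m <- buildReducedModel()
  path <- withr::local_tempfile(fileext = ".json")
  writeModelJson(m, path)
  m2 <- readModelJson(path)
  expect_identical(speciesNames(m2), speciesNames(m))
  expect_equal(parameterValues(m2), parameterValues(m))
  expect_equal(length(m2@reactions), length(m@reactions))
  expect_identical(modelGenes(m2), modelGenes(m))
})

test_that("detailed mode requires an external base model", {
  expect_error(buildDetailedModel(tempfile("missing")),
               "detailed mode requires external base model")
})

test_that("detailed-mode extension counts new variables and guards idempotence", {
  # synthetic stand-in base model: the real published base is not bundled
  base <- buildReducedModel(list(chrono_enabled = FALSE))
  base_path <- withr::local_tempfile(fileext = ".json")
  writeModelJson(base, base_path)
  rules <- defaultChronoBindingRules("model")
  rules <- makeBindingRules(rbind(rules, data.frame(
    partnerA = "BMAL1", partnerB = "PER2", allowed = TRUE)))
  det <- buildDetailedModel(base_path, list(binding_rules = rules,
                                            max_complex_size = 3))
  base_monomers <- unique(unlist(
    base@species$constituents[base@species$kind != "mRNA"]))
  candidates <- intersect(base_monomers,
                          unique(c(rules$partnerA, rules$partnerB)))
  expected_complexes <- bruteForceChronoComplexes(candidates, rules, 3)
  # added variables = Chrono mRNA + CHRONO monomer + permitted complexes
  expect_equal(det@metadata$newly_added_variable_count,
               2 + length(expected_complexes))
  expect_equal(nrow(det@species) - nrow(base@species),
               det@metadata$newly_added_variable_count)
  # applying the extension twice must fail, not silently duplicate
  det_path <- withr::local_tempfile(fileext = ".json")
  writeModelJson(det, det_path)
  expect_error(buildDetailedModel(det_path), "already present")
})

test_that("a zero-species base file is rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version":"1.0","species":[],"parameters":[]}', path)
  expect_error(buildDetailedModel(path), "zero species|invalid|malformed")
})
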