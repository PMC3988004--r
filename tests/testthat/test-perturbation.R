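test_that("perturbation mini-grammar parses and round-trips", {
  ps <- parsePerturbations("Cry2:kd:0.3,Chrono:oe,Cry1:ko")
  expect_length(ps, 3)
  expect_equal(ps[[1]]$action, "knockdown")
  expect_equal(ps[[1]]$fraction, 0.3)
  expect_equal(ps[[2]]$action, "overexpress")
  expect_equal(ps[[3]]$action, "knockout")
  expect_equal(parsePerturbations(""), list())
  expect_error(parsePerturbations("Cry2:kd"), "fraction")
  expect_error(parsePerturbations("Cry2:xx"), "unknown perturbation action")
  expect_error(perturbation("Cry2", "knockdown", fraction = 1.5),
               "fraction")
})

test_that("Cry2 knockdown to 30% scales both transcription rates by 0.3", {
  m <- buildReducedModel()
  kd <- applyPerturbation(m, "Cry2:kd:0.3")
  pv0 <- parameterValues(m); pv1 <- parameterValues(kd)
  expect_equal(pv1[["v_cry2"]], 0.3 * pv0[["v_cry2"]])
  expect_equal(pv1[["basal_cry2"]], 0.3 * pv0[["basal_cry2"]])
  # everything else untouched; the input model is not modified
  other <- setdiff(names(pv0), c("v_cry2", "basal_cry2"))
  expect_equal(pv1[other], pv0[other])
  expect_equal(parameterValues(m), pv0)
})

test_that("knockdown with fraction 1 is the identity on parameters", {
  m <- buildReducedModel()
  kd <- applyPerturbation(m, "Per1:kd:1.0")
  expect_equal(parameterValues(kd), parameterValues(m))
  expect_equal(length(kd@reactions), length(m@reactions))
})

test_that("knockouts commute: model content is order-independent", {
  m <- buildReducedModel()
  ab <- applyPerturbation(m, "Cry1:ko,Cry2:ko")
  ba <- applyPerturbation(m, "Cry2:ko,Cry1:ko")
  expect_identical(ab@species, ba@species)
  expect_identical(ab@reactions, ba@reactions)
  expect_identical(ab@transcription, ba@transcription)
  expect_equal(ab@parameters, ba@parameters)
})

test_that("knockout and knockdown preserve the species count; overexpression adds one production term", {
  m <- buildReducedModel()
  expect_equal(nrow(applyPerturbation(m, "Cry1:ko")@species),
               nrow(m@species))
  expect_equal(nrow(applyPerturbation(m, "Cry2:kd:0.5")@species),
               nrow(m@species))
  oe <- applyPerturbation(m, "Chrono:oe")
  expect_equal(nrow(oe@species), nrow(m@species))
  expect_equal(length(oe@reactions), length(m@reactions) + 1)
  added <- oe@reactions[[length(oe@reactions)]]
  expect_length(added$reactants, 0)
  expect_identical(names(added$products), "CHRONO_cyt")
})

test_that("perturbing an unknown gene names the available genes", {
  m <- buildReducedModel()
  expect_error(applyPerturbation(m, "Dec2:ko"), "available genes.*Per1")
})
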