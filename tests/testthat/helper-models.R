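# tiny hand-built models used as integration oracles

# single species with first-order decay d, no transcription
decayModel <- function(d = 0.5) {
  sp <- chronoclock:::speciesRow("X_cyt", "cytoplasm", "monomer", "X")
  new("ModelSpec",
      species = sp,
      reactions = list(chronoclock:::reaction(c(X_cyt = 1), c(), "d")),
      transcription = list(),
      bindingRules = makeBindingRules(data.frame(
        partnerA = character(0), partnerB = character(0),
        allowed = logical(0))),
      parameters = data.frame(name = "d", value = d, unit = "1/h"),
      mode = "reduced", metadata = list(perturbations = list()))
}

# isolated reversible binding A + B <-> C (no production, no decay)
bindingModel <- function(kon = 2, koff = 0.5) {
  sp <- rbind(
    chronoclock:::speciesRow("A_cyt", "cytoplasm", "monomer", "A"),
    chronoclock:::speciesRow("B_cyt", "cytoplasm", "monomer", "B"),
    chronoclock:::speciesRow("A:B_cyt", "cytoplasm", "complex",
                             c("A", "B")))
  new("ModelSpec",
      species = sp,
      reactions = list(
        chronoclock:::reaction(c(A_cyt = 1, B_cyt = 1), c(`A:B_cyt` = 1),
                               "kon"),
        chronoclock:::reaction(c(`A:B_cyt` = 1), c(A_cyt = 1, B_cyt = 1),
                               "koff")),
      transcription = list(),
      bindingRules = makeBindingRules(data.frame(
        partnerA = "A", partnerB = "B", allowed = TRUE)),
      parameters = data.frame(name = c("kon", "koff"),
                              value = c(kon, koff),
                              unit = c("1/(conc.h)", "1/h")),
      mode = "reduced", metadata = list(perturbations = list()))
}

# brute-force oracle: all subsets containing CHRONO whose pairwise
# contacts are allowed, enumerated independently of the implementation
bruteForceChronoComplexes <- function(baseMonomers, rules, maxSize) {
  baseMonomers <- setdiff(baseMonomers, "CHRONO")
  allowed <- function(a, b) {
    pa <- pmin(a, b); pb <- pmax(a, b)
    hit <- rules$partnerA == pa & rules$partnerB == pb
    any(hit) && rules$allowed[which(hit)[1]]
  }
  out <- character(0)
  nb <- length(baseMonomers)
  if (nb == 0) return(out)
  for (mask in seq_len(2^nb - 1)) {
    s <- baseMonomers[bitwAnd(mask, 2^(seq_len(nb) - 1)) > 0]
    members <- c("CHRONO", s)
    if (length(members) < 2 || length(members) > maxSize) next
    ok <- TRUE
    for (i in seq_along(members)) for (j in seq_along(members))
      if (i < j && !allowed(members[i], members[j])) ok <- FALSE
    if (ok) out <- c(out, canonicalSpeciesName(members, "nucleus"))
  }
  sort(out)
}

# a cached wild-type model + limit-cycle snapshot shared across tests
wtModelCache <- new.env(parent = emptyenv())
cachedWtModel <- function() {
  if (is.null(wtModelCache$model))
    wtModelCache$model <- buildReducedModel()
  wtModelCache$model
}
cachedWtState <- function() {
  if (is.null(wtModelCache$state))
    wtModelCache$state <- limitCycleState(cachedWtModel())
  wtModelCache$state
}
cachedWtVerdict <- function() {
  if (is.null(wtModelCache$verdict))
    wtModelCache$verdict <- findCycle(cachedWtModel())
  wtModelCache$verdict
}
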