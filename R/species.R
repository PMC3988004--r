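#' @include AllClasses.R
NULL

compartmentSuffix <- c(cytoplasm = "_cyt", nucleus = "_nuc")

#' Canonical species name
#'
#' Complexes and monomers are named by their alphabetically sorted
#' constituents joined by \code{":"}, with a compartment suffix
#' (\code{_cyt} / \code{_nuc}); mRNAs as \code{<Gene>_mRNA}.  Sorting makes
#' the naming deterministic and order-independent.
#'
#' @param constituents character vector (multiset) of monomer names.
#' @param compartment \code{"cytoplasm"} or \code{"nucleus"}.
#' @return a single canonical name.
#' @export
canonicalSpeciesName <- function(constituents, compartment) {
  stopifnot(length(constituents) >= 1)
  compartment <- match.arg(compartment, c("cytoplasm", "nucleus"))
  paste0(paste(sort(constituents, method = "radix"), collapse = ":"),
         compartmentSuffix[[compartment]])
}

speciesRow <- function(name, compartment, kind, constituents = character()) {
  if (length(name) == 0)
    return(data.frame(name = character(0), compartment = character(0),
                      kind = character(0),
                      constituents = I(list()),
                      stringsAsFactors = FALSE))
  data.frame(name = name, compartment = compartment, kind = kind,
             constituents = I(list(constituents)),
             stringsAsFactors = FALSE)
}

mrnaSpecies <- function(gene) {
  speciesRow(paste0(gene, "_mRNA"), "cytoplasm", "mRNA")
}

monomerSpecies <- function(monomer, compartment) {
  speciesRow(canonicalSpeciesName(monomer, compartment), compartment,
             "monomer", monomer)
}

complexSpecies <- function(constituents, compartment) {
  speciesRow(canonicalSpeciesName(constituents, compartment), compartment,
             "complex", sort(constituents, method = "radix"))
}

#' Pairwise protein-binding rules for CHRONO
#'
#' The default rule set encodes the co-immunoprecipitation pattern of
#' CHRONO: it binds BMAL1, PER2, CRY2 and DEC2 but not PER1, CRY1 or DEC1,
#' and CHRONO-CRY2 binding is not represented in the oscillator model.
#' Rules are stored symmetrically (one row per unordered pair, partners
#' sorted).
#'
#' @param pairs \code{data.frame} with columns \code{partnerA},
#'   \code{partnerB}, \code{allowed}.
#' @return normalized \code{data.frame} of rules.
#' @export
makeBindingRules <- function(pairs) {
  stopifnot(all(c("partnerA", "partnerB", "allowed") %in% names(pairs)))
  a <- pmin(pairs$partnerA, pairs$partnerB)
  b <- pmax(pairs$partnerA, pairs$partnerB)
  out <- data.frame(partnerA = a, partnerB = b, allowed = pairs$allowed,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  key <- paste(out$partnerA, out$partnerB)
  if (anyDuplicated(key))
    stop("conflicting binding rules for pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  out[order(out$partnerA, out$partnerB), , drop = FALSE]
}

#' Default CHRONO binding rules
#'
#' Two rule sets are provided.  \code{"interaction"} encodes the
#' co-immunoprecipitation pattern: CHRONO binds BMAL1, PER2, CRY2 and DEC2,
#' and does not bind PER1, CRY1 or DEC1.  \code{"model"} is the subset
#' carried into the oscillator network: CHRONO-CRY2 binding is not
#' represented (repression by CHRONO does not require CRY2), and DEC2 is
#' not a model species, so both are marked disallowed there.
#'
#' @param context \code{"model"} (default) or \code{"interaction"}.
#' @return binding-rule \code{data.frame} (see \code{\link{makeBindingRules}}).
#' @export
defaultChronoBindingRules <- function(context = c("model", "interaction")) {
  context <- match.arg(context)
  partners <- switch(context,
    interaction = c("BMAL1", "PER2", "CRY2", "DEC2"),
    model       = c("BMAL1", "PER2"))
  all_p <- c("BMAL1", "PER1", "PER2", "CRY1", "CRY2", "DEC1", "DEC2")
  makeBindingRules(data.frame(
    partnerA = "CHRONO",
    partnerB = all_p,
    allowed  = all_p %in% partners
  ))
}

pairAllowed <- function(rules, a, b) {
  pa <- pmin(a, b); pb <- pmax(a, b)
  hit <- rules$partnerA == pa & rules$partnerB == pb
  if (!any(hit)) return(NA)       # pair not covered by the rule set
  rules$allowed[which(hit)[1]]
}

#' Enumerate CHRONO-containing complexes permitted by binding rules
#'
#' Generates every complex (as a set of distinct monomers, sizes 2 to
#' \code{maxSize}) that contains CHRONO and whose pairwise contacts are all
#' allowed by the rule set.  A pair absent from the rule set is treated as
#' not allowed, so forbidden partners can never be smuggled in through an
#' unspecified contact.  Output ordering is deterministic: by complex size,
#' then canonical name.
#'
#' @param baseMonomers character vector of candidate monomer names
#'   (CHRONO itself need not be listed).
#' @param rules binding rules from \code{\link{makeBindingRules}}; must
#'   cover every pair involving CHRONO among \code{baseMonomers}.
#' @param maxSize maximum complex size (>= 2).
#' @param compartment compartment assigned to the generated complexes.
#' @return \code{data.frame} of complex species rows (possibly 0 rows).
#' @export
enumerateChronoComplexes <- function(baseMonomers, rules, maxSize = 2,
                                     compartment = "nucleus") {
  stopifnot(maxSize >= 2)
  baseMonomers <- setdiff(unique(baseMonomers), "CHRONO")
  known <- unique(c(rules$partnerA, rules$partnerB))
  bad <- setdiff(baseMonomers, known)
  # rules must mention every base monomer at least once (CHRONO pair coverage)
  for (m in baseMonomers)
    if (is.na(pairAllowed(rules, "CHRONO", m)))
      stop("binding rules do not cover the pair (CHRONO, ", m, ")")
  if (length(bad))
    stop("unknown monomer name(s) in rules/base set: ",
         paste(bad, collapse = ", "))
  if (length(baseMonomers) == 0)
    return(speciesRow(character(0), character(0), character(0))[0, ])

  out <- list()
  for (k in seq_len(min(maxSize - 1, length(baseMonomers)))) {
    subsets <- combn(baseMonomers, k, simplify = FALSE)
    for (s in subsets) {
      members <- c("CHRONO", s)
      ok <- TRUE
      for (i in seq_len(length(members) - 1)) {
        for (j in seq(i + 1, length(members))) {
          al <- pairAllowed(rules, members[i], members[j])
          if (is.na(al) || !al) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) out[[length(out) + 1]] <- members
    }
  }
  if (!length(out))
    return(speciesRow(character(0), character(0), character(0))[0, ])
  sizes <- vapply(out, length, integer(1))
  nms <- vapply(out, canonicalSpeciesName, character(1),
                compartment = compartment)
  ord <- order(sizes, nms, method = "radix")
  do.call(rbind, lapply(ord, function(i)
    complexSpecies(out[[i]], compartment)))
}
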