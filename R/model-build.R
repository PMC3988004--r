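#' @include species.R params.R
NULL

reaction <- function(reactants, products, rate) {
  list(reactants = reactants, products = products, rate = rate)
}

eboxRule <- function(gene, vmax, basal, channels) {
  list(gene = gene, mrna = paste0(gene, "_mRNA"), type = "ebox",
       activator = "A_nuc", vmax = vmax, K = "K_tx", basal = basal,
       channels = channels, mode = "sequestration")
}

#' Build the reduced clock model
#'
#' Constructs the reduced-mode network: E-box genes \{Per1, Per2, Cry1,
#' Cry2, Rev, Chrono\} transcribed as \code{basal + v * A/(K_tx + A)} with
#' \code{A} the free (unsequestered) BMAL1-CLOCK activator pool; Bmal1
#' mRNA repressed by nuclear REV-ERB; lumped cytoplasmic PER protein
#' binding CRY1, CRY2 or CHRONO; the three complexes imported into the
#' nucleus at a shared rate (CHRONO enters via the PER2-bound route) where
#' they stoichiometrically sequester the activator (no Hill repression
#' term).  CRY1-containing complexes are the strong/slow repressor channel;
#' CRY2 and CHRONO channels are weak/fast.  Chrono mRNA degradation is
#' tied to Per2's (\code{dm_per2} is the shared symbol).
#'
#' @param config optional list: \code{chrono_enabled} (default
#'   \code{TRUE}), \code{parameter_file} (path to a flat YAML parameter
#'   table), \code{parameters} (named list of overrides),
#'   \code{parameter_set} (label).
#' @return a validated \code{\link{ModelSpec}} in reduced mode.
#' @export
buildReducedModel <- function(config = list()) {
  chrono <- config$chrono_enabled %||% TRUE
  params <- if (!is.null(config$parameter_file))
    readParameterFile(config$parameter_file)
  else defaultReducedParameters()
  if (!is.null(config$parameters)) {
    ov <- config$parameters
    for (nm in names(ov)) {
      if (nm %in% params$name) params$value[params$name == nm] <- ov[[nm]]
      else params <- rbind(params, data.frame(name = nm, value = ov[[nm]],
                                              unit = paramUnit(nm)))
    }
  }
  missing <- setdiff(reducedRequiredParams(), params$name)
  if (length(missing))
    stop("parameter set missing required keys: ",
         paste(missing, collapse = ", "))

  chan_all <- c("CRY1:PER_nuc", "CRY2:PER_nuc",
                if (chrono) "CHRONO:PER_nuc")
  genes <- c("Per1", "Per2", "Cry1", "Cry2", "Rev", if (chrono) "Chrono")

  species <- rbind(
    do.call(rbind, lapply(c(genes, "Bmal1"), mrnaSpecies)),
    monomerSpecies("PER", "cytoplasm"),
    monomerSpecies("CRY1", "cytoplasm"),
    monomerSpecies("CRY2", "cytoplasm"),
    if (chrono) monomerSpecies("CHRONO", "cytoplasm"),
    monomerSpecies("REV", "nucleus"),
    monomerSpecies("A", "nucleus"),
    complexSpecies(c("PER", "CRY1"), "cytoplasm"),
    complexSpecies(c("PER", "CRY2"), "cytoplasm"),
    if (chrono) complexSpecies(c("PER", "CHRONO"), "cytoplasm"),
    complexSpecies(c("PER", "CRY1"), "nucleus"),
    complexSpecies(c("PER", "CRY2"), "nucleus"),
    if (chrono) complexSpecies(c("PER", "CHRONO"), "nucleus"),
    complexSpecies(c("A", "PER", "CRY1"), "nucleus"),
    complexSpecies(c("A", "PER", "CRY2"), "nucleus"),
    if (chrono) complexSpecies(c("A", "PER", "CHRONO"), "nucleus")
  )
  rownames(species) <- NULL

  rx <- list(
    # translation (mRNA catalytic: M -> M + protein)
    reaction(c(Per1_mRNA = 1), c(Per1_mRNA = 1, PER_cyt = 1), "ktl_per"),
    reaction(c(Per2_mRNA = 1), c(Per2_mRNA = 1, PER_cyt = 1), "ktl_per"),
    reaction(c(Cry1_mRNA = 1), c(Cry1_mRNA = 1, CRY1_cyt = 1), "ktl_cry1"),
    reaction(c(Cry2_mRNA = 1), c(Cry2_mRNA = 1, CRY2_cyt = 1), "ktl_cry2"),
    reaction(c(Rev_mRNA = 1), c(Rev_mRNA = 1, REV_nuc = 1), "ktl_rev"),
    reaction(c(Bmal1_mRNA = 1), c(Bmal1_mRNA = 1, A_nuc = 1), "ktl_bmal"),
    # mRNA degradation
    reaction(c(Per1_mRNA = 1), c(), "dm_per1"),
    reaction(c(Per2_mRNA = 1), c(), "dm_per2"),
    reaction(c(Cry1_mRNA = 1), c(), "dm_cry1"),
    reaction(c(Cry2_mRNA = 1), c(), "dm_cry2"),
    reaction(c(Rev_mRNA = 1), c(), "dm_rev"),
    reaction(c(Bmal1_mRNA = 1), c(), "dm_bmal"),
    # free-protein degradation
    reaction(c(PER_cyt = 1), c(), "dp_per"),
    reaction(c(CRY1_cyt = 1), c(), "dp_cry1"),
    reaction(c(CRY2_cyt = 1), c(), "dp_cry2"),
    reaction(c(REV_nuc = 1), c(), "dp_rev"),
    reaction(c(A_nuc = 1), c(), "dp_a"),
    # cytoplasmic PER-partner binding
    reaction(c(PER_cyt = 1, CRY1_cyt = 1), c(`CRY1:PER_cyt` = 1), "kon_pc"),
    reaction(c(`CRY1:PER_cyt` = 1), c(PER_cyt = 1, CRY1_cyt = 1), "koff_pc1"),
    reaction(c(PER_cyt = 1, CRY2_cyt = 1), c(`CRY2:PER_cyt` = 1), "kon_pc"),
    reaction(c(`CRY2:PER_cyt` = 1), c(PER_cyt = 1, CRY2_cyt = 1), "koff_pc2"),
    # nuclear import (shared rate)
    reaction(c(`CRY1:PER_cyt` = 1), c(`CRY1:PER_nuc` = 1), "kimp"),
    reaction(c(`CRY2:PER_cyt` = 1), c(`CRY2:PER_nuc` = 1), "kimp"),
    # nuclear repressor-pool degradation
    reaction(c(`CRY1:PER_nuc` = 1), c(), "dn_pc1"),
    reaction(c(`CRY2:PER_nuc` = 1), c(), "dn_pc2"),
    # activator sequestration
    reaction(c(A_nuc = 1, `CRY1:PER_nuc` = 1), c(`A:CRY1:PER_nuc` = 1), "kona"),
    reaction(c(`A:CRY1:PER_nuc` = 1), c(A_nuc = 1, `CRY1:PER_nuc` = 1), "koffa1"),
    reaction(c(A_nuc = 1, `CRY2:PER_nuc` = 1), c(`A:CRY2:PER_nuc` = 1), "kona"),
    reaction(c(`A:CRY2:PER_nuc` = 1), c(A_nuc = 1, `CRY2:PER_nuc` = 1), "koffa2"),
    # repressor degradation inside activator complexes (releases A)
    reaction(c(`A:CRY1:PER_nuc` = 1), c(A_nuc = 1), "da_pc1"),
    reaction(c(`A:CRY2:PER_nuc` = 1), c(A_nuc = 1), "da_pc2")
  )
  if (chrono) {
    rx <- c(rx, list(
      reaction(c(Chrono_mRNA = 1), c(Chrono_mRNA = 1, CHRONO_cyt = 1), "ktl_chrono"),
      reaction(c(Chrono_mRNA = 1), c(), "dm_per2"),  # decay tied to Per2's
      reaction(c(CHRONO_cyt = 1), c(), "dp_chrono"),
      reaction(c(PER_cyt = 1, CHRONO_cyt = 1), c(`CHRONO:PER_cyt` = 1), "kon_pc"),
      reaction(c(`CHRONO:PER_cyt` = 1), c(PER_cyt = 1, CHRONO_cyt = 1), "koff_chr"),
      reaction(c(`CHRONO:PER_cyt` = 1), c(`CHRONO:PER_nuc` = 1), "kimp"),
      reaction(c(`CHRONO:PER_nuc` = 1), c(), "dn_chr"),
      reaction(c(A_nuc = 1, `CHRONO:PER_nuc` = 1), c(`A:CHRONO:PER_nuc` = 1), "kona"),
      reaction(c(`A:CHRONO:PER_nuc` = 1), c(A_nuc = 1, `CHRONO:PER_nuc` = 1), "koffa_chr"),
      reaction(c(`A:CHRONO:PER_nuc` = 1), c(A_nuc = 1), "da_chr")
    ))
  }

  tr <- c(
    lapply(genes[genes != "Rev"], function(g)
      eboxRule(g, paste0("v_", tolower(g)), paste0("basal_", tolower(g)),
               chan_all)),
    list(eboxRule("Rev", "v_rev", "basal_rev", chan_all)),
    list(list(gene = "Bmal1", mrna = "Bmal1_mRNA", type = "hill_repression",
              repressor = "REV_nuc", vmax = "v_bmal", K = "K_rev",
              basal = "basal_bmal", channels = character(),
              mode = "hill"))
  )

  # the committed parameter set ships with its wild-type limit-cycle
  # snapshot (state at a Per2 mRNA peak), used as the default initial
  # condition so that simulations start on (or very near) the cycle
  state_file <- config$initial_state_file %||%
    if (is.null(config$parameter_file))
      system.file("extdata", "params", "default_reduced_v1_state.yaml",
                  package = "chronoclock")
  init <- NULL
  if (!is.null(state_file) && nzchar(state_file) && file.exists(state_file)) {
    st <- yaml::read_yaml(state_file)
    init <- setNames(unlist(st), names(st))
  }

  new("ModelSpec",
      species = species, reactions = rx, transcription = tr,
      bindingRules = defaultChronoBindingRules("model"),
      parameters = params, mode = "reduced",
      metadata = list(parameter_set = config$parameter_set %||%
                        "default_reduced_v1",
                      chrono_enabled = chrono,
                      schema_version = MODEL_SCHEMA_VERSION,
                      initial_state = init,
                      perturbations = list()))
}

#' Build the detailed model from a user-supplied base definition
#'
#' Detailed mode augments an externally supplied base clock model (a
#' serialized \code{ModelSpec} JSON document: species, reactions,
#' transcription rules, parameters) with Chrono mRNA dynamics and with
#' every CHRONO-containing complex permitted by the binding rules, and
#' records the number of newly added state variables in the model
#' metadata.  The base definition is not bundled with the package and must
#' be provided by the user.
#'
#' @param baseDefinitionFile path to the base-model JSON document.
#' @param config optional list: \code{binding_rules} (defaults to the
#'   model rule set), \code{max_complex_size} (default 4),
#'   \code{chrono_parameters} (named list of parameters for the added
#'   CHRONO reactions).
#' @return a \code{\link{ModelSpec}} in detailed mode with
#'   \code{metadata$newly_added_variable_count} set.
#' @export
buildDetailedModel <- function(baseDefinitionFile, config = list()) {
  if (missing(baseDefinitionFile) || is.null(baseDefinitionFile) ||
      !nzchar(baseDefinitionFile) || !file.exists(baseDefinitionFile))
    stop("detailed mode requires external base model: supply the path to ",
         "a serialized base-model definition (JSON)")
  base <- readModelJson(baseDefinitionFile)
  if (nrow(base@species) == 0)
    stop("base model invalid: zero species")
  if (any(grepl("CHRONO", base@species$name)) ||
      "Chrono_mRNA" %in% base@species$name)
    stop("CHRONO species already present in base model; ",
         "extension is not idempotent and may be applied only once")

  rules <- config$binding_rules %||% defaultChronoBindingRules("model")
  maxSize <- config$max_complex_size %||% 4

  base_monomers <- unique(unlist(
    base@species$constituents[base@species$kind != "mRNA"]))
  candidates <- intersect(base_monomers,
                          unique(c(rules$partnerA, rules$partnerB)))

  added <- rbind(
    mrnaSpecies("Chrono"),
    monomerSpecies("CHRONO", "cytoplasm"),
    if (length(candidates))
      enumerateChronoComplexes(candidates, rules, maxSize = maxSize,
                               compartment = "nucleus")
  )
  rownames(added) <- NULL

  params <- base@parameters
  cp <- config$chrono_parameters %||% list()
  for (nm in names(cp))
    params <- rbind(params, data.frame(name = nm, value = cp[[nm]],
                                       unit = paramUnit(nm)))

  out <- new("ModelSpec",
             species = rbind(base@species, added),
             reactions = base@reactions,
             transcription = base@transcription,
             bindingRules = rules,
             parameters = params,
             mode = "detailed",
             metadata = modifyList(base@metadata, list(
               newly_added_variable_count = nrow(added),
               schema_version = MODEL_SCHEMA_VERSION,
               perturbations = base@metadata$perturbations %||% list())))
  validObject(out)
  out
}

#' Audit monomer conservation of binding/unbinding reactions
#'
#' For every pure binding/unbinding reaction (no net synthesis or
#' degradation: both sides non-empty and all species are proteins or
#' complexes), checks that the total multiset of monomer constituents is
#' identical on both sides.
#'
#' @param model a \code{ModelSpec}.
#' @return logical; \code{TRUE} if all audited reactions balance.
#'   Attribute \code{"failures"} lists indices of unbalanced reactions.
#' @export
conservationAudit <- function(model) {
  sp <- model@species
  cons <- setNames(sp$constituents, sp$name)
  kind <- setNames(sp$kind, sp$name)
  fails <- integer()
  for (i in seq_along(model@reactions)) {
    r <- model@reactions[[i]]
    all_sp <- c(names(r$reactants), names(r$products))
    if (!length(r$reactants) || !length(r$products)) next
    if (any(kind[all_sp] == "mRNA")) next
    expand <- function(side) sort(unname(unlist(mapply(
      function(nm, st) rep(cons[[nm]], st), names(side), side,
      SIMPLIFY = FALSE))))
    lhs <- expand(r$reactants); rhs <- expand(r$products)
    # degradation-with-release reactions (e.g. complex -> activator) are
    # net-removal steps, not pure binding events: skip if one side is a
    # strict sub-multiset of the other
    if (length(lhs) != length(rhs)) next
    if (!identical(lhs, rhs)) fails <- c(fails, i)
  }
  structure(length(fails) == 0L, failures = fails)
}
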