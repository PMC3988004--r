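#' @include chronoclock-package.R
NULL

MODEL_SCHEMA_VERSION <- "1.0"

#' ModelSpec: a clock reaction network
#'
#' An S4 container for the circadian clock reaction network: species,
#' elementary mass-action reactions, transcription rules, binding rules and
#' the parameter table.  Concentrations are in arbitrary units (a.u.),
#' time in hours.
#'
#' @slot species \code{data.frame} with columns \code{name},
#'   \code{compartment} (\code{"cytoplasm"} or \code{"nucleus"}),
#'   \code{kind} (\code{"mRNA"}, \code{"monomer"} or \code{"complex"}) and a
#'   list-column \code{constituents} (monomer names; empty for mRNA).
#' @slot reactions list of mass-action reactions; each a list with named
#'   numeric vectors \code{reactants} and \code{products} (stoichiometries,
#'   integers >= 1) and \code{rate} (a parameter name).  An empty reactant
#'   set denotes a constant source.
#' @slot transcription list of transcription rules; each a list with
#'   \code{gene}, \code{mrna} (species), \code{type} (\code{"ebox"} for
#'   Michaelis activation by the free activator, \code{"hill_repression"}
#'   for repression of Bmal1 by REV-ERB), the driving species
#'   (\code{activator} or \code{repressor}), and parameter names
#'   \code{vmax}, \code{K}, \code{basal}, plus \code{channels}, the
#'   sequestration repressor pools acting on this gene's activator.
#' @slot bindingRules \code{data.frame} of pairwise protein-binding rules:
#'   \code{partnerA}, \code{partnerB}, \code{allowed} (logical).
#' @slot parameters \code{data.frame} with \code{name}, \code{value},
#'   \code{unit} (one of \code{"1/h"}, \code{"conc/h"},
#'   \code{"1/(conc.h)"}, \code{"conc"}, \code{"dimensionless"}).
#' @slot mode \code{"reduced"} or \code{"detailed"}.
#' @slot metadata free-form list (parameter-set name, perturbation log,
#'   cached limit-cycle state, schema version, ...).
#'
#' @seealso \code{\link{buildReducedModel}}, \code{\link{applyPerturbation}},
#'   \code{\link{integrateModel}}
#' @export
setClass("ModelSpec",
  representation(
    species       = "data.frame",
    reactions     = "list",
    transcription = "list",
    bindingRules  = "data.frame",
    parameters    = "data.frame",
    mode          = "character",
    metadata      = "list"
  )
)

setValidity("ModelSpec", function(object) {
  msgs <- character()
  sp <- object@species
  need <- c("name", "compartment", "kind", "constituents")
  if (!all(need %in% names(sp)))
    return(paste("species table must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(sp$name))
    msgs <- c(msgs, "species names must be unique")
  if (!all(sp$compartment %in% c("cytoplasm", "nucleus")))
    msgs <- c(msgs, "compartment must be cytoplasm or nucleus")
  if (!all(sp$kind %in% c("mRNA", "monomer", "complex")))
    msgs <- c(msgs, "kind must be mRNA, monomer or complex")
  ncon <- vapply(sp$constituents, length, integer(1))
  if (any(sp$kind == "complex" & ncon < 2))
    msgs <- c(msgs, "complex species must have >= 2 constituents")
  if (any(sp$kind == "mRNA" & ncon != 0))
    msgs <- c(msgs, "mRNA species must have no constituents")

  pnames <- object@parameters$name
  if (anyDuplicated(pnames))
    msgs <- c(msgs, "parameter names must be unique")
  for (i in seq_along(object@reactions)) {
    r <- object@reactions[[i]]
    refs <- c(names(r$reactants), names(r$products))
    bad <- setdiff(refs, sp$name)
    if (length(bad))
      msgs <- c(msgs, sprintf("reaction %d references undeclared species: %s",
                              i, paste(bad, collapse = ", ")))
    st <- c(r$reactants, r$products)
    if (length(st) && (any(st < 1) || any(st != round(st))))
      msgs <- c(msgs, sprintf("reaction %d has non-integer or < 1 stoichiometry", i))
    if (!r$rate %in% pnames)
      msgs <- c(msgs, sprintf("reaction %d rate parameter '%s' not in parameter table",
                              i, r$rate))
  }
  for (tr in object@transcription) {
    refs <- c(tr$vmax, tr$K, tr$basal)
    bad <- setdiff(refs, pnames)
    if (length(bad))
      msgs <- c(msgs, sprintf("transcription rule for %s references missing parameters: %s",
                              tr$gene, paste(bad, collapse = ", ")))
    if (!tr$mrna %in% sp$name)
      msgs <- c(msgs, sprintf("transcription rule for %s: mRNA species '%s' undeclared",
                              tr$gene, tr$mrna))
  }
  if (!object@mode %in% c("reduced", "detailed"))
    msgs <- c(msgs, "mode must be 'reduced' or 'detailed'")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Trajectory: a simulated time course
#'
#' Dense time grid (hours) by species-concentration matrix (a.u.) from ODE
#' integration, with provenance metadata.
#'
#' @slot times strictly increasing numeric vector, hours.
#' @slot states numeric matrix, one row per time point, columns named by
#'   species.
#' @slot metadata list: model hash/parameter-set name, perturbations,
#'   solver tolerances.
#' @export
setClass("Trajectory",
  representation(times = "numeric", states = "matrix", metadata = "list")
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  if (length(object@times) != nrow(object@states))
    msgs <- c(msgs, "times length must equal states row count")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  atol <- object@metadata$atol %||% 1e-10
  if (length(object@states) && min(object@states) < -10 * atol)
    msgs <- c(msgs, "negative concentrations beyond -10*atol")
  if (is.null(colnames(object@states)))
    msgs <- c(msgs, "states must have species column names")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn ModelSpec-accessors species table
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))
#' @describeIn ModelSpec-accessors species names
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))
#' @describeIn ModelSpec-accessors named parameter vector
#' @export
setGeneric("parameterValues", function(x) standardGeneric("parameterValues"))
#' @describeIn ModelSpec-accessors genes with a transcription rule
#' @export
setGeneric("modelGenes", function(x) standardGeneric("modelGenes"))

#' Accessors for ModelSpec and Trajectory
#'
#' @param x a \code{ModelSpec} or \code{Trajectory}.
#' @name ModelSpec-accessors
NULL

#' @rdname ModelSpec-accessors
#' @export
setMethod("speciesTable", "ModelSpec", function(x) x@species)
#' @rdname ModelSpec-accessors
#' @export
setMethod("speciesNames", "ModelSpec", function(x) x@species$name)
#' @rdname ModelSpec-accessors
#' @export
setMethod("speciesNames", "Trajectory", function(x) colnames(x@states))
#' @rdname ModelSpec-accessors
#' @export
setMethod("parameterValues", "ModelSpec", function(x)
  setNames(x@parameters$value, x@parameters$name))
#' @rdname ModelSpec-accessors
#' @export
setMethod("modelGenes", "ModelSpec", function(x)
  vapply(x@transcription, `[[`, character(1), "gene"))

#' @rdname ModelSpec-accessors
#' @export
trajTimes <- function(x) x@times

#' @rdname ModelSpec-accessors
#' @export
trajStates <- function(x) x@states

#' Extract one species' time course from a Trajectory
#'
#' @param x a \code{Trajectory}.
#' @param species species name (column of the state matrix).
#' @return numeric vector of concentrations (a.u.).
#' @export
trajSeries <- function(x, species) {
  if (!species %in% colnames(x@states))
    stop("species '", species, "' not in trajectory; available: ",
         paste(colnames(x@states), collapse = ", "))
  x@states[, species]
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec (%s mode): %d species, %d reactions, %d transcription rules\n",
              object@mode, nrow(object@species), length(object@reactions),
              length(object@transcription)))
  cat(sprintf("  genes: %s\n", paste(modelGenes(object), collapse = ", ")))
  kinds <- table(object@species$kind)
  cat(sprintf("  species kinds: %s\n",
              paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", ")))
  if (!is.null(object@metadata$parameter_set))
    cat(sprintf("  parameter set: %s\n", object@metadata$parameter_set))
  pert <- object@metadata$perturbations
  if (length(pert))
    cat(sprintf("  perturbations: %s\n",
                paste(vapply(pert, formatPerturbation, character(1)),
                      collapse = ", ")))
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over [%.2f, %.2f] h, %d species\n",
              length(object@times), min(object@times), max(object@times),
              ncol(object@states)))
  invisible(object)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
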