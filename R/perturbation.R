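#' @include model-build.R
NULL

# target protein species for constitutive overexpression, reduced model
oeTargetSpecies <- function(model, gene) {
  map <- c(Per1 = "PER_cyt", Per2 = "PER_cyt", Cry1 = "CRY1_cyt",
           Cry2 = "CRY2_cyt", Chrono = "CHRONO_cyt", Rev = "REV_nuc",
           Bmal1 = "A_nuc")
  tgt <- unname(map[gene])
  if (is.na(tgt) || !tgt %in% model@species$name)
    stop("no overexpression target protein known for gene ", gene)
  tgt
}

#' Construct a genetic perturbation
#'
#' A directive applied to one gene: \code{knockout} (transcription zeroed
#' and the transcript removed from the start of simulated day 0),
#' \code{knockdown} (transcription scaled by \code{fraction}), or
#' \code{overexpress} (a constitutive, E-box-independent production term
#' for the gene's protein).
#'
#' @param gene gene name (e.g. \code{"Cry2"}).
#' @param action \code{"knockout"}, \code{"knockdown"} or
#'   \code{"overexpress"}.
#' @param fraction remaining transcription fraction in (0, 1]
#'   (knockdown only; e.g. 0.3 for knockdown to 30\% of the original).
#' @param extraProduction constitutive production rate, conc/h
#'   (overexpress only; > 0).  \code{NULL} uses the parameter-set default
#'   \code{oe_<gene>}.
#' @param onsetTime perturbation onset, hours (default 0 = start of
#'   simulated day 0).
#' @return an object of class \code{"GeneticPerturbation"}.
#' @export
perturbation <- function(gene,
                         action = c("knockout", "knockdown", "overexpress"),
                         fraction = NULL, extraProduction = NULL,
                         onsetTime = 0) {
  action <- match.arg(action)
  if (action == "knockdown") {
    if (is.null(fraction) || fraction <= 0 || fraction > 1)
      stop("knockdown requires a fraction in (0, 1]")
  } else fraction <- NULL
  if (action == "overexpress") {
    if (!is.null(extraProduction) && extraProduction <= 0)
      stop("overexpress requires extraProduction > 0")
  } else extraProduction <- NULL
  structure(list(gene = gene, action = action, fraction = fraction,
                 extra_production = extraProduction,
                 onset_time = onsetTime),
            class = "GeneticPerturbation")
}

formatPerturbation <- function(p) {
  switch(p$action,
    knockout   = paste0(p$gene, ":ko"),
    knockdown  = sprintf("%s:kd:%g", p$gene, p$fraction),
    overexpress = if (is.null(p$extra_production)) paste0(p$gene, ":oe")
                  else sprintf("%s:oe:%g", p$gene, p$extra_production))
}

#' @export
print.GeneticPerturbation <- function(x, ...) {
  cat("GeneticPerturbation:", formatPerturbation(x), "\n")
  invisible(x)
}

#' Parse a perturbation mini-grammar string
#'
#' Grammar: \code{"gene:ko"}, \code{"gene:kd:0.3"},
#' \code{"gene:oe"} or \code{"gene:oe:rate"}; multiple specs separated by
#' commas, applied left to right.
#'
#' @param spec a specification string, e.g.
#'   \code{"Cry2:kd:0.3,Chrono:oe"}. An empty string gives an empty list.
#' @return list of \code{GeneticPerturbation}.
#' @export
parsePerturbations <- function(spec) {
  if (is.null(spec) || !nzchar(trimws(spec))) return(list())
  parts <- trimws(strsplit(spec, ",", fixed = TRUE)[[1]])
  lapply(parts, function(s) {
    f <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed perturbation spec: '", s, "'")
    gene <- f[1]
    switch(f[2],
      ko = perturbation(gene, "knockout"),
      kd = {
        if (length(f) < 3) stop("knockdown spec needs a fraction: '", s, "'")
        perturbation(gene, "knockdown", fraction = as.numeric(f[3]))
      },
      oe = perturbation(gene, "overexpress",
                        extraProduction = if (length(f) >= 3)
                          as.numeric(f[3])),
      stop("unknown perturbation action '", f[2], "' in '", s,
           "' (use ko, kd or oe)"))
  })
}

#' Apply genetic perturbations to a model
#'
#' Pure transformation: the input model is unmodified.  Knockout sets the
#' gene's maximal and basal transcription rates to 0 (the transcript
#' initial condition is forced to 0 at onset by the simulation layer, per
#' the day-0 knockout convention); knockdown multiplies both rates by
#' \code{fraction}; overexpression adds one constitutive production
#' reaction for the gene's protein, independent of E-box state.
#' Perturbations compose left to right.
#'
#' @param model a \code{ModelSpec}.
#' @param perturbations a single \code{GeneticPerturbation}, a list of
#'   them, or a spec string for \code{\link{parsePerturbations}}.
#' @return a new \code{ModelSpec}.
#' @export
applyPerturbation <- function(model, perturbations) {
  if (is.character(perturbations))
    perturbations <- parsePerturbations(perturbations)
  if (inherits(perturbations, "GeneticPerturbation"))
    perturbations <- list(perturbations)
  for (p in perturbations) model <- applyOnePerturbation(model, p)
  model
}

applyOnePerturbation <- function(model, p) {
  genes <- modelGenes(model)
  if (!p$gene %in% genes)
    stop("unknown gene '", p$gene, "'; available genes: ",
         paste(genes, collapse = ", "))
  rule <- model@transcription[[which(genes == p$gene)[1]]]
  setPar <- function(m, nm, value) {
    m@parameters$value[m@parameters$name == nm] <- value
    m
  }
  getPar <- function(m, nm) m@parameters$value[m@parameters$name == nm]

  if (p$action == "knockout") {
    model <- setPar(model, rule$vmax, 0)
    model <- setPar(model, rule$basal, 0)
  } else if (p$action == "knockdown") {
    model <- setPar(model, rule$vmax, getPar(model, rule$vmax) * p$fraction)
    model <- setPar(model, rule$basal, getPar(model, rule$basal) * p$fraction)
  } else { # overexpress
    tgt <- oeTargetSpecies(model, p$gene)
    pname <- paste0("oe_", tolower(p$gene))
    rate <- p$extra_production
    if (is.null(rate)) {
      if (!pname %in% model@parameters$name)
        stop("no default overexpression rate '", pname,
             "' in parameter set; supply extraProduction")
      rate <- getPar(model, pname)
    }
    # a fresh parameter symbol per applied OE keeps composition explicit
    k <- length(model@metadata$perturbations) + 1L
    sym <- sprintf("oe_applied_%s_%d", tolower(p$gene), k)
    model@parameters <- rbind(model@parameters,
                              data.frame(name = sym, value = rate,
                                         unit = "conc/h"))
    model@reactions <- c(model@reactions,
                         list(reaction(c(), setNames(1, tgt), sym)))
  }
  model@metadata$perturbations <- c(model@metadata$perturbations, list(p))
  model
}
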