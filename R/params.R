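#' @include AllClasses.R
NULL

# unit classification by parameter-name prefix; K_* are concentrations and
# are invariant under time rescaling, everything else is a rate
paramUnit <- function(name) {
  ifelse(grepl("^K_", name), "conc",
    ifelse(grepl("^(v_|basal_|oe_)", name), "conc/h",
      ifelse(grepl("^kon", name), "1/(conc.h)", "1/h")))
}

#' Read a flat name-value parameter file (YAML)
#'
#' Parameter files are flat name -> value tables; units are documented in
#' comments and inferred here from the name prefix.
#'
#' @param path file path.
#' @return \code{data.frame} with \code{name}, \code{value}, \code{unit}.
#' @export
readParameterFile <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (!length(vals) || !all(vapply(vals, is.numeric, logical(1))))
    stop("parameter file must be a flat name: numeric-value mapping: ", path)
  data.frame(name = names(vals),
             value = unname(unlist(vals)),
             unit = paramUnit(names(vals)),
             stringsAsFactors = FALSE)
}

#' The committed default parameter set for the reduced model
#'
#' Returns the versioned \code{default_reduced_v1} set shipped with the
#' package (see the parameter file itself for provenance comments).
#'
#' @return parameter \code{data.frame} (\code{name}, \code{value},
#'   \code{unit}).
#' @export
defaultReducedParameters <- function() {
  path <- system.file("extdata", "params", "default_reduced_v1.yaml",
                      package = "chronoclock", mustWork = TRUE)
  readParameterFile(path)
}

# required parameter names for the reduced model builder
reducedRequiredParams <- function() {
  genes <- c("per1", "per2", "cry1", "cry2", "chrono", "rev", "bmal")
  c(paste0("v_", genes), paste0("basal_", genes),
    "K_tx", "K_rev",
    paste0("dm_", c("per1", "per2", "cry1", "cry2", "rev", "bmal")),
    paste0("ktl_", c("per", "cry1", "cry2", "chrono", "rev", "bmal")),
    paste0("dp_", c("per", "cry1", "cry2", "chrono", "rev", "a")),
    "kon_pc", "koff_pc1", "koff_pc2", "koff_chr", "kimp",
    "dn_pc1", "dn_pc2", "dn_chr",
    "kona", "koffa1", "koffa2", "koffa_chr",
    "da_pc1", "da_pc2", "da_chr")
}
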