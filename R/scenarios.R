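#' @include io.R
NULL

#' The standard genotype battery
#'
#' Named perturbation-spec strings for the in-silico experiment battery:
#' wild type; Chrono KO; Cry1 KO; Chrono+Cry1 double KO; Cry2 knockdown
#' to 30\% alone and rescued by constitutive Cry2 or Chrono
#' overexpression; Cry1+Cry2 double KO; and the Cry1+Cry2+Chrono triple
#' KO.
#'
#' @return named character vector (names are genotype labels).
#' @export
standardGenotypeBattery <- function() {
  c(WT = "",
    Chrono_KO = "Chrono:ko",
    Cry1_KO = "Cry1:ko",
    Chrono_Cry1_dKO = "Chrono:ko,Cry1:ko",
    Cry2_kd30 = "Cry2:kd:0.3",
    Cry2_kd30_Cry2_OE = "Cry2:kd:0.3,Cry2:oe",
    Cry2_kd30_Chrono_OE = "Cry2:kd:0.3,Chrono:oe",
    Cry1_Cry2_dKO = "Cry1:ko,Cry2:ko",
    Cry1_Cry2_Chrono_tKO = "Cry1:ko,Cry2:ko,Chrono:ko")
}

#' Run the in-silico genotype battery
#'
#' Simulates each genotype from the wild-type limit cycle, classifies
#' the Per2 mRNA rhythm, and checks the machine-readable phenotype
#' ladder: period(Cry1 KO) < period(WT) < period(Chrono KO); the
#' Chrono+Cry1 double KO stays sustained with a period within 0.3 h of
#' the Cry1 single KO; Cry2 knockdown to 30\% lengthens the period and
#' constitutive Cry2 or Chrono overexpression shortens it back toward
#' control; the Cry1+Cry2 double KO is damped while the triple KO is
#' arrhythmic; and Chrono KO preserves at least 80\% of the wild-type
#' Per2 mRNA relative amplitude.
#'
#' @param model a \code{ModelSpec} (default: the reduced model with the
#'   committed parameter set).
#' @param genotypes named character vector of perturbation specs
#'   (default \code{\link{standardGenotypeBattery}}).
#' @param reporter reporter species.
#' @param days simulated days per genotype.
#' @return a \code{ScenarioReport}: \code{data.frame} with one row per
#'   genotype (\code{genotype}, \code{perturbations},
#'   \code{classification}, \code{period_h}, \code{relative_amplitude},
#'   \code{damping_rate}, \code{ok}); attributes \code{"ladder"} (named
#'   logical vector of property checks, NA where not applicable) and
#'   \code{"metadata"}.
#' @export
runScenarioBattery <- function(model = buildReducedModel(),
                               genotypes = standardGenotypeBattery(),
                               reporter = "Per2_mRNA", days = 40) {
  wt_state <- limitCycleState(model, reporter)
  rows <- list()
  for (i in seq_along(genotypes)) {
    label <- names(genotypes)[i]
    spec <- genotypes[[i]]
    res <- tryCatch(
      runGenotype(model, spec, reporter = reporter, days = days,
                  wtState = wt_state),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[label]] <- data.frame(
        genotype = label, perturbations = spec,
        classification = "error", period_h = NA_real_,
        relative_amplitude = NA_real_, damping_rate = NA_real_,
        ok = FALSE, message = conditionMessage(res))
    } else {
      v <- res$verdict
      rows[[label]] <- data.frame(
        genotype = label, perturbations = spec,
        classification = v$classification,
        period_h = round(v$period, 2),
        relative_amplitude = v$relative_amplitude,
        damping_rate = if (v$classification == "damped") v$damping_rate
                       else NA_real_,
        ok = TRUE, message = "")
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "ladder") <- checkPhenotypeLadder(report)
  attr(report, "metadata") <- list(
    parameter_set = model@metadata$parameter_set,
    mode = model@mode, reporter = reporter, days = days,
    tool_version = as.character(utils::packageVersion("chronoclock")),
    schema_version = MODEL_SCHEMA_VERSION)
  class(report) <- c("ScenarioReport", class(report))
  report
}

#' Check the phenotype ladder on a scenario report
#'
#' @param report a \code{ScenarioReport}.
#' @return named logical vector (NA where a needed genotype is absent).
#' @export
checkPhenotypeLadder <- function(report) {
  g <- function(label, col) {
    i <- match(label, report$genotype)
    if (is.na(i)) NA else report[[col]][i]
  }
  p <- function(label) g(label, "period_h")
  cls <- function(label) g(label, "classification")
  maybe <- function(x) if (length(x) == 1 && !is.na(x)) x else NA
  c(
    cry1_short      = maybe(p("Cry1_KO") < p("WT")),
    chrono_long     = maybe(p("WT") < p("Chrono_KO")),
    dko_sustained   = maybe(cls("Chrono_Cry1_dKO") == "sustained"),
    dko_near_cry1   = maybe(abs(p("Chrono_Cry1_dKO") - p("Cry1_KO")) < 0.3),
    kd_lengthens    = maybe(p("Cry2_kd30") > p("WT")),
    cry2_oe_rescue  = maybe(p("Cry2_kd30_Cry2_OE") < p("Cry2_kd30")),
    chrono_oe_rescue = maybe(p("Cry2_kd30_Chrono_OE") < p("Cry2_kd30")),
    crydko_damped   = maybe(cls("Cry1_Cry2_dKO") == "damped"),
    tko_arrhythmic  = maybe(cls("Cry1_Cry2_Chrono_tKO") == "arrhythmic"),
    amplitude_kept  = maybe(g("Chrono_KO", "relative_amplitude") >=
                              0.8 * g("WT", "relative_amplitude"))
  )
}

#' @export
print.ScenarioReport <- function(x, ...) {
  cat("Scenario report (", attr(x, "metadata")$parameter_set, ", ",
      attr(x, "metadata")$mode, " mode)\n", sep = "")
  print.data.frame(x[, c("genotype", "classification", "period_h",
                         "relative_amplitude", "damping_rate")],
                   digits = 4)
  ladder <- attr(x, "ladder")
  ok <- sum(ladder %in% TRUE); tot <- sum(!is.na(ladder))
  cat(sprintf("Phenotype ladder: %d/%d checks pass\n", ok, tot))
  bad <- names(ladder)[ladder %in% FALSE]
  if (length(bad)) cat("  failing:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' Write a scenario report (JSON and markdown)
#'
#' @param report a \code{ScenarioReport}.
#' @param path output path without extension; writes \code{<path>.json}
#'   and \code{<path>.md}.
#' @return invisibly, the two paths.
#' @export
writeScenarioReport <- function(report, path) {
  json_path <- paste0(path, ".json")
  md_path <- paste0(path, ".md")
  jsonlite::write_json(
    list(metadata = attr(report, "metadata"),
         ladder = as.list(attr(report, "ladder")),
         genotypes = as.data.frame(report)),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
    na = "null")
  lines <- c(
    "# Genotype battery report", "",
    sprintf("Parameter set: %s (%s mode); reporter %s; %d days/genotype.",
            attr(report, "metadata")$parameter_set,
            attr(report, "metadata")$mode,
            attr(report, "metadata")$reporter,
            attr(report, "metadata")$days), "",
    "| genotype | perturbations | classification | period (h) | rel. amplitude | damping (1/h) |",
    "|---|---|---|---|---|---|",
    vapply(seq_len(nrow(report)), function(i) sprintf(
      "| %s | %s | %s | %s | %s | %s |",
      report$genotype[i], report$perturbations[i],
      report$classification[i],
      ifelse(is.na(report$period_h[i]), "-",
             sprintf("%.2f", report$period_h[i])),
      ifelse(is.na(report$relative_amplitude[i]), "-",
             sprintf("%.3f", report$relative_amplitude[i])),
      ifelse(is.na(report$damping_rate[i]), "-",
             sprintf("%.4f", report$damping_rate[i]))), character(1)),
    "", "## Phenotype ladder", "")
  ladder <- attr(report, "ladder")
  lines <- c(lines, vapply(names(ladder), function(nm) sprintf(
    "- %s: %s", nm,
    if (is.na(ladder[[nm]])) "skipped"
    else if (ladder[[nm]]) "pass" else "FAIL"), character(1)))
  writeLines(lines, md_path)
  invisible(c(json = json_path, md = md_path))
}
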