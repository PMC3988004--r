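#' @include synthetic.R
NULL

#' Write / read a trajectory as CSV with a JSON metadata sidecar
#'
#' The CSV has header \code{time_h,<species...>}; metadata (parameter
#' set, perturbations, solver tolerances) goes to \code{<path>.meta.json}.
#'
#' @param trajectory a \code{\link{Trajectory}}.
#' @param path CSV file path.
#' @return \code{path}, invisibly (writer); a \code{Trajectory} (reader).
#' @export
writeTrajectoryCsv <- function(trajectory, path) {
  df <- data.frame(time_h = trajectory@times,
                   trajectory@states, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(trajectory@metadata, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeTrajectoryCsv
#' @export
readTrajectoryCsv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_h")
    stop("trajectory CSV must start with a 'time_h' column")
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list()
  new("Trajectory", times = df$time_h,
      states = as.matrix(df[, -1, drop = FALSE]), metadata = meta)
}

#' Write / read an actogram CSV
#'
#' Format: \code{bin_start_min,count,lights(0/1)}.
#'
#' @param actogram an \code{Actogram}.
#' @param path file path.
#' @return \code{path}, invisibly (writer); an \code{Actogram} (reader;
#'   the per-day schedule is reconstructed from the lights column:
#'   a day with any lights-on bin is LD, otherwise DD).
#' @export
writeActogramCsv <- function(actogram, path) {
  df <- data.frame(
    bin_start_min = (seq_along(actogram$counts) - 1) * actogram$bin_width,
    count = actogram$counts,
    lights = actogram$lights %||% rep(0L, length(actogram$counts)))
  names(df)[3] <- "lights"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeActogramCsv
#' @export
readActogramCsv <- function(path) {
  df <- read.csv(path)
  need <- c("bin_start_min", "count", "lights")
  if (!all(need %in% names(df)))
    stop("actogram CSV must have columns: ", paste(need, collapse = ", "))
  bw <- if (nrow(df) > 1) df$bin_start_min[2] - df$bin_start_min[1] else 1
  bins_per_day <- as.integer(round(24 * 60 / bw))
  days <- length(df$count) %/% bins_per_day
  sched <- vapply(seq_len(days), function(d) {
    sel <- ((d - 1) * bins_per_day + 1):(d * bins_per_day)
    if (any(df$lights[sel] > 0)) "LD" else "DD"
  }, character(1))
  structure(list(bin_width = bw, counts = df$count, schedule = sched,
                 days = days, lights = df$lights),
            class = "Actogram")
}

#' Write a periodogram result as TSV
#'
#' Format: \code{period_h\\tQp\\tthreshold\\tsignificant}.
#'
#' @param pg a \code{PeriodogramResult}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writePeriodogramTsv <- function(pg, path) {
  df <- data.frame(period_h = pg$test_periods, Qp = pg$Qp,
                   threshold = pg$significance_line,
                   significant = as.integer(pg$Qp > pg$significance_line))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / deserialize a ModelSpec as JSON
#'
#' The document carries a \code{schema_version} field, the species table,
#' reactions, transcription rules, binding rules and parameters.
#'
#' @param model a \code{ModelSpec}.
#' @param path file path.
#' @return \code{path}, invisibly (writer); a \code{ModelSpec} (reader).
#' @export
writeModelJson <- function(model, path) {
  doc <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    mode = model@mode,
    species = lapply(seq_len(nrow(model@species)), function(i) list(
      name = model@species$name[i],
      compartment = model@species$compartment[i],
      kind = model@species$kind[i],
      constituents = as.list(model@species$constituents[[i]]))),
    reactions = lapply(model@reactions, function(r) list(
      reactants = as.list(r$reactants), products = as.list(r$products),
      rate = r$rate)),
    transcription = model@transcription,
    binding_rules = model@bindingRules,
    parameters = model@parameters,
    metadata = model@metadata[setdiff(names(model@metadata),
                                      c("initial_state", "perturbations"))]
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  if (!file.exists(path)) stop("model JSON not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("malformed model JSON at ", path, ": ",
                         conditionMessage(e)))
  for (f in c("schema_version", "species", "parameters"))
    if (is.null(doc[[f]]))
      stop("malformed model JSON at ", path, ": missing field '", f, "'")
  species <- do.call(rbind, lapply(doc$species, function(s)
    speciesRow(s$name, s$compartment, s$kind,
               as.character(unlist(s$constituents)))))
  if (is.null(species))
    species <- speciesRow(character(0), character(0), character(0))[0, ]
  reactions <- lapply(doc$reactions, function(r) reaction(
    unlist(r$reactants) %||% numeric(0),
    unlist(r$products) %||% numeric(0),
    r$rate))
  transcription <- lapply(doc$transcription, function(t) {
    t$channels <- as.character(unlist(t$channels))
    t
  })
  params <- do.call(rbind, lapply(doc$parameters, function(p)
    data.frame(name = p$name, value = p$value, unit = p$unit)))
  if (is.null(params))
    params <- data.frame(name = character(0), value = numeric(0),
                         unit = character(0))
  rules <- do.call(rbind, lapply(doc$binding_rules, function(b)
    data.frame(partnerA = b$partnerA, partnerB = b$partnerB,
               allowed = b$allowed)))
  out <- new("ModelSpec", species = species, reactions = reactions,
             transcription = transcription,
             bindingRules = rules %||% makeBindingRules(
               data.frame(partnerA = character(0), partnerB = character(0),
                          allowed = logical(0))),
             parameters = params,
             mode = doc$mode %||% "reduced",
             metadata = c(doc$metadata, list(perturbations = list())))
  validObject(out)
  out
}

#' Write a cycle verdict / rhythm summary as JSON
#'
#' @param x a \code{CycleVerdict} or \code{RhythmSummary} (or any named
#'   list of scalars).
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeReportJson <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
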