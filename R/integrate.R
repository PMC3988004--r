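#' @include perturbation.R
NULL

# Compile a ModelSpec into a fast derivative closure for deSolve.
# Mass-action rate_j = k_j * prod(x[reactants_j]^stoich); the species
# derivative is S %*% rates plus the transcription-rule terms.
compileModel <- function(model) {
  sp <- model@species$name
  nsp <- length(sp)
  idx <- setNames(seq_len(nsp), sp)
  pv <- parameterValues(model)

  nr <- length(model@reactions)
  k <- numeric(nr)
  ri <- vector("list", nr)   # reactant indices
  rs <- vector("list", nr)   # reactant stoichiometries
  S <- matrix(0, nsp, nr)
  for (j in seq_len(nr)) {
    r <- model@reactions[[j]]
    k[j] <- pv[[r$rate]]
    ri[j] <- list(unname(idx[names(r$reactants)]))
    rs[j] <- list(as.numeric(r$reactants))
    if (length(r$reactants))
      S[idx[names(r$reactants)], j] <-
        S[idx[names(r$reactants)], j] - unname(r$reactants)
    if (length(r$products))
      S[idx[names(r$products)], j] <-
        S[idx[names(r$products)], j] + unname(r$products)
  }
  simple <- vapply(seq_len(nr), function(j)
    length(ri[[j]]) <= 2 && all(rs[[j]] == 1), logical(1))
  i1 <- vapply(seq_len(nr), function(j)
    if (length(ri[[j]]) >= 1) ri[[j]][1] else NA_integer_, integer(1))
  i2 <- vapply(seq_len(nr), function(j)
    if (length(ri[[j]]) >= 2) ri[[j]][2] else NA_integer_, integer(1))

  tr <- lapply(model@transcription, function(t) list(
    m = idx[[t$mrna]],
    type = t$type,
    drv = idx[[if (t$type == "ebox") t$activator else t$repressor]],
    v = pv[[t$vmax]], K = pv[[t$K]], basal = pv[[t$basal]]))

  derivs <- function(t, y, parms) {
    x <- pmax(y, 0)
    rates <- k
    for (j in seq_len(nr)) {
      if (is.na(i1[j])) next
      rates[j] <- if (simple[j]) {
        if (is.na(i2[j])) k[j] * x[i1[j]] else k[j] * x[i1[j]] * x[i2[j]]
      } else k[j] * prod(x[ri[[j]]]^rs[[j]])
    }
    dx <- as.vector(S %*% rates)
    for (r in tr) {
      d <- x[r$drv]
      dx[r$m] <- dx[r$m] + r$basal +
        if (r$type == "ebox") r$v * d / (r$K + d) else r$v * r$K / (r$K + d)
    }
    list(dx)
  }
  list(derivs = derivs, species = sp, nsp = nsp)
}

#' Default initial state for a model
#'
#' Modest non-negative starting concentrations (a.u.): 0.2 for mRNAs and
#' monomers, 0.01 for complexes, unless the model carries a stored
#' limit-cycle snapshot in its metadata.
#'
#' @param model a \code{ModelSpec}.
#' @return named numeric vector over all species.
#' @export
defaultInitialState <- function(model) {
  st <- model@metadata$initial_state
  if (!is.null(st) && all(model@species$name %in% names(st)))
    return(st[model@species$name])
  x <- ifelse(model@species$kind == "complex", 0.01, 0.2)
  setNames(x, model@species$name)
}

#' Integrate a clock model
#'
#' Deterministic stiff-capable integration (\code{deSolve::lsoda}) of the
#' mass-action network plus transcription rules.  The network mixes fast
#' binding and slow transcription timescales, so an adaptive stiff/
#' non-stiff switching method is used with tight default tolerances.
#'
#' @param model a \code{ModelSpec}.
#' @param initialState named numeric vector (defaults to
#'   \code{\link{defaultInitialState}}).
#' @param tEnd end time, hours (> 0).
#' @param stepOut output grid step, hours.
#' @param rtol,atol relative / absolute solver tolerances.
#' @param t0 start time, hours.
#' @return a \code{\link{Trajectory}}.
#' @export
integrateModel <- function(model, initialState = NULL, tEnd,
                           stepOut = 0.1, rtol = 1e-8, atol = 1e-10,
                           t0 = 0) {
  stopifnot(tEnd > t0)
  cm <- compileModel(model)
  y0 <- if (is.null(initialState)) defaultInitialState(model) else initialState
  if (length(y0) != cm$nsp)
    stop("initial state dimension (", length(y0),
         ") does not match species count (", cm$nsp, ")")
  y0 <- y0[cm$species]
  times <- seq(t0, tEnd, by = stepOut)
  out <- deSolve::lsoda(y = y0, times = times, func = cm$derivs,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  if (nrow(out) < length(times)) {
    last_t <- out[nrow(out), 1]
    stop(sprintf("integration failed at t = %.4f h", last_t))
  }
  states <- out[, -1, drop = FALSE]
  colnames(states) <- cm$species
  # round solver-scale negative undershoot up to zero
  states[states < 0 & states > -1e-6] <- 0
  new("Trajectory", times = out[, 1], states = states,
      metadata = list(
        parameter_set = model@metadata$parameter_set,
        mode = model@mode,
        perturbations = lapply(model@metadata$perturbations %||% list(),
                               formatPerturbation),
        rtol = rtol, atol = atol))
}
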