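#' @import methods
NULL

setClassUnion("dataframeOrNULL", c("data.frame", "NULL"))

#' Parameter set for one temperature regime
#'
#' Named, module-partitioned kinetic constants for a single culture
#' temperature. Slots hold named numeric vectors for the growth/death,
#' metabolism, antibody-synthesis, nucleotide/NSD and Golgi glycosylation
#' modules. Every parameter is addressable as \code{module.name}
#' (e.g. \code{"growth.mu_max"}) via [getParam()] / [setParam()].
#'
#' @slot temperature label of the regime, e.g. \code{"36.5C"}.
#' @slot growth,metabolism,mab,nsd,golgi named numeric parameter vectors.
#' @seealso [defaultParameters()], [paramUnits()]
#' @export
setClass("ParameterSet",
         representation(temperature = "character",
                        growth = "numeric",
                        metabolism = "numeric",
                        mab = "numeric",
                        nsd = "numeric",
                        golgi = "numeric"))

setValidity("ParameterSet", function(object) {
  msgs <- character()
  for (mod in c("growth", "metabolism", "mab", "nsd", "golgi")) {
    v <- slot(object, mod)
    need <- .PARAM_NAMES[[mod]]
    miss <- setdiff(need, names(v))
    if (length(miss))
      msgs <- c(msgs, sprintf("missing %s parameters: %s", mod,
                              paste(miss, collapse = ", ")))
    bad <- names(v)[!is.finite(v) | v < 0]
    if (length(bad))
      msgs <- c(msgs, sprintf("negative or non-finite %s parameters: %s",
                              mod, paste(bad, collapse = ", ")))
  }
  e2 <- object@mab["epsilon2"]
  if (is.finite(e2) && (e2 < 0 || e2 > 1))
    msgs <- c(msgs, "mab.epsilon2 must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Fed-batch experiment design
#'
#' Feed schedule, temperature-shift time, sampling times and initial
#' conditions of one bioreactor run. Bolus feeds are instantaneous
#' dilution-and-addition events; the glucose-only feed can additionally be
#' triggered on demand when extracellular glucose falls below a threshold at
#' a daily check.
#'
#' @slot tEnd end of the run (h).
#' @slot shiftTime temperature-shift time (h); \code{NA} for a
#'   constant-temperature run.
#' @slot feedEvents data.frame with columns \code{time}, \code{feed_id},
#'   \code{volume} (h, character, L).
#' @slot feedCompositions named list: feed_id -> named numeric of species
#'   concentrations (mM).
#' @slot glucoseFeeds data.frame with columns \code{time}, \code{volume},
#'   \code{conc}: scheduled glucose-only boluses ([Glc]_in,glc in mM).
#' @slot glucoseTrigger named numeric \code{c(threshold, volume, conc,
#'   checkEvery)}; set \code{volume = 0} to disable on-demand feeding.
#' @slot samplingTimes sampling schedule (h).
#' @slot initialState named numeric over all non-volume model states.
#' @slot initialVolume starting culture volume (L).
#' @export
setClass("ExperimentDesign",
         representation(tEnd = "numeric",
                        shiftTime = "numeric",
                        feedEvents = "data.frame",
                        feedCompositions = "list",
                        glucoseFeeds = "data.frame",
                        glucoseTrigger = "numeric",
                        samplingTimes = "numeric",
                        initialState = "numeric",
                        initialVolume = "numeric"))

setValidity("ExperimentDesign", function(object) {
  msgs <- character()
  tEnd <- object@tEnd
  if (length(tEnd) != 1 || !is.finite(tEnd) || tEnd <= 0)
    msgs <- c(msgs, "tEnd must be a single positive number")
  st <- object@shiftTime
  if (length(st) != 1) msgs <- c(msgs, "shiftTime must be length 1 (NA for none)")
  else if (!is.na(st) && (st < 0 || st > tEnd))
    msgs <- c(msgs, "shiftTime must lie in [0, tEnd]")
  fe <- object@feedEvents
  if (!all(c("time", "feed_id", "volume") %in% names(fe)))
    msgs <- c(msgs, "feedEvents needs columns time, feed_id, volume")
  else {
    if (nrow(fe) && (any(fe$time < 0) || any(fe$time > tEnd)))
      msgs <- c(msgs, "feed event times must lie in [0, tEnd]")
    if (nrow(fe) && any(fe$volume <= 0))
      msgs <- c(msgs, "feed volumes must be positive")
    unknown <- setdiff(unique(fe$feed_id), names(object@feedCompositions))
    if (length(unknown))
      msgs <- c(msgs, sprintf("feed_id without composition: %s",
                              paste(unknown, collapse = ", ")))
  }
  for (comp in object@feedCompositions) {
    if (any(comp < 0)) msgs <- c(msgs, "feed compositions must be non-negative")
    if (length(setdiff(names(comp), .STATE_CULTURE)))
      msgs <- c(msgs, "feed composition names must be culture species")
  }
  gf <- object@glucoseFeeds
  if (!all(c("time", "volume", "conc") %in% names(gf)))
    msgs <- c(msgs, "glucoseFeeds needs columns time, volume, conc")
  else if (nrow(gf) && (any(gf$time < 0) || any(gf$time > tEnd) ||
                        any(gf$volume <= 0) || any(gf$conc < 0)))
    msgs <- c(msgs, "invalid glucose feed events")
  gt <- object@glucoseTrigger
  if (!all(c("threshold", "volume", "conc", "checkEvery") %in% names(gt)))
    msgs <- c(msgs, "glucoseTrigger needs threshold, volume, conc, checkEvery")
  stt <- object@samplingTimes
  if (length(stt) && (is.unsorted(stt, strictly = TRUE) ||
                      any(stt < 0) || any(stt > tEnd)))
    msgs <- c(msgs, "samplingTimes must be strictly increasing within [0, tEnd]")
  y0 <- object@initialState
  miss <- setdiff(setdiff(.STATE_ALL, "V"), names(y0))
  if (length(miss))
    msgs <- c(msgs, sprintf("initialState missing: %s", paste(miss, collapse = ", ")))
  else {
    if (any(y0 < 0)) msgs <- c(msgs, "initial concentrations must be non-negative")
    if (y0["Xt"] < y0["Xv"]) msgs <- c(msgs, "initial Xt must be >= Xv")
  }
  if (length(object@initialVolume) != 1 || object@initialVolume <= 0)
    msgs <- c(msgs, "initialVolume must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Simulated culture trajectory
#'
#' Output of [integrateCulture()]: the full state at every requested time,
#' plus derived specific rates (growth, death, metabolite and mAb rates).
#'
#' @slot times time grid (h), strictly increasing.
#' @slot states numeric matrix, one row per time, columns named by state.
#' @slot derived numeric matrix of derived rates (mu, mud, q_glc, q_lac,
#'   q_amm, q_mAb) per time.
#' @slot design the [ExperimentDesign-class] that produced the run.
#' @slot modules character: which model modules were active.
#' @slot regime character regime label per time point.
#' @export
setClass("Trajectory",
         representation(times = "numeric",
                        states = "matrix",
                        derived = "matrix",
                        design = "ExperimentDesign",
                        modules = "character",
                        regime = "character"))

setValidity("Trajectory", function(object) {
  msgs <- character()
  if (is.unsorted(object@times, strictly = TRUE))
    msgs <- c(msgs, "times must be strictly increasing")
  if (nrow(object@states) != length(object@times))
    msgs <- c(msgs, "states must have one row per time")
  if (any(object@states < -1e-8, na.rm = TRUE))
    msgs <- c(msgs, "state values must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Golgi glycan processing network
#'
#' Directed acyclic reaction network of mAb Fc N-glycan processing: species,
#' reactions (substrate, product, catalysing enzyme, NSD co-substrate and
#' the name of the dissociation constant used), and the enzyme list.
#'
#' @slot species ordered character vector of glycan species; the first entry
#'   is the inlet species.
#' @slot reactions data.frame with columns \code{substrate}, \code{product},
#'   \code{enzyme}, \code{nsd} (NA for mannosidases), \code{kd} (name of the
#'   dissociation-constant parameter in the golgi slot).
#' @slot enzymes character vector of enzyme names.
#' @export
setClass("GlycanNetwork",
         representation(species = "character",
                        reactions = "data.frame",
                        enzymes = "character"))

setValidity("GlycanNetwork", function(object) {
  msgs <- character()
  rx <- object@reactions
  need <- c("substrate", "product", "enzyme", "nsd", "kd")
  if (!all(need %in% names(rx)))
    return(sprintf("reactions needs columns %s", paste(need, collapse = ", ")))
  sp <- object@species
  if (anyDuplicated(sp)) msgs <- c(msgs, "duplicate species")
  dangling <- setdiff(c(rx$substrate, rx$product), sp)
  if (length(dangling))
    msgs <- c(msgs, sprintf("undeclared species: %s", paste(dangling, collapse = ", ")))
  if (length(setdiff(rx$enzyme, object@enzymes)))
    msgs <- c(msgs, "undeclared enzyme")
  # DAG check by repeated leaf-stripping over the substrate->product graph
  if (!length(msgs) && nrow(rx)) {
    edges <- rx[, c("substrate", "product")]
    nodes <- sp
    repeat {
      leaves <- setdiff(nodes, edges$substrate)
      if (!length(leaves)) break
      nodes <- setdiff(nodes, leaves)
      edges <- edges[!(edges$product %in% leaves), , drop = FALSE]
      if (!nrow(edges)) break
    }
    if (nrow(edges)) msgs <- c(msgs, "reaction network contains a cycle")
    # reachability from inlet
    reach <- sp[1]
    repeat {
      nxt <- unique(rx$product[rx$substrate %in% reach])
      new <- setdiff(nxt, reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    unreach <- setdiff(sp, reach)
    if (length(unreach))
      msgs <- c(msgs, sprintf("species unreachable from inlet: %s",
                              paste(unreach, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Maximum-likelihood fit result
#'
#' @slot estimates named numeric of fitted parameter values (best start).
#' @slot se normal-approximation standard errors (NA when not identifiable).
#' @slot ciLower,ciUpper 95\% confidence bounds.
#' @slot nll negative log-likelihood at the optimum.
#' @slot convergence integer code from the optimizer (0 = success).
#' @slot message optimizer message for the best start.
#' @slot starts data.frame of all multistart results.
#' @slot residuals data.frame of data, predictions and residuals.
#' @slot identifiable logical per parameter: finite positive-variance CI.
#' @slot freeNames character parameter names in estimation order.
#' @export
setClass("FitResult",
         representation(estimates = "numeric",
                        se = "numeric",
                        ciLower = "numeric",
                        ciUpper = "numeric",
                        nll = "numeric",
                        convergence = "integer",
                        message = "character",
                        starts = "data.frame",
                        residuals = "dataframeOrNULL",
                        identifiable = "logical",
                        freeNames = "character"))

#' Measurement noise model for the synthetic-data generator
#'
#' Multiplicative log-normal measurement error with class-specific
#' coefficients of variation (CV). The log-normal factor is mean-one, so
#' noisy measurements are non-negative and unbiased.
#'
#' @slot cvExtracellular CV for extracellular species, cells and titer.
#' @slot cvIntracellular CV for intracellular species.
#' @slot cvGlycoform CV for glycoform fractions.
#' @slot cvOverride named numeric of per-species CV overrides.
#' @export
setClass("NoiseModel",
         representation(cvExtracellular = "numeric",
                        cvIntracellular = "numeric",
                        cvGlycoform = "numeric",
                        cvOverride = "numeric"))

setValidity("NoiseModel", function(object) {
  cvs <- c(object@cvExtracellular, object@cvIntracellular,
           object@cvGlycoform, object@cvOverride)
  if (any(cvs < 0)) "CVs must be non-negative" else TRUE
})
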