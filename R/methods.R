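# show() methods and small accessors.

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet <", object@temperature, ">\n", sep = "")
  for (mod in c("growth", "metabolism", "mab", "nsd", "golgi"))
    cat(sprintf("  %-10s %d parameters\n", mod, length(slot(object, mod))))
  invisible(NULL)
})

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf("ExperimentDesign: %g h run, %s, %d feed events, %d sampling times\n",
              object@tEnd,
              if (is.na(object@shiftTime)) "constant temperature"
              else sprintf("shift at %g h", object@shiftTime),
              nrow(object@feedEvents), length(object@samplingTimes)))
  invisible(NULL)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d time points over [%g, %g] h; modules: %s\n",
              length(object@times), min(object@times), max(object@times),
              paste(object@modules, collapse = "+")))
  invisible(NULL)
})

setMethod("show", "GlycanNetwork", function(object) {
  cat(sprintf("GlycanNetwork: %d species, %d reactions, enzymes: %s\n",
              length(object@species), nrow(object@reactions),
              paste(object@enzymes, collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: NLL = %.6g (convergence %d, %d starts)\n",
              object@nll, object@convergence, nrow(object@starts)))
  if (length(object@estimates)) {
    df <- data.frame(estimate = object@estimates,
                     ci_lower = object@ciLower,
                     ci_upper = object@ciUpper,
                     identifiable = object@identifiable)
    print(df)
  }
  invisible(NULL)
})

#' Accessors for fit results and trajectories
#'
#' \code{estimates()} returns the fitted values, \code{confint95()} the
#' 95\% normal-approximation interval table, \code{trajectoryStates()} the
#' state matrix and \code{trajectoryTimes()} the time grid.
#'
#' @param object a [FitResult-class] or [Trajectory-class].
#' @return see individual functions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @rdname accessors
#' @export
setMethod("estimates", "FitResult", function(object) object@estimates)

#' @rdname accessors
#' @export
setGeneric("confint95", function(object) standardGeneric("confint95"))

#' @rdname accessors
#' @export
setMethod("confint95", "FitResult", function(object)
  data.frame(parameter = object@freeNames,
             estimate = unname(object@estimates),
             se = unname(object@se),
             lower = unname(object@ciLower),
             upper = unname(object@ciUpper),
             identifiable = unname(object@identifiable),
             row.names = NULL))

#' @rdname accessors
#' @export
setGeneric("trajectoryStates", function(object) standardGeneric("trajectoryStates"))

#' @rdname accessors
#' @export
setMethod("trajectoryStates", "Trajectory", function(object) object@states)

#' @rdname accessors
#' @export
setGeneric("trajectoryTimes", function(object) standardGeneric("trajectoryTimes"))

#' @rdname accessors
#' @export
setMethod("trajectoryTimes", "Trajectory", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("derivedRates", function(object) standardGeneric("derivedRates"))

#' @rdname accessors
#' @export
setMethod("derivedRates", "Trajectory", function(object) object@derived)
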