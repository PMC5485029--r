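# Maximum-likelihood estimation against long-format measurement tables.
# Gaussian error model per measurement; bound-constrained local
# optimization (nlminb) from Latin-hypercube multistarts; 95% confidence
# intervals from the observed-information Hessian.

#' Gaussian negative log-likelihood of a prediction table
#'
#' Matches predictions to data by (species, time) and sums
#' \eqn{\frac{1}{2}\log(2\pi\sigma^2) + \frac{(y-\hat y)^2}{2\sigma^2}}.
#' The error model is either the data's \code{sd} column
#' (\code{errorModel = "sd"}) or constant-relative
#' (\eqn{\sigma = cv \cdot \max(|y|, floor)}) with a tiny per-species floor
#' (1e-6 of the species' maximum magnitude) that only guards against
#' exactly-zero measurements.
#'
#' @param data data.frame time_h, species, value (and sd).
#' @param prediction data.frame time_h, species, value.
#' @param errorModel \code{"relative"} or \code{"sd"}.
#' @param cv relative-error CV (default 0.1).
#' @return scalar negative log-likelihood; rows of \code{data} without a
#'   matching prediction raise an error.
#' @export
negLogLikelihood <- function(data, prediction, errorModel = c("relative", "sd"),
                             cv = 0.1) {
  errorModel <- match.arg(errorModel)
  key <- paste(data$species, signif(data$time_h, 12))
  pkey <- paste(prediction$species, signif(prediction$time_h, 12))
  idx <- match(key, pkey)
  if (anyNA(idx))
    stop(sprintf("no prediction for %s",
                 paste(utils::head(key[is.na(idx)], 3), collapse = "; ")),
         call. = FALSE)
  yhat <- prediction$value[idx]
  y <- data$value
  if (errorModel == "sd") {
    sigma <- data$sd
    if (any(!is.finite(sigma) | sigma <= 0))
      stop("errorModel='sd' requires a positive sd column", call. = FALSE)
  } else {
    floorBy <- stats::ave(abs(y), data$species,
                          FUN = function(v) max(v, na.rm = TRUE) * 1e-6)
    sigma <- cv * pmax(abs(y), floorBy, 1e-300)
  }
  sum(0.5 * log(2 * pi * sigma^2) + 0.5 * ((y - yhat) / sigma)^2)
}

#' Specify free parameters for a fit
#'
#' @param name dotted parameter paths (\code{"module.name"}).
#' @param lower,upper box bounds (recycled).
#' @param init initial central values (defaults to the current parameter
#'   values at fit time).
#' @param regime \code{"pre"}, \code{"post"} or \code{"both"}: which
#'   regime's parameter set the entry applies to (recycled).
#' @return data.frame understood by [fitParameters()].
#' @export
freeParameters <- function(name, lower, upper, init = NA_real_,
                           regime = "pre") {
  if (!length(name))
    return(data.frame(name = character(), lower = numeric(),
                      upper = numeric(), init = numeric(),
                      regime = character(), stringsAsFactors = FALSE))
  data.frame(name = name, lower = lower, upper = upper, init = init,
             regime = regime, stringsAsFactors = FALSE)
}

.applyFree <- function(params, paramsPost, free, x) {
  for (i in seq_len(nrow(free))) {
    r <- free$regime[i]
    if (r %in% c("pre", "both"))
      params <- setParam(params, free$name[i], x[i])
    if (!is.null(paramsPost) && r %in% c("post", "both"))
      paramsPost <- setParam(paramsPost, free$name[i], x[i])
  }
  list(pre = params, post = paramsPost)
}

#' Maximum-likelihood parameter fit
#'
#' Minimizes the Gaussian negative log-likelihood over the free parameters
#' with bound-constrained local optimization (\code{stats::nlminb}) from
#' \code{nStarts} Latin-hypercube starting points spanning the bounds
#' (plus the initial value itself); one-dimensional problems additionally
#' run a derivative-free Brent search over the whole interval and the best
#' optimum wins. Simulation failures inside the objective return a large
#' penalty so the optimizer can retreat.
#' 95% confidence intervals use the observed-information Hessian
#' (numerical, \code{pracma::hessian}) under the normal approximation;
#' parameters whose variance estimate is not positive are flagged
#' non-identifiable and reported with NA intervals rather than silently.
#'
#' @param data measurement table (time_h, species, value, sd).
#' @param free data.frame from [freeParameters()].
#' @param params pre-shift [ParameterSet-class] (initial/fixed values).
#' @param paramsPost post-shift set when fitting a shifted design.
#' @param design an [ExperimentDesign-class] (used by the default
#'   predictor).
#' @param predictFn optional custom predictor:
#'   \code{function(paramsPre, paramsPost)} returning a data.frame
#'   \code{time_h, species, value}. Defaults to simulating the design with
#'   [integrateCulture()] over \code{modules}.
#' @param modules modules for the default predictor.
#' @param errorModel,cv passed to [negLogLikelihood()].
#' @param nStarts number of multistart points (default 20).
#' @param seed seed for the Latin-hypercube draw.
#' @param fitWindow optional \code{c(tmin, tmax)}: restrict the likelihood
#'   to data inside the window.
#' @param rtol,atol solver tolerances used during fitting.
#' @param control passed to \code{nlminb}.
#' @return a [FitResult-class].
#' @export
fitParameters <- function(data, free, params, paramsPost = NULL,
                          design = NULL, predictFn = NULL,
                          modules = "culture",
                          errorModel = c("relative", "sd"), cv = 0.1,
                          nStarts = 20, seed = 1, fitWindow = NULL,
                          rtol = 1e-6, atol = 1e-8,
                          control = list(rel.tol = 1e-10)) {
  errorModel <- match.arg(errorModel)
  stopifnot(nrow(free) >= 0)
  if (!is.null(fitWindow))
    data <- data[data$time_h >= fitWindow[1] & data$time_h <= fitWindow[2], ]
  if (!nrow(data)) stop("no data in fit window", call. = FALSE)
  if (is.null(predictFn)) {
    if (is.null(design)) stop("need a design or a predictFn", call. = FALSE)
    predictFn <- function(pPre, pPost) {
      tr <- integrateCulture(design, pPre, pPost, modules = modules,
                             times = sort(unique(c(0, data$time_h))),
                             rtol = rtol, atol = atol)
      trajectoryToLong(tr)
    }
  }
  init <- free$init
  for (i in seq_len(nrow(free)))
    if (is.na(init[i])) init[i] <- getParam(
      if (free$regime[i] == "post" && !is.null(paramsPost)) paramsPost
      else params, free$name[i])
  init <- pmin(pmax(init, free$lower), free$upper)

  objective <- function(x) {
    ps <- tryCatch(.applyFree(params, paramsPost, free, x),
                   error = function(e) NULL)
    if (is.null(ps)) return(1e10)
    pred <- tryCatch(predictFn(ps$pre, ps$post), error = function(e) NULL)
    if (is.null(pred) || anyNA(pred$value)) return(1e10)
    nll <- tryCatch(negLogLikelihood(data, pred, errorModel, cv),
                    error = function(e) NA_real_)
    if (!is.finite(nll)) 1e10 else nll
  }

  if (nrow(free) == 0) {
    nll <- objective(numeric(0))
    return(new("FitResult", estimates = numeric(0), se = numeric(0),
               ciLower = numeric(0), ciUpper = numeric(0), nll = nll,
               convergence = 0L, message = "no free parameters",
               starts = data.frame(), residuals = NULL,
               identifiable = logical(0), freeNames = character(0)))
  }

  # optimize in unit scale: free parameters span many orders of magnitude
  # (yields ~1e9 beside transport coefficients ~1e-12), which breaks
  # finite-difference steps on the raw scale
  ref <- pmax(abs(init), 1e-3 * pmax(abs(free$lower), abs(free$upper)))
  ref[ref == 0] <- 1
  objScaled <- function(u) objective(u * ref)

  set.seed(seed)
  nLhs <- max(nStarts - 1, 0)
  startMat <- rbind(init, if (nLhs > 0) {
    u <- lhs::randomLHS(nLhs, nrow(free))
    sweep(sweep(u, 2, free$upper - free$lower, `*`), 2, free$lower, `+`)
  })
  res <- vector("list", nrow(startMat))
  for (k in seq_len(nrow(startMat))) {
    res[[k]] <- tryCatch({
      r <- stats::nlminb(startMat[k, ] / ref, objScaled,
                         lower = free$lower / ref,
                         upper = free$upper / ref, control = control)
      r$par <- r$par * ref
      r
    }, error = function(e) list(objective = Inf, par = startMat[k, ],
                                convergence = 1L,
                                message = conditionMessage(e)))
  }
  # one-dimensional problems additionally get a derivative-free Brent
  # search over the whole interval: the finite-difference gradients that
  # nlminb relies on can stall when the simulator's adaptive-step noise is
  # comparable to the FD step
  if (nrow(free) == 1) {
    br <- tryCatch(stats::optimize(function(u) objScaled(u),
                                   lower = free$lower / ref,
                                   upper = free$upper / ref,
                                   tol = 1e-9),
                   error = function(e) NULL)
    if (!is.null(br))
      res <- c(res, list(list(objective = br$objective,
                              par = br$minimum * ref,
                              convergence = 0L, message = "brent")))
  }
  objs <- vapply(res, function(r) r$objective, numeric(1))
  if (all(!is.finite(objs) | objs >= 1e10))
    stop(paste0("all ", length(res), " starts failed; messages: ",
                paste(unique(vapply(res, function(r)
                  as.character(r$message %||% ""), character(1))),
                  collapse = "; ")), call. = FALSE)
  best <- res[[which.min(objs)]]
  est <- best$par
  names(est) <- free$name

  # observed-information CIs (Hessian in unit scale, mapped back)
  se <- rep(NA_real_, nrow(free))
  H <- tryCatch(pracma::hessian(objScaled, est / ref),
                error = function(e) NULL)
  if (!is.null(H)) {
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      v <- diag(cov) * ref^2
      se[v > 0] <- sqrt(v[v > 0])
    }
  }
  identifiable <- is.finite(se) & se > 0
  ciL <- est - 1.959963984540054 * se
  ciU <- est + 1.959963984540054 * se
  names(se) <- names(ciL) <- names(ciU) <- free$name
  names(identifiable) <- free$name

  ps <- .applyFree(params, paramsPost, free, est)
  pred <- predictFn(ps$pre, ps$post)
  key <- paste(data$species, signif(data$time_h, 12))
  pkey <- paste(pred$species, signif(pred$time_h, 12))
  resid <- data
  resid$predicted <- pred$value[match(key, pkey)]
  resid$residual <- resid$value - resid$predicted

  starts <- data.frame(start = seq_along(res),
                       nll = objs,
                       convergence = vapply(res, function(r)
                         as.integer(r$convergence %||% 1L), integer(1)))
  for (i in seq_len(nrow(free)))
    starts[[free$name[i]]] <- vapply(res, function(r) r$par[i], numeric(1))

  new("FitResult", estimates = est, se = se, ciLower = ciL, ciUpper = ciU,
      nll = best$objective, convergence = as.integer(best$convergence),
      message = as.character(best$message %||% ""),
      starts = starts, residuals = resid, identifiable = identifiable,
      freeNames = free$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare fitted parameter values between two temperature regimes
#'
#' Per-parameter ratio (regime B over regime A), 95% CI overlap flag and
#' direction of change. Typically A is the physiological fit and B the
#' mild-hypothermia fit, so \code{ratio < 1} means the parameter drops on
#' the shift.
#'
#' @param fitA,fitB [FitResult-class] objects over the same parameters.
#' @return data.frame parameter, estimate_A, estimate_B, ratio,
#'   ci_overlap, direction.
#' @export
compareRegimes <- function(fitA, fitB) {
  if (!identical(fitA@freeNames, fitB@freeNames))
    stop("fits estimate different parameters", call. = FALSE)
  a <- fitA@estimates; b <- fitB@estimates
  overlap <- pmax(fitA@ciLower, fitB@ciLower) <=
    pmin(fitA@ciUpper, fitB@ciUpper)
  data.frame(parameter = fitA@freeNames,
             estimate_A = unname(a), estimate_B = unname(b),
             ratio = unname(b / a),
             ci_overlap = unname(overlap),
             direction = ifelse(b > a, "up", ifelse(b < a, "down", "equal")),
             row.names = NULL)
}

#' Two-regime parameter contrast for full parameter sets
#'
#' Ratios 32C/36.5C over a chosen parameter list, with the qualitative
#' orderings reported as logical flags — the machine-checkable form of the
#' published two-temperature comparison (all NSD maximum rates lower under
#' mild hypothermia, GalT lower, FucT higher, assembly constant lower,
#' transport/translation constants higher).
#'
#' @param pHot 36.5C [ParameterSet-class].
#' @param pCold 32C [ParameterSet-class].
#' @return list with \code{table} (parameter, hot, cold, ratio) and
#'   \code{orderings} (named logicals).
#' @export
parameterContrast <- function(pHot, pCold) {
  nsdV <- paste0("nsd.V_max_", c("UDPGlc", "UDPGal", "UDPGlcNAc",
                                 "UDPGalNAc", "GDPMan", "GDPFuc"))
  nm <- c("growth.mu_max", "growth.mu_d_max", "growth.K_lysis",
          "metabolism.Y_lac_glc",
          "mab.K_A", "mab.K_ER", "mab.K_G", "mab.T_H", "mab.T_L",
          nsdV, "golgi.E_GalT", "golgi.E_FucT")
  hot <- getParam(pHot, nm); cold <- getParam(pCold, nm)
  tab <- data.frame(parameter = nm, hot = unname(hot), cold = unname(cold),
                    ratio = unname(cold / hot), row.names = NULL)
  ord <- c(
    nsd_vmax_all_lower = all(cold[nsdV] < hot[nsdV]),
    galt_lower = cold[["golgi.E_GalT"]] < hot[["golgi.E_GalT"]],
    fuct_higher = cold[["golgi.E_FucT"]] > hot[["golgi.E_FucT"]],
    assembly_lower = cold[["mab.K_A"]] < hot[["mab.K_A"]],
    transport_translation_higher = all(
      cold[c("mab.K_ER", "mab.K_G", "mab.T_H", "mab.T_L")] >
        hot[c("mab.K_ER", "mab.K_G", "mab.T_H", "mab.T_L")]),
    growth_slower = cold[["growth.mu_max"]] < hot[["growth.mu_max"]])
  list(table = tab, orderings = ord)
}
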