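# Independent fixed-step integrators used as oracles. These deliberately
# share only the model right-hand side with the package: the stepping,
# event application and bookkeeping are re-implemented here.

# classic RK4 with fixed step h from t0 to t1 (h is shortened on the last
# step to land exactly on t1)
rk4Steps <- function(rhs, y, t0, t1, h) {
  t <- t0
  while (t < t1 - 1e-12) {
    hh <- min(h, t1 - t)
    k1 <- rhs(t, y, NULL)[[1]]
    k2 <- rhs(t + hh / 2, y + hh / 2 * k1, NULL)[[1]]
    k3 <- rhs(t + hh / 2, y + hh / 2 * k2, NULL)[[1]]
    k4 <- rhs(t + hh, y + hh * k3, NULL)[[1]]
    y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + hh
  }
  y
}

# hand-written bolus mixing (independent of the package's event code)
oracleBolus <- function(y, vol, comp) {
  V <- y[["V"]]
  concNames <- setdiff(names(y), "V")
  added <- setNames(numeric(length(concNames)), concNames)
  if (length(comp)) added[names(comp)] <- comp
  y[concNames] <- (y[concNames] * V + added * vol) / (V + vol)
  y[["V"]] <- V + vol
  y
}

# full fed-batch culture-module run with RK4: same design semantics
# (bolus feeds, daily glucose-trigger checks, regime switch) implemented
# independently, reporting states at the design sampling times.
oracleCultureRun <- function(design, params, paramsPost = NULL, h = 0.01) {
  rhs <- hypothermAb:::.makeRHS(params, "culture")
  stateNames <- c("V", setdiff(hypothermAb:::.STATE_CULTURE, "V"))
  y <- c(V = design@initialVolume,
         design@initialState[setdiff(stateNames, "V")])
  names(y) <- stateNames
  gt <- design@glucoseTrigger
  evTimes <- sort(unique(c(
    design@feedEvents$time,
    if (gt[["volume"]] > 0) seq(gt[["checkEvery"]], design@tEnd,
                                by = gt[["checkEvery"]]),
    design@shiftTime[!is.na(design@shiftTime)],
    design@samplingTimes, design@tEnd)))
  evTimes <- evTimes[evTimes > 0]
  out <- matrix(NA_real_, length(design@samplingTimes), length(y),
                dimnames = list(NULL, stateNames))
  if (design@samplingTimes[1] == 0) out[1, ] <- y
  cur <- 0
  for (tb in evTimes) {
    y <- rk4Steps(rhs, y, cur, tb, h)
    for (i in which(abs(design@feedEvents$time - tb) < 1e-9)) {
      y <- oracleBolus(y, design@feedEvents$volume[i],
                       design@feedCompositions[[design@feedEvents$feed_id[i]]])
    }
    if (gt[["volume"]] > 0 && tb %% gt[["checkEvery"]] < 1e-9 &&
        y[["Glc"]] < gt[["threshold"]]) {
      y <- oracleBolus(y, gt[["volume"]], c(Glc = gt[["conc"]]))
    }
    if (!is.na(design@shiftTime) && abs(tb - design@shiftTime) < 1e-9 &&
        !is.null(paramsPost)) {
      rhs <- hypothermAb:::.makeRHS(paramsPost, "culture")
    }
    hit <- which(abs(design@samplingTimes - tb) < 1e-9)
    if (length(hit)) out[hit, ] <- y
    cur <- tb
  }
  out
}

# first-order upwind (explicit Euler) fixed-grid PFR solve with nSteps
# cells, using the package's reference rate function.
oracleGolgiUpwind <- function(inletSpecies, nsd, params,
                              network = buildGlycanNetwork(),
                              nSteps = 10000) {
  p <- params@golgi
  sp <- network@species
  conc <- setNames(numeric(length(sp)), sp)
  conc[inletSpecies] <- p[["inletConc"]]
  rx <- network@reactions
  iS <- match(rx$substrate, sp)
  iP <- match(rx$product, sp)
  dz <- 1 / nSteps
  for (step in seq_len(nSteps)) {
    r <- golgiReactionRates(conc, nsd, p, network)
    # positivity-preserving limiter: a cell cannot convert more substrate
    # than it holds, so outgoing rates are scaled per species (plain
    # clamping would create mass in the sharp inlet layers)
    out <- numeric(length(sp))
    for (k in seq_along(r)) out[iS[k]] <- out[iS[k]] + r[k]
    lim <- ifelse(out > 0, pmin(1, conc / (dz * p[["tau"]] * out)), 1)
    r <- r * lim[iS]
    d <- numeric(length(sp))
    for (k in seq_along(r)) {
      d[iS[k]] <- d[iS[k]] - r[k]
      d[iP[k]] <- d[iP[k]] + r[k]
    }
    conc <- pmax(conc + dz * p[["tau"]] * d, 0)
  }
  conc / sum(conc)
}

relErr <- function(a, b) {
  scale <- pmax(abs(a), abs(b))
  err <- abs(a - b) / scale
  err[scale < 1e-10] <- 0
  err
}
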