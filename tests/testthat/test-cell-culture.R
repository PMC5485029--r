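p36 <- defaultParameters("36.5C")
g <- p36@growth
m <- p36@metabolism

state0 <- c(Xv = 1e9, Xt = 1e9, Glc = 40, Lac = 5, Amm = 2,
            Asn = 10, Asp = 4, Arg = 4, Glu = 4, Gln = 6, Lys = 4, Pro = 4,
            mAb = 0)

test_that("growth rate reaches its saturating limit and vanishes without lactate", {
  sat <- state0
  sat[c("Glc", "Asn", "Glu")] <- 1e6
  # lactate sits in both limitation and inhibition; its optimum is
  # sqrt(K_lac * KI_lac), where the combined factor is ~0.92
  sat["Lac"] <- sqrt(g[["K_lac"]] * g[["KI_lac"]])
  sat["Amm"] <- 0
  expect_gt(specificGrowthRate(sat, g), 0.9 * g[["mu_max"]])
  expect_lte(specificGrowthRate(sat, g), g[["mu_max"]])

  noLac <- sat
  noLac["Lac"] <- 0
  expect_identical(specificGrowthRate(noLac, g), 0)
})

test_that("growth rate is the hand-evaluated product of saturation terms", {
  s <- state0
  s["Glc"] <- g[["K_glc"]]; s["Asn"] <- g[["K_asn"]]; s["Glu"] <- g[["K_glu"]]
  s["Amm"] <- g[["KI_amm"]]
  s["Lac"] <- g[["KI_lac"]]   # lactate inhibition at half; limitation ~ 1
  byHand <- g[["mu_max"]] *
    0.5 * (s[["Lac"]] / (g[["K_lac"]] + s[["Lac"]])) * 0.5 * 0.5 *
    0.5 * (g[["KI_lac"]] / (g[["KI_lac"]] + s[["Lac"]]))
  expect_equal(specificGrowthRate(s, g), byHand, tolerance = 1e-12)
})

test_that("death rate is zero without ammonia, half-saturating, bounded", {
  expect_identical(specificDeathRate(0, g), 0)
  expect_equal(specificDeathRate(g[["K_d_amm"]], g), g[["mu_d_max"]] / 2)
  expect_lt(specificDeathRate(1e9, g), g[["mu_d_max"]])
  expect_gt(specificDeathRate(1e9, g), 0.999 * g[["mu_d_max"]])
  amm <- c(0.5, 1, 2, 4, 8, 16)
  expect_true(all(diff(vapply(amm, specificDeathRate, numeric(1),
                              p = g)) > 0))
})

test_that("metabolite rates follow the stated reductions", {
  # mu = 0: glucose consumption is maintenance only
  q0 <- metaboliteRates(state0, 0, m)
  expect_equal(unname(q0[["Glc"]]), -m[["m_glc"]])
  expect_lt(q0[["Glc"]], 0)
  # zero lactate: pure production, stoichiometric to glucose flux
  sNoLac <- state0; sNoLac["Lac"] <- 0
  q <- metaboliteRates(sNoLac, 0.05, m)
  qglc <- -0.05 / m[["Y_xv_glc"]] - m[["m_glc"]]
  expect_equal(unname(q[["Lac"]]), -qglc * m[["Y_lac_glc"]])
  # ammonia reduces to the growth term when gln/asn/arg rates vanish
  m2 <- m
  m2[c("Y_xv_gln", "Y_xv_asn", "Y_xv_arg")] <- Inf
  m2[c("m_gln", "m_asn", "m_arg")] <- 0
  q2 <- metaboliteRates(state0, 0.05, m2, q_mAb = 0)
  expect_equal(unname(q2[["Amm"]]), 0.05 / m[["Y_xv_amm"]])
})

test_that("culture balances: no growth means frozen cells, no lysis when Xt = Xv", {
  d <- cultureRHS(state0, p36)
  expect_identical(unname(d[["V"]]), 0)
  # Xt == Xv: the lysis term contributes nothing to total-cell dynamics
  rates <- attr(d, "rates")
  expect_equal(unname(d[["Xt"]]), rates[["mu"]] * state0[["Xv"]])
  # zero growth and death: viable cells frozen
  gz <- p36
  gz@growth["mu_max"] <- 0
  s <- state0; s["Amm"] <- 0
  dz <- cultureRHS(s, gz)
  expect_identical(unname(dz[["Xv"]]), 0)
})

test_that("specific rates stay within their bounds across random states", {
  set.seed(42)
  for (i in 1:200) {
    s <- state0
    s[c("Glc", "Lac", "Amm", "Asn", "Glu")] <-
      stats::runif(5, 0, 100)
    mu <- specificGrowthRate(s, g)
    mud <- specificDeathRate(s[["Amm"]], g)
    expect_gte(mu, 0); expect_lte(mu, g[["mu_max"]])
    expect_gte(mud, 0); expect_lte(mud, g[["mu_d_max"]])
  }
})

test_that("nutrient-excess growth is exponential at mu_max over 24 h", {
  # saturating nutrients, no ammonia, death and lysis disabled
  p <- p36
  p@growth["mu_d_max"] <- 0
  p@growth["K_lysis"] <- 0
  des <- defaultDesign(shift = FALSE)
  init <- des@initialState
  init[c("Glc", "Asn", "Glu")] <- 1e6
  init["Lac"] <- 50 * p@growth[["K_lac"]]
  init["Amm"] <- 0
  # freeze metabolite consumption so saturation persists
  p@metabolism["Y_xv_glc"] <- Inf
  p@metabolism[paste0("Y_xv_", tolower(c("Asn", "Asp", "Arg", "Glu",
                                         "Gln", "Lys", "Pro")))] <- Inf
  p@metabolism[c("m_glc", paste0("m_", tolower(c("Asn", "Asp", "Arg",
                                                 "Glu", "Gln", "Lys",
                                                 "Pro"))))] <- 0
  p@metabolism["Y_lac_glc"] <- 0
  p@metabolism["k_T_lac"] <- 0
  p@metabolism["Y_xv_lac"] <- Inf
  p@metabolism["Y_xv_amm"] <- Inf
  des@initialState <- init
  des@feedEvents <- des@feedEvents[0, ]
  des@glucoseTrigger["volume"] <- 0
  des@samplingTimes <- c(0, 24)
  tr <- integrateCulture(des, p, modules = "culture")
  muEff <- p@growth[["mu_max"]] *
    (init[["Lac"]] / (p@growth[["K_lac"]] + init[["Lac"]])) *
    (p@growth[["KI_lac"]] / (p@growth[["KI_lac"]] + init[["Lac"]])) *
    (init[["Glc"]] / (p@growth[["K_glc"]] + init[["Glc"]])) *
    (init[["Asn"]] / (p@growth[["K_asn"]] + init[["Asn"]])) *
    (init[["Glu"]] / (p@growth[["K_glu"]] + init[["Glu"]]))
  expected <- init[["Xv"]] * exp(muEff * 24)
  expect_equal(unname(tr@states[2, "Xv"]), unname(expected),
               tolerance = 1e-3)
})

test_that("dead cells never outnumber total cells along default runs", {
  sims <- cachedSims()
  for (tr in list(sims$tr36, sims$trShift)) {
    expect_true(all(tr@states[, "Xt"] >= tr@states[, "Xv"] - 1e-6))
  }
})

test_that("fast integrator RHS matches the reference module functions", {
  sims <- cachedSims()
  p36 <- sims$p36
  rhs <- hypothermAb:::.makeRHS(p36, c("culture", "mab", "intracellular"))
  y <- sims$trShift@states[8, ]
  d <- rhs(0, y, NULL)[[1]]
  # reference composition
  mabP <- p36@mab
  qm <- mabP[["K_G"]] * y[["GolgiMab"]] / hypothermAb:::.NA_PER_MMOL *
    mabP[["MW"]]
  dc <- cultureRHS(y[hypothermAb:::.STATE_CULTURE], p36, q_mAb = qm)
  rates <- attr(dc, "rates")
  dm <- mabRHS(y[hypothermAb:::.STATE_MAB], rates[["mu"]], mabP)
  qq <- metaboliteRates(y[hypothermAb:::.STATE_CULTURE], rates[["mu"]],
                        p36@metabolism, q_mAb = qm, MW = mabP[["MW"]])
  di <- intracellularRHS(y[hypothermAb:::.STATE_INTRA], qq[["Glc"]],
                         qq[["Gln"]], qm, rates[["mu"]], p36@nsd,
                         mabP[["MW"]])
  ref <- c(as.numeric(dc), as.numeric(dm), as.numeric(di))
  expect_equal(d, ref, tolerance = 1e-12)
})

test_that("culture RHS is consistent with integrator finite differences", {
  sims <- cachedSims()
  tr <- sims$tr36
  des <- tr@design
  # short free interval (no events) starting at 30 h
  p36 <- sims$p36
  y0 <- tr@states[2, ]  # state at 24 h (post any event)
  rhs <- hypothermAb:::.makeRHS(p36, c("culture", "mab", "intracellular"))
  h <- 1e-3
  sol <- deSolve::lsoda(y0, c(0, h), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  fd <- (sol[2, -1] - y0) / h
  d <- rhs(0, y0, NULL)[[1]]
  big <- abs(d) > 1e-6
  expect_lt(max(abs(fd[big] - d[big]) / abs(d[big])), 1e-2)
})
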