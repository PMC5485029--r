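p36 <- defaultParameters("36.5C")
p32 <- defaultParameters("32C")
nd <- p36@nsd

intra0 <- setNames(numeric(length(hypothermAb:::.STATE_INTRA)),
                   hypothermAb:::.STATE_INTRA)

test_that("all synthesis rates vanish without substrates", {
  expect_true(all(nucleotideRates(intra0, nd) == 0))
  expect_true(all(nsdRates(intra0, nd) == 0))
})

test_that("every Michaelis-Menten rate respects half-saturation and its V_max", {
  # saturating limit: r -> 1000 * V_max (uM h^-1)
  sat <- intra0 + 1e15
  rn <- nucleotideRates(sat, nd)
  expect_equal(unname(rn[["r_3f"]]), 1000 * 23.71, tolerance = 1e-6)
  rs <- nsdRates(sat, nd)
  # product-inhibited rates do not reach V_max at saturating product; the
  # plain ones do
  expect_equal(unname(rs[["UDPGal"]]), 1000 * nd[["V_max_UDPGal"]],
               tolerance = 1e-6)
  s <- sat; s["CMPNeu5Ac"] <- 0; s["GDPFuc"] <- 0
  rs2 <- nsdRates(s, nd)
  expect_equal(unname(rs2[["UDPGlcNAc"]]),
               1000 * nd[["V_max_UDPGlcNAc"]], tolerance = 1e-6)
  # half-saturation: single-substrate rate at its K is V_max/2
  s <- intra0 + 1e15
  s["UDPGlc"] <- nd[["K_UDPGal_UDPGlc"]]
  expect_equal(unname(nsdRates(s, nd)[["UDPGal"]]),
               1000 * nd[["V_max_UDPGal"]] / 2, tolerance = 1e-9)
  # product of two half-saturations gives V_max/4
  s <- intra0
  s["Glc_int"] <- nd[["K_4_glc"]]; s["Gln_int"] <- nd[["K_4_gln"]]
  expect_equal(unname(nucleotideRates(s, nd)[["r_4"]]),
               1000 * nd[["V_max_4"]] / 4, tolerance = 1e-9)
  # rates never exceed V_max over random states
  set.seed(7)
  for (i in 1:50) {
    s <- intra0 + stats::runif(length(intra0), 0, 1e6)
    expect_true(all(nucleotideRates(s, nd) <=
                      1000 * nd[paste0("V_max_", c("1a", "1b", "2f", "2b",
                                                   "3f", "3b", "4", "5"))]
                    + 1e-9))
  }
})

test_that("product inhibition halves the sialylation rate at Ki", {
  s <- intra0 + 1e15
  s["CMPNeu5Ac"] <- 0
  r0 <- nsdRates(s, nd)[["CMPNeu5Ac"]]
  s["CMPNeu5Ac"] <- nd[["Ki_CMPNeu5Ac"]]
  expect_equal(unname(nsdRates(s, nd)[["CMPNeu5Ac"]]), unname(r0 / 2),
               tolerance = 1e-9)
})

test_that("transport demand follows growth/productivity and saturates", {
  s <- intra0 + 1e3
  expect_true(all(nsdTransportDemand(s, 0, 0, nd) == 0))
  # far above K_TP the flux equals the bracketed demand
  sat <- intra0 + 1e12
  Fo <- nsdTransportDemand(sat, 0.05, 0, nd)
  hostExp <- 0.05 * nd[["N_glyc_cell"]] / nd[["V_cell"]] *
    nd[["N_glyc_UDPGal"]] * 1000
  expect_equal(unname(Fo[["UDPGal"]]), hostExp, tolerance = 1e-6)
  # CMP-Neu5Ac transport is inhibited by UDP-GlcNAc, monotonically
  s1 <- intra0 + 500
  s2 <- s1; s2["UDPGlcNAc"] <- 2 * s1[["UDPGlcNAc"]]
  f1 <- nsdTransportDemand(s1, 0.05, 1e-9, nd)[["CMPNeu5Ac"]]
  f2 <- nsdTransportDemand(s2, 0.05, 1e-9, nd)[["CMPNeu5Ac"]]
  expect_lt(f2, f1)
  # UDP-GalNAc and CMP-Neu5Ac carry no product-glycosylation term
  fNoMab <- nsdTransportDemand(s1, 0.05, 0, nd)
  fMab <- nsdTransportDemand(s1, 0.05, 1e-8, nd)
  expect_equal(fMab[["UDPGalNAc"]], fNoMab[["UDPGalNAc"]])
  expect_gt(fMab[["UDPGlcNAc"]], fNoMab[["UDPGlcNAc"]])
})

test_that("zero inputs freeze the intracellular state", {
  d <- intracellularRHS(intra0, 0, 0, 0, 0, nd)
  expect_true(all(as.numeric(d) == 0))
})

test_that("adenylate pool changes only through de novo synthesis and dilution", {
  # closed configuration: no de novo input, no growth -> ATP+ADP+AMP constant
  p <- nd
  p["V_max_1a"] <- 0
  y0 <- intra0
  y0[c("ATP", "ADP", "AMP")] <- c(600, 150, 30)
  y0["Glc_int"] <- 1500
  rhs <- function(t, y, parms)
    list(as.numeric(intracellularRHS(y, 0, 0, 0, 0, p)))
  names(y0) <- hypothermAb:::.STATE_INTRA
  sol <- deSolve::lsoda(y0, c(0, 50), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-10)
  tot0 <- sum(y0[c("ATP", "ADP", "AMP")])
  tot1 <- sum(sol[2, c("ATP", "ADP", "AMP")])
  expect_equal(tot1, tot0, tolerance = 1e-8)
})

test_that("UDP-Gal mass balance closes over the forced module", {
  sims <- cachedSims()
  fc <- cultureForcings(sims$tr36)
  y0 <- defaultDesign()@initialState[hypothermAb:::.STATE_INTRA]
  times <- seq(0, 240, by = 4)
  m <- simulateIntracellular(fc, p36, times, y0 = y0,
                             rtol = 1e-10, atol = 1e-12)
  # integrate the component fluxes along the solution (trapezoid) and
  # compare with the pool change
  flux <- vapply(seq_along(times), function(i) {
    mu <- stats::approx(fc$time_h, fc$mu, times[i], rule = 2)$y
    qm <- stats::approx(fc$time_h, fc$q_mAb, times[i], rule = 2)$y
    d <- intracellularRHS(m[i, ], 0, 0, qm, mu, nd)
    rs <- attr(d, "r_nsd"); Fo <- attr(d, "F_out")
    rs[["UDPGal"]] - Fo[["UDPGal"]] - mu * m[i, "UDPGal"]
  }, numeric(1))
  # trapezoid the fluxes over 48-240 h (the first hours hold a fast
  # equilibration transient the 4 h grid cannot resolve)
  win <- which(times >= 48)
  fw <- flux[win]; tw <- times[win]
  net <- sum((fw[-1] + fw[-length(fw)]) / 2 * diff(tw))
  expect_equal(unname(m[max(win), "UDPGal"] - m[min(win), "UDPGal"]),
               net, tolerance = 1e-2)
})

test_that("every NSD synthesis maximum rate is lower under mild hypothermia", {
  nsdV <- paste0("nsd.V_max_", c("UDPGlc", "UDPGal", "UDPGlcNAc",
                                 "UDPGalNAc", "GDPMan", "GDPFuc"))
  expect_true(all(getParam(p32, nsdV) < getParam(p36, nsdV)))
})

test_that("key NSD pools are depressed after the shift relative to control", {
  sims <- cachedSims()
  late <- sims$tr36@times >= 200
  for (sp in c("UDPGlcNAc", "UDPGal")) {
    expect_true(all(sims$tr36@states[late, sp] >
                      sims$trShift@states[late, sp]))
  }
})
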