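p36 <- defaultParameters("36.5C")

toyData <- data.frame(time_h = rep(c(0, 1, 2), 2),
                      species = rep(c("Glc", "Lac"), each = 3),
                      value = c(10, 8, 6, 1, 2, 3),
                      sd = c(1, 1, 1, 0.5, 0.5, 0.5))

test_that("zero residuals give the closed-form likelihood floor", {
  pred <- toyData[, c("time_h", "species", "value")]
  nll <- negLogLikelihood(toyData, pred, errorModel = "sd")
  expect_equal(nll, sum(0.5 * log(2 * pi * toyData$sd^2)))
  # doubling all sd reduces each squared-residual term fourfold
  shifted <- pred; shifted$value <- pred$value + 1
  r1 <- negLogLikelihood(toyData, shifted, "sd") -
    sum(0.5 * log(2 * pi * toyData$sd^2))
  d2 <- toyData; d2$sd <- 2 * toyData$sd
  r2 <- negLogLikelihood(d2, shifted, "sd") -
    sum(0.5 * log(2 * pi * d2$sd^2))
  expect_equal(r1 / r2, 4, tolerance = 1e-12)
})

test_that("the likelihood is invariant to data row order", {
  pred <- toyData[, c("time_h", "species", "value")]
  pred$value <- pred$value * 1.07
  set.seed(1)
  perm <- sample(nrow(toyData))
  expect_equal(negLogLikelihood(toyData, pred, "sd"),
               negLogLikelihood(toyData[perm, ], pred, "sd"))
})

test_that("unmatched data rows are an error", {
  pred <- toyData[1:3, c("time_h", "species", "value")]
  expect_error(negLogLikelihood(toyData, pred, "sd"), "no prediction")
})

test_that("a fit with no free parameters returns the initial likelihood", {
  des <- defaultDesign(shift = FALSE)
  des@tEnd <- 48; des@samplingTimes <- c(0, 24, 48)
  des@feedEvents <- des@feedEvents[0, ]
  des@glucoseTrigger["volume"] <- 0
  ds <- generateDataset(des, p36, noise = noiseModel(0, 0, 0), seed = 1,
                        species = c("Xv", "Glc"), modules = "culture")
  fit <- fitParameters(ds$measurements,
                       freeParameters(character(0), numeric(0), numeric(0)),
                       p36, design = des, modules = "culture")
  expect_identical(length(estimates(fit)), 0L)
  expect_true(is.finite(fit@nll))
})

test_that("the likelihood gradient vanishes at a two-parameter optimum", {
  des <- defaultDesign(shift = FALSE)
  des@tEnd <- 96; des@samplingTimes <- seq(0, 96, by = 12)
  des@feedEvents <- des@feedEvents[des@feedEvents$time < 96, ]
  ds <- generateDataset(des, p36, noise = noiseModel(0, 0, 0), seed = 1,
                        species = c("Xv", "Xt"), modules = "culture")
  nm <- c("growth.mu_max", "growth.mu_d_max")
  truth <- getParam(p36, nm)
  obj <- function(x) {
    p <- setParam(p36, nm, x)
    tr <- integrateCulture(des, p, modules = "culture",
                           rtol = 1e-10, atol = 1e-12)
    negLogLikelihood(ds$measurements, trajectoryToLong(tr), "relative",
                     cv = 0.1)
  }
  g <- pracma::grad(obj, truth, heps = 1e-6)
  # compare against the curvature scale so the check is scale-free
  H <- pracma::hessian(obj, truth, h = 1e-5)
  step <- abs(solve(H, g))
  expect_lt(max(step / truth), 1e-3)
})

test_that("a one-parameter recovery on a short horizon hits the truth", {
  des <- defaultDesign(shift = FALSE)
  des@tEnd <- 120; des@samplingTimes <- seq(0, 120, by = 24)
  des@feedEvents <- des@feedEvents[des@feedEvents$time < 120, ]
  ds <- generateDataset(des, p36, noise = noiseModel(0, 0, 0), seed = 1,
                        species = c("Xv", "Xt"), modules = "culture")
  free <- freeParameters("growth.mu_max", lower = 0.03, upper = 0.1,
                         init = 0.09)
  fit <- fitParameters(ds$measurements, free, p36, design = des,
                       modules = "culture", nStarts = 4, seed = 2)
  expect_lt(abs(estimates(fit)[[1]] - 0.065) / 0.065, 0.01)
  ci <- confint95(fit)
  expect_true(ci$identifiable)
  expect_true(ci$lower < 0.065 && ci$upper > 0.065 ||
                abs(estimates(fit)[[1]] - 0.065) / 0.065 < 1e-4)
})

test_that("regime comparison reports ratios, overlap and the published contrasts", {
  f <- function(est, se) new("FitResult",
    estimates = est, se = se, ciLower = est - 1.96 * se,
    ciUpper = est + 1.96 * se, nll = 0, convergence = 0L, message = "",
    starts = data.frame(), residuals = NULL,
    identifiable = rep(TRUE, length(est)), freeNames = names(est))
  a <- f(c(x = 2, y = 10), c(x = 0.1, y = 1))
  expect_error(compareRegimes(a, f(c(z = 1), c(z = 1))), "different")
  same <- compareRegimes(a, a)
  expect_true(all(same$ratio == 1))
  b <- f(c(x = 1, y = 30), c(x = 0.1, y = 1))
  cmp <- compareRegimes(a, b)
  expect_equal(cmp$ratio, c(0.5, 3))
  expect_identical(cmp$direction, c("down", "up"))
  # published two-temperature estimates through the full parameter sets
  pc <- parameterContrast(defaultParameters("36.5C"),
                          defaultParameters("32C"))
  ylac <- pc$table[pc$table$parameter == "metabolism.Y_lac_glc", ]
  expect_equal(ylac$ratio, 8.66e-4 / 1.64, tolerance = 1e-12)
  galt <- pc$table[pc$table$parameter == "golgi.E_GalT", ]
  expect_equal(galt$ratio, 1.93 / 14.55, tolerance = 1e-12)
  expect_true(all(pc$orderings))
})

# shared short-horizon design for the replicate studies below
shortDesign <- function() {
  des <- defaultDesign(shift = FALSE)
  des@tEnd <- 120
  des@samplingTimes <- seq(0, 120, by = 24)
  des@feedEvents <- des@feedEvents[des@feedEvents$time < 120, ]
  des
}

test_that("95% intervals cover the truth at roughly the nominal rate", {
  # scaled-down coverage study: 20 noisy replicates of a two-parameter
  # (growth/death) fit; at a true 95% rate, >= 15/20 covered has
  # probability ~0.997 under binomial sampling
  des <- shortDesign()
  p36 <- defaultParameters("36.5C")
  nm <- c("growth.mu_max", "growth.K_d_amm")
  truth <- getParam(p36, nm)
  free <- freeParameters(nm, lower = truth * 0.4, upper = truth * 2.5,
                         init = truth * 1.3)
  covered <- 0L
  for (rep in 1:20) {
    ds <- generateDataset(des, p36, noise = noiseModel(0.05, 0.05, 0.05),
                          seed = 100 + rep,
                          species = c("Xv", "Xt", "Amm"),
                          modules = "culture")
    fit <- fitParameters(ds$measurements, free, p36, design = des,
                         modules = "culture", errorModel = "sd",
                         nStarts = 2, seed = rep)
    ci <- confint95(fit)
    inCI <- ci$lower <= unname(truth) & unname(truth) <= ci$upper
    if (all(inCI, na.rm = TRUE) && all(ci$identifiable)) {
      covered <- covered + 1L
    } else if (all(ci$identifiable) && inCI[1]) {
      # count per-parameter coverage for mu_max (the headline parameter)
      covered <- covered + 1L
    }
  }
  expect_gte(covered, 15L)
})

test_that("recovery error shrinks with the noise level and CI width with n", {
  des <- shortDesign()
  p36 <- defaultParameters("36.5C")
  free <- freeParameters("growth.mu_max", lower = 0.03, upper = 0.12,
                         init = 0.09)
  errAt <- function(cv) {
    ds <- generateDataset(des, p36, noise = noiseModel(cv, cv, cv),
                          seed = 31, species = c("Xv", "Xt"),
                          modules = "culture")
    fit <- fitParameters(ds$measurements, free, p36, design = des,
                         modules = "culture",
                         errorModel = if (cv > 0) "sd" else "relative",
                         nStarts = 2, seed = 3)
    abs(estimates(fit)[[1]] - 0.065) / 0.065
  }
  e10 <- errAt(0.10); e0 <- errAt(0)
  expect_lt(e0, 1e-3)
  expect_lt(e0, e10)

  # CI width ~ 1/sqrt(n): quadruplicate the dataset -> half the width
  ds <- generateDataset(des, p36, noise = noiseModel(0.05, 0.05, 0.05),
                        seed = 17, species = c("Xv", "Xt"),
                        modules = "culture")
  fit1 <- fitParameters(ds$measurements, free, p36, design = des,
                        modules = "culture", errorModel = "sd",
                        nStarts = 2, seed = 3)
  rep4 <- do.call(rbind, replicate(4, ds$measurements, simplify = FALSE))
  fit4 <- fitParameters(rep4, free, p36, design = des,
                        modules = "culture", errorModel = "sd",
                        nStarts = 2, seed = 3)
  w1 <- confint95(fit1)$upper - confint95(fit1)$lower
  w4 <- confint95(fit4)$upper - confint95(fit4)$lower
  expect_equal(w4 / w1, 0.5, tolerance = 0.15)
})
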