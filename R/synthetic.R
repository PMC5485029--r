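# Synthetic fed-batch dataset generator. All quantitative choices here are
# synthetic defaults emulating a 14-day, 5 L fed-batch campaign with a
# day-6 shift to mild hypothermia; none are measured values.

#' Default fed-batch experiment design (synthetic)
#'
#' A 336 h (14-day) run with daily sampling, temperature shift at 144 h
#' (day 6), nutrient-feed boluses every 48 h from 72 h, and an on-demand
#' glucose bolus triggered when extracellular glucose falls below 20 mM at
#' a daily check. Initial conditions and the feed composition are synthetic
#' defaults chosen to land trajectories in physiological fed-batch ranges;
#' the feed composition emulates a concentrated commercial nutrient feed.
#'
#' @param shift logical: include the 144 h temperature shift.
#' @return an [ExperimentDesign-class].
#' @examples
#' design <- defaultDesign()
#' design@shiftTime
#' @export
defaultDesign <- function(shift = TRUE) {
  init <- c(
    Xv = 3e8, Xt = 3e8,
    Glc = 40, Lac = 1.0, Amm = 0.5,
    Asn = 10, Asp = 4, Arg = 4, Glu = 4, Gln = 6, Lys = 4, Pro = 4,
    mAb = 0,
    mRNA_H = 0, mRNA_L = 0, HC = 0, LC = 0, H2 = 0, H2L = 0, H2L2 = 0,
    GolgiMab = 0,
    Glc_int = 1500, Gln_int = 1000,
    ATP = 600, ADP = 150, AMP = 30,
    GTP = 500, UTP = 800, CTP = 300,
    UDPGlc = 800, UDPGal = 0.5, UDPGlcNAc = 500, UDPGalNAc = 30,
    GDPMan = 20, GDPFuc = 100, CMPNeu5Ac = 50)
  feedC <- c(Glc = 100, Asn = 80, Asp = 15, Arg = 20, Glu = 30,
             Lys = 20, Pro = 25)
  new("ExperimentDesign",
      tEnd = 336,
      shiftTime = if (shift) 144 else NA_real_,
      feedEvents = data.frame(time = seq(72, 312, by = 48),
                              feed_id = "feedC", volume = 0.14),
      feedCompositions = list(feedC = feedC),
      glucoseFeeds = data.frame(time = numeric(), volume = numeric(),
                                conc = numeric()),
      glucoseTrigger = c(threshold = 20, volume = 0.03, conc = 2500,
                         checkEvery = 24),
      samplingTimes = seq(0, 336, by = 24),
      initialState = init,
      initialVolume = 3.5)
}

#' Construct a measurement noise model
#'
#' @param cvExtracellular CV of extracellular species, cells and titer
#'   (default 0.10).
#' @param cvIntracellular CV of intracellular species (default 0.15).
#' @param cvGlycoform CV of glycoform fractions (default 0.15).
#' @param cvOverride optional named numeric of per-species CVs.
#' @return a [NoiseModel-class].
#' @export
noiseModel <- function(cvExtracellular = 0.10, cvIntracellular = 0.15,
                       cvGlycoform = 0.15, cvOverride = numeric()) {
  new("NoiseModel", cvExtracellular = cvExtracellular,
      cvIntracellular = cvIntracellular, cvGlycoform = cvGlycoform,
      cvOverride = cvOverride)
}

#' CV applicable to a species under a noise model
#'
#' @param noise a [NoiseModel-class].
#' @param species character vector of species names.
#' @return numeric CVs.
#' @export
speciesCV <- function(noise, species) {
  cls <- ifelse(species %in% .STATE_INTRA, "intra",
                ifelse(startsWith(species, "glyco_"), "glyco", "extra"))
  cv <- ifelse(cls == "intra", noise@cvIntracellular,
               ifelse(cls == "glyco", noise@cvGlycoform,
                      noise@cvExtracellular))
  if (length(noise@cvOverride)) {
    hit <- species %in% names(noise@cvOverride)
    cv[hit] <- noise@cvOverride[species[hit]]
  }
  cv
}

# mean-one multiplicative log-normal factors for a target CV
.lnormFactor <- function(n, cv) {
  if (all(cv == 0)) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate a synthetic fed-batch dataset
#'
#' Simulates the model under a design and ground-truth parameter set(s),
#' samples the requested species at the sampling times, and applies
#' mean-one multiplicative log-normal noise. With \code{cv = 0} the
#' measurements equal the simulated truth exactly; measurements are
#' non-negative at any CV. Reproducible for a fixed seed.
#'
#' @param design an [ExperimentDesign-class].
#' @param params ground-truth pre-shift [ParameterSet-class].
#' @param paramsPost post-shift truth (required if the design shifts).
#' @param noise a [NoiseModel-class].
#' @param seed integer seed.
#' @param species species to report (default: a standard measured panel of
#'   cells, metabolites, titer, antibody intermediates and intracellular
#'   pools).
#' @param modules modules to simulate (passed to [integrateCulture()]).
#' @param glycoformDays if non-NULL, also report cumulative glycoform
#'   fractions (species \code{glyco_*}) at these culture days.
#' @return list with elements \code{measurements} (long data.frame with sd
#'   column = cv * truth), \code{truth} (noiseless long table),
#'   \code{trajectory}, \code{design}, \code{params}, \code{paramsPost}.
#' @export
generateDataset <- function(design, params, paramsPost = NULL,
                            noise = noiseModel(), seed = 1,
                            species = NULL,
                            modules = c("culture", "mab", "intracellular"),
                            glycoformDays = NULL) {
  tr <- integrateCulture(design, params, paramsPost, modules = modules)
  if (is.null(species)) {
    species <- intersect(
      c("Xv", "Xt", "Glc", "Lac", "Amm", .AMINO_ACIDS, "mAb",
        "mRNA_H", "mRNA_L", "H2", "H2L",
        .STATE_INTRA),
      colnames(tr@states))
  }
  truth <- trajectoryToLong(tr, species)
  if (!is.null(glycoformDays)) {
    gf <- cumulativeGlycoforms(tr, params, paramsPost, days = glycoformDays)
    truth <- rbind(truth,
                   data.frame(time_h = gf$day * 24,
                              species = paste0("glyco_", gf$glycoform),
                              value = gf$fraction, sd = NA_real_))
  }
  set.seed(seed)
  cv <- speciesCV(noise, truth$species)
  meas <- truth
  meas$value <- truth$value * .lnormFactor(nrow(truth), cv)
  meas$sd <- cv * truth$value
  list(measurements = meas, truth = truth, trajectory = tr,
       design = design, params = params, paramsPost = paramsPost)
}
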