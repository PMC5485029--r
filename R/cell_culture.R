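# Cell growth, death, lysis and metabolite kinetics.
#
# Sign convention: specific rates q are net production into the medium
# (positive = production), so the extracellular balance is
# d(V[met])/dt = q_met * Xv * V + feed terms.

#' Specific growth rate (Monod kinetics with waste inhibition)
#'
#' \eqn{\mu = \mu_{max} f_{lim} f_{inh}} where the limitation factor is the
#' product of four Monod terms (glucose, lactate, asparagine, glutamate) and
#' the inhibition factor the product of ammonia and lactate inhibition
#' terms. Lactate appears in both: it is consumed as a secondary carbon
#' source late in culture (limitation) and inhibits at high concentration.
#' The lactate limitation term implies \eqn{\mu = 0} at exactly zero
#' lactate, an acknowledged structural artefact of the published form that
#' is kept verbatim.
#'
#' @param state named numeric with at least Glc, Lac, Asn, Glu, Amm (mM).
#' @param p growth parameter vector (see [defaultParameters()]).
#' @return specific growth rate, h^-1, in \[0, mu_max\].
#' @export
specificGrowthRate <- function(state, p) {
  s <- pmax(state, 0)
  flim <- .sat(s[["Glc"]], p[["K_glc"]]) *
    .sat(s[["Lac"]], p[["K_lac"]]) *
    .sat(s[["Asn"]], p[["K_asn"]]) *
    .sat(s[["Glu"]], p[["K_glu"]])
  finh <- (p[["KI_amm"]] / (p[["KI_amm"]] + s[["Amm"]])) *
    (p[["KI_lac"]] / (p[["KI_lac"]] + s[["Lac"]]))
  p[["mu_max"]] * flim * finh
}

#' Specific death rate driven by ammonia
#'
#' \eqn{\mu_d = \mu_{d,max} / (1 + K_{d,amm}/[Amm])}: zero without ammonia,
#' monotone increasing, saturating at \eqn{\mu_{d,max}}.
#'
#' @param amm extracellular ammonia (mM).
#' @param p growth parameter vector.
#' @return specific death rate, h^-1.
#' @export
specificDeathRate <- function(amm, p) {
  amm <- max(amm, 0)
  if (amm == 0) return(0)
  p[["mu_d_max"]] / (1 + p[["K_d_amm"]] / amm)
}

#' Specific metabolite production/consumption rates
#'
#' Computes the net specific rate (mmol cell^-1 h^-1; positive =
#' production) for glucose, lactate, ammonia and the seven tracked amino
#' acids. Glucose: growth demand plus maintenance. Lactate: production
#' stoichiometric to glycolytic flux minus a saturable consumption term
#' active once lactate has accumulated. Amino acids: growth demand,
#' maintenance and antibody incorporation, with asparagine/glutamine/
#' arginine deamination feeding ammonia.
#'
#' @param state named numeric culture state (mM / cells L^-1).
#' @param mu specific growth rate (h^-1).
#' @param p metabolism parameter vector.
#' @param q_mAb specific antibody productivity (mg cell^-1 h^-1).
#' @param MW antibody molecular weight (g mol^-1 = mg mmol^-1).
#' @return named numeric of specific rates for
#'   Glc, Lac, Amm, Asn, Asp, Arg, Glu, Gln, Lys, Pro.
#' @export
metaboliteRates <- function(state, mu, p, q_mAb = 0, MW = 1.5e5) {
  s <- pmax(state, 0)
  q_mab_mmol <- q_mAb / MW
  q_glc <- -mu / p[["Y_xv_glc"]] - p[["m_glc"]]
  lac <- s[["Lac"]]
  q_lac <- -q_glc * p[["Y_lac_glc"]] -
    (mu / p[["Y_xv_lac"]] + p[["k_T_lac"]] * lac) * lac / (lac + .K_LAC_MOD)
  q_aa <- vapply(.AMINO_ACIDS, function(a) {
    al <- tolower(a)
    -mu / p[[paste0("Y_xv_", al)]] - p[[paste0("m_", al)]] -
      p[[paste0("nu_", al)]] * q_mab_mmol
  }, numeric(1))
  names(q_aa) <- .AMINO_ACIDS
  # asparagine deamination produces aspartate and ammonia
  q_aa[["Asp"]] <- q_aa[["Asp"]] + (-q_aa[["Asn"]]) * p[["Y_asp_asn"]]
  q_amm <- -q_aa[["Gln"]] - q_aa[["Asn"]] * p[["Y_asp_asn"]] - q_aa[["Arg"]] +
    mu / p[["Y_xv_amm"]]
  c(Glc = q_glc, Lac = unname(q_lac), Amm = unname(q_amm), q_aa)
}

# Monod constant of the lactate production/consumption modulator (mM).
# Matches the growth-limitation K_lac default; kept as a package constant so
# metaboliteRates() needs only the metabolism parameter block.
.K_LAC_MOD <- 0.5

#' Culture right-hand side (material balances)
#'
#' Time derivatives of volume, viable/total cells and extracellular species
#' between feed events (bolus feeds are applied as instantaneous events by
#' the integrator, so no F_in terms appear here; F_out = 0).
#'
#' @param state named culture state.
#' @param p parameter set ([ParameterSet-class]).
#' @param q_mAb specific productivity (mg cell^-1 h^-1) fed in from the
#'   antibody module (0 when that module is inactive).
#' @return named numeric of derivatives for the culture states.
#' @export
cultureRHS <- function(state, p, q_mAb = 0) {
  g <- p@growth
  m <- p@metabolism
  s <- pmax(state, 0)
  mu <- specificGrowthRate(s, g)
  mud <- specificDeathRate(s[["Amm"]], g)
  q <- metaboliteRates(s, mu, m, q_mAb = q_mAb, MW = p@mab[["MW"]])
  Xv <- s[["Xv"]]
  d <- c(V = 0,
         Xv = (mu - mud) * Xv,
         Xt = mu * Xv - g[["K_lysis"]] * (s[["Xt"]] - Xv),
         q[c("Glc", "Lac", "Amm", .AMINO_ACIDS)] * Xv,
         mAb = q_mAb * Xv)
  names(d) <- .STATE_CULTURE
  attr(d, "rates") <- c(mu = mu, mud = mud,
                        q_glc = q[["Glc"]], q_lac = q[["Lac"]],
                        q_amm = q[["Amm"]])
  d
}
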