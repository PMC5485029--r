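# De novo nucleotide synthesis, nucleotide sugar donor (NSD) synthesis and
# Golgi transport demand. Intracellular concentrations are uM; maximum
# rates V_max are carried in mmol L_cell^-1 h^-1 (= mM h^-1) and converted
# once here. Many V_max/K pairs are only identifiable through their ratio;
# the reconstructed saturation constants place rates on physiological
# scales (methods vignette).

#' De novo nucleotide synthesis and interconversion rates
#'
#' Michaelis-Menten saturation kinetics over a semi-structured purine /
#' pyrimidine network: r_1a (de novo -> AMP), r_1b (de novo -> GTP),
#' r_2f (ATP -> AMP), r_2b (ADP -> AMP), r_3f (ADP -> ATP),
#' r_3b (ATP -> ADP), r_4 (de novo -> UTP), r_5 (UTP -> CTP). De novo
#' reactions draw on intracellular glucose and glutamine; glutamate and
#' asparagine as nitrogen donors are assumed non-limiting.
#'
#' @param state named intracellular state (uM).
#' @param p nsd parameter vector.
#' @return named rates (uM h^-1), each bounded by 1000 * V_max.
#' @export
nucleotideRates <- function(state, p) {
  s <- pmax(state, 0)
  U <- .UM_PER_MM
  c(r_1a = U * p[["V_max_1a"]] * .sat(s[["Glc_int"]], p[["K_1a_glc"]]) *
      .sat(s[["Gln_int"]], p[["K_1a_gln"]]),
    r_1b = U * p[["V_max_1b"]] * .sat(s[["Glc_int"]], p[["K_1b_glc"]]) *
      .sat(s[["Gln_int"]], p[["K_1b_gln"]]),
    r_2f = U * p[["V_max_2f"]] * .sat(s[["ADP"]], p[["K_2f_adp"]]),
    r_2b = U * p[["V_max_2b"]] * .sat(s[["AMP"]], p[["K_2b_amp"]]),
    r_3f = U * p[["V_max_3f"]] * .sat(s[["ADP"]], p[["K_3f_adp"]]) *
      .sat(s[["Glc_int"]], p[["K_3f_glc"]]),
    r_3b = U * p[["V_max_3b"]] * .sat(s[["ATP"]], p[["K_3b_atp"]]),
    r_4 = U * p[["V_max_4"]] * .sat(s[["Glc_int"]], p[["K_4_glc"]]) *
      .sat(s[["Gln_int"]], p[["K_4_gln"]]),
    r_5 = U * p[["V_max_5"]] * .sat(s[["UTP"]], p[["K_5_utp"]]) *
      .sat(s[["Gln_int"]], p[["K_5_gln"]]))
}

#' NSD synthesis rates
#'
#' Saturation kinetics in the precursor pools: UDP-GlcNAc from intracellular
#' glucose, glutamine and UTP; UDP-Glc from glucose and UTP; GDP-Man from
#' glucose and GTP; UDP-GalNAc from UDP-GlcNAc; CMP-Neu5Ac from UDP-GlcNAc
#' and glutamine with competitive product inhibition (K_i,CMPNeu5Ac);
#' UDP-Gal from UDP-Glc; GDP-Fuc from GDP-Man with non-competitive product
#' inhibition (K_i,GDPFuc).
#'
#' @inheritParams nucleotideRates
#' @return named rates (uM h^-1) for the seven NSD species.
#' @export
nsdRates <- function(state, p) {
  s <- pmax(state, 0)
  U <- .UM_PER_MM
  c(UDPGlcNAc = U * p[["V_max_UDPGlcNAc"]] *
      .sat(s[["Glc_int"]], p[["K_UDPGlcNAc_glc"]]) *
      .sat(s[["Gln_int"]], p[["K_UDPGlcNAc_gln"]]) *
      .sat(s[["UTP"]], p[["K_UDPGlcNAc_utp"]]),
    UDPGlc = U * p[["V_max_UDPGlc"]] *
      .sat(s[["Glc_int"]], p[["K_UDPGlc_glc"]]) *
      .sat(s[["UTP"]], p[["K_UDPGlc_utp"]]),
    GDPMan = U * p[["V_max_GDPMan"]] *
      .sat(s[["Glc_int"]], p[["K_GDPMan_glc"]]) *
      .sat(s[["GTP"]], p[["K_GDPMan_gtp"]]),
    UDPGalNAc = U * p[["V_max_UDPGalNAc"]] *
      .sat(s[["UDPGlcNAc"]], p[["K_UDPGalNAc_UDPGlcNAc"]]),
    CMPNeu5Ac = U * p[["V_max_CMPNeu5Ac"]] *
      .sat(s[["UDPGlcNAc"]], p[["K_CMPNeu5Ac_UDPGlcNAc"]]) *
      .sat(s[["Gln_int"]], p[["K_CMPNeu5Ac_gln"]]) /
      (1 + s[["CMPNeu5Ac"]] / p[["Ki_CMPNeu5Ac"]]),
    UDPGal = U * p[["V_max_UDPGal"]] *
      .sat(s[["UDPGlc"]], p[["K_UDPGal_UDPGlc"]]),
    GDPFuc = U * p[["V_max_GDPFuc"]] *
      .sat(s[["GDPMan"]], p[["K_GDPFuc_GDPMan"]]) *
      p[["Ki_GDPFuc"]] / (p[["Ki_GDPFuc"]] + s[["GDPFuc"]]))
}

#' NSD transport demand into the Golgi
#'
#' Transport of each NSD out of the cytosol, saturable in the NSD
#' concentration (transporter constant K_TP) and limited by the
#' glycosylation demand: host-cell protein glycosylation proportional to
#' growth (mu * N_glyc,cell * N_NSD,glyc / V_cell) and, for the five NSDs
#' consumed on the antibody Fc glycan, product glycosylation proportional
#' to specific productivity (q_mAb/MW * N_glyc,mAb * N_NSD,mAb / V_cell).
#' UDP-GalNAc and CMP-Neu5Ac serve host glycans only, and CMP-Neu5Ac
#' transport is competitively inhibited by UDP-GlcNAc.
#'
#' @param state named intracellular state (uM).
#' @param mu specific growth rate (h^-1).
#' @param q_mAb specific productivity (mg cell^-1 h^-1).
#' @param p nsd parameter vector.
#' @param MW antibody molecular weight (mg mmol^-1).
#' @return named transport rates (uM h^-1) per NSD species.
#' @export
nsdTransportDemand <- function(state, mu, q_mAb, p, MW = 1.5e5) {
  s <- pmax(state, 0)
  U <- .UM_PER_MM
  host <- mu * p[["N_glyc_cell"]] / p[["V_cell"]]          # mmol L^-1 h^-1 per N
  mabd <- (q_mAb / MW) * p[["N_glyc_mAb"]] / p[["V_cell"]]
  out <- vapply(.NSD_SPECIES, function(sp) {
    demand <- host * p[[paste0("N_glyc_", sp)]]
    if (sp %in% .NSD_MAB_TRANSPORT)
      demand <- demand + mabd * p[[paste0("N_mab_", sp)]]
    f <- .sat(s[[sp]], p[[paste0("K_TP_", sp)]]) * U * demand
    if (sp == "CMPNeu5Ac")
      f <- f / (1 + s[["UDPGlcNAc"]] / p[["Ki_CMPNeu5Ac_UDPGlcNAc_TP"]])
    f
  }, numeric(1))
  names(out) <- .NSD_SPECIES
  out
}

#' Intracellular right-hand side (nucleotides, NSDs, glucose, glutamine)
#'
#' Balances the intracellular glucose and glutamine pools (uptake supply
#' scaled into the cell volume minus nucleotide, NSD and non-glycosylation
#' metabolic drains), the six nucleotides and the seven NSDs. All pools are
#' diluted by growth.
#'
#' @param state named intracellular state (uM).
#' @param q_glc,q_gln specific uptake rates from the culture module
#'   (mmol cell^-1 h^-1, negative = consumption).
#' @param q_mAb specific productivity (mg cell^-1 h^-1).
#' @param mu specific growth rate (h^-1).
#' @param p nsd parameter vector.
#' @param MW antibody molecular weight (mg mmol^-1).
#' @return named derivatives (uM h^-1); attributes \code{"r_nuc"},
#'   \code{"r_nsd"} and \code{"F_out"} expose the component rates.
#' @export
intracellularRHS <- function(state, q_glc, q_gln, q_mAb, mu, p, MW = 1.5e5) {
  s <- pmax(state, 0)
  U <- .UM_PER_MM
  rn <- nucleotideRates(s, p)
  rs <- nsdRates(s, p)
  Fo <- nsdTransportDemand(s, mu, q_mAb, p, MW)
  supply_glc <- U * max(0, -q_glc) / p[["V_cell"]]
  supply_gln <- U * max(0, -q_gln) / p[["V_cell"]] * (1 + p[["q_gln_syn_frac"]])
  r_met_glc <- U * p[["V_met_glc"]] * .sat(s[["Glc_int"]], p[["K_met_glc"]])
  r_met_gln <- U * p[["V_met_gln"]] * .sat(s[["Gln_int"]], p[["K_met_gln"]])
  d <- c(
    Glc_int = supply_glc -
      (p[["N_glc_ATP"]] * rn[["r_3f"]] + p[["N_glc_GTP"]] * rn[["r_1b"]] +
         p[["N_glc_UTP"]] * rn[["r_4"]] +
         p[["N_glc_UDPGlcNAc"]] * rs[["UDPGlcNAc"]] +
         p[["N_glc_UDPGlc"]] * rs[["UDPGlc"]] +
         p[["N_glc_GDPMan"]] * rs[["GDPMan"]] + r_met_glc) -
      mu * s[["Glc_int"]],
    Gln_int = supply_gln -
      (p[["N_gln_ATP"]] * rn[["r_3f"]] + p[["N_gln_CTP"]] * rn[["r_5"]] +
         p[["N_gln_GTP"]] * rn[["r_1b"]] + p[["N_gln_UTP"]] * rn[["r_4"]] +
         p[["N_gln_UDPGlcNAc"]] * rs[["UDPGlcNAc"]] +
         p[["N_gln_CMPNeu5Ac"]] * rs[["CMPNeu5Ac"]] + r_met_gln) -
      mu * s[["Gln_int"]],
    ATP = rn[["r_3f"]] - rn[["r_3b"]] - mu * s[["ATP"]],
    ADP = rn[["r_3b"]] - rn[["r_3f"]] + rn[["r_2b"]] - rn[["r_2f"]] -
      mu * s[["ADP"]],
    AMP = rn[["r_1a"]] + rn[["r_2f"]] - rn[["r_2b"]] - mu * s[["AMP"]],
    GTP = rn[["r_1b"]] - p[["N_GTP_GDPMan"]] * rs[["GDPMan"]] - mu * s[["GTP"]],
    UTP = rn[["r_4"]] - rn[["r_5"]] -
      p[["N_UTP_UDPGlc"]] * rs[["UDPGlc"]] -
      p[["N_UTP_UDPGlcNAc"]] * rs[["UDPGlcNAc"]] - mu * s[["UTP"]],
    CTP = rn[["r_5"]] - p[["N_CTP_CMPNeu5Ac"]] * rs[["CMPNeu5Ac"]] -
      mu * s[["CTP"]],
    UDPGlc = rs[["UDPGlc"]] - rs[["UDPGal"]] - Fo[["UDPGlc"]] -
      mu * s[["UDPGlc"]],
    UDPGal = rs[["UDPGal"]] - Fo[["UDPGal"]] - mu * s[["UDPGal"]],
    UDPGlcNAc = rs[["UDPGlcNAc"]] - rs[["UDPGalNAc"]] -
      p[["N_UDPGlcNAc_CMPNeu5Ac"]] * rs[["CMPNeu5Ac"]] -
      Fo[["UDPGlcNAc"]] - mu * s[["UDPGlcNAc"]],
    UDPGalNAc = rs[["UDPGalNAc"]] - Fo[["UDPGalNAc"]] - mu * s[["UDPGalNAc"]],
    GDPMan = rs[["GDPMan"]] - rs[["GDPFuc"]] - Fo[["GDPMan"]] -
      mu * s[["GDPMan"]],
    GDPFuc = rs[["GDPFuc"]] - Fo[["GDPFuc"]] - mu * s[["GDPFuc"]],
    CMPNeu5Ac = rs[["CMPNeu5Ac"]] - Fo[["CMPNeu5Ac"]] - mu * s[["CMPNeu5Ac"]])
  attr(d, "r_nuc") <- rn
  attr(d, "r_nsd") <- rs
  attr(d, "F_out") <- Fo
  d
}
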