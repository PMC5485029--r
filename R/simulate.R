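# Event-aware integration of the coupled model. Bolus feeds are applied as
# instantaneous dilution-and-addition events between stiff-solver segments;
# the parameter set is swapped at the temperature-shift time (right-closed:
# the post-shift set applies from the shift instant onward).

#' Select the parameter regime for a time point
#'
#' Pure function implementing the right-closed shift convention: the
#' pre-shift set applies on \[0, shiftTime), the post-shift set from
#' shiftTime onward. With no shift (or no post-shift set) the single set is
#' returned.
#'
#' @param t time (h).
#' @param shiftTime shift time (h) or \code{NA}.
#' @param params pre-shift [ParameterSet-class].
#' @param paramsPost post-shift set or \code{NULL}.
#' @return a [ParameterSet-class].
#' @export
switchRegime <- function(t, shiftTime, params, paramsPost = NULL) {
  stopifnot(t >= 0)
  if (is.null(paramsPost) || is.na(shiftTime) || t < shiftTime) params
  else paramsPost
}

# Fast closure RHS over the active modules. Reference semantics live in
# cultureRHS()/mabRHS()/intracellularRHS(); a consistency test pins this
# implementation to those.
.makeRHS <- function(params, modules, nCulture = length(.STATE_CULTURE)) {
  g <- params@growth; m <- params@metabolism
  mb <- params@mab; nd <- params@nsd
  hasMab <- "mab" %in% modules
  hasIntra <- "intracellular" %in% modules
  # hoist every constant out of the inner function: the RHS is evaluated
  # O(1e4-1e6) times per fit, so named-vector lookups are not affordable.
  mu_max <- g[["mu_max"]]; mu_d_max <- g[["mu_d_max"]]
  K_lysis <- g[["K_lysis"]]; K_glc <- g[["K_glc"]]; K_lac <- g[["K_lac"]]
  K_asn <- g[["K_asn"]]; K_glu <- g[["K_glu"]]
  KI_amm <- g[["KI_amm"]]; KI_lac <- g[["KI_lac"]]; K_d_amm <- g[["K_d_amm"]]
  Y_xv_glc <- m[["Y_xv_glc"]]; Y_xv_lac <- m[["Y_xv_lac"]]
  Y_xv_amm <- m[["Y_xv_amm"]]; Y_lac_glc <- m[["Y_lac_glc"]]
  Y_asp_asn <- m[["Y_asp_asn"]]; m_glc <- m[["m_glc"]]
  k_T_lac <- m[["k_T_lac"]]
  Yaa <- unname(m[paste0("Y_xv_", tolower(.AMINO_ACIDS))])
  maa <- unname(m[paste0("m_", tolower(.AMINO_ACIDS))])
  nuaa <- unname(m[paste0("nu_", tolower(.AMINO_ACIDS))])
  S_H <- mb[["S_H"]]; S_L <- mb[["S_L"]]; T_H <- mb[["T_H"]]
  T_L <- mb[["T_L"]]; K_H <- mb[["K_H"]]; K_L <- mb[["K_L"]]
  K_A <- mb[["K_A"]]; K_ER <- mb[["K_ER"]]; K_G <- mb[["K_G"]]
  N_Hc <- mb[["N_H"]]; N_Lc <- mb[["N_L"]]; MW <- mb[["MW"]]
  iMab <- if (hasMab) nCulture + seq_along(.STATE_MAB) else integer()
  iIntra <- if (hasIntra) nCulture + length(iMab) + seq_along(.STATE_INTRA)
            else integer()
  U <- .UM_PER_MM
  if (hasIntra) {
    V1a <- U * nd[["V_max_1a"]]; V1b <- U * nd[["V_max_1b"]]
    V2b <- U * nd[["V_max_2b"]]; V2f <- U * nd[["V_max_2f"]]
    V3b <- U * nd[["V_max_3b"]]; V3f <- U * nd[["V_max_3f"]]
    V4 <- U * nd[["V_max_4"]]; V5 <- U * nd[["V_max_5"]]
    K1ag <- nd[["K_1a_glc"]]; K1aq <- nd[["K_1a_gln"]]
    K1bg <- nd[["K_1b_glc"]]; K1bq <- nd[["K_1b_gln"]]
    K2f <- nd[["K_2f_adp"]]; K2b <- nd[["K_2b_amp"]]
    K3fa <- nd[["K_3f_adp"]]; K3fg <- nd[["K_3f_glc"]]
    K3b <- nd[["K_3b_atp"]]
    K4g <- nd[["K_4_glc"]]; K4q <- nd[["K_4_gln"]]
    K5u <- nd[["K_5_utp"]]; K5q <- nd[["K_5_gln"]]
    Vgn <- U * nd[["V_max_UDPGlcNAc"]]; Vug <- U * nd[["V_max_UDPGlc"]]
    Vgm <- U * nd[["V_max_GDPMan"]]; Vga <- U * nd[["V_max_UDPGalNAc"]]
    Vne <- U * nd[["V_max_CMPNeu5Ac"]]; Vul <- U * nd[["V_max_UDPGal"]]
    Vgf <- U * nd[["V_max_GDPFuc"]]
    Kgn_g <- nd[["K_UDPGlcNAc_glc"]]; Kgn_q <- nd[["K_UDPGlcNAc_gln"]]
    Kgn_u <- nd[["K_UDPGlcNAc_utp"]]
    Kug_g <- nd[["K_UDPGlc_glc"]]; Kug_u <- nd[["K_UDPGlc_utp"]]
    Kgm_g <- nd[["K_GDPMan_glc"]]; Kgm_t <- nd[["K_GDPMan_gtp"]]
    Kga <- nd[["K_UDPGalNAc_UDPGlcNAc"]]
    Kne_n <- nd[["K_CMPNeu5Ac_UDPGlcNAc"]]; Kne_q <- nd[["K_CMPNeu5Ac_gln"]]
    Kul <- nd[["K_UDPGal_UDPGlc"]]; Kgf <- nd[["K_GDPFuc_GDPMan"]]
    KiNe <- nd[["Ki_CMPNeu5Ac"]]; KiGf <- nd[["Ki_GDPFuc"]]
    KTP <- unname(nd[paste0("K_TP_", .NSD_SPECIES)])
    Nglyc <- unname(nd[paste0("N_glyc_", .NSD_SPECIES)])
    Nmab <- numeric(7)
    Nmab[match(.NSD_MAB_TRANSPORT, .NSD_SPECIES)] <-
      unname(nd[paste0("N_mab_", .NSD_MAB_TRANSPORT)])
    KiTP <- nd[["Ki_CMPNeu5Ac_UDPGlcNAc_TP"]]
    NgcATP <- nd[["N_glc_ATP"]]; NgcGTP <- nd[["N_glc_GTP"]]
    NgcUTP <- nd[["N_glc_UTP"]]; NgcGN <- nd[["N_glc_UDPGlcNAc"]]
    NgcUG <- nd[["N_glc_UDPGlc"]]; NgcGM <- nd[["N_glc_GDPMan"]]
    NqATP <- nd[["N_gln_ATP"]]; NqCTP <- nd[["N_gln_CTP"]]
    NqGTP <- nd[["N_gln_GTP"]]; NqUTP <- nd[["N_gln_UTP"]]
    NqGN <- nd[["N_gln_UDPGlcNAc"]]; NqNe <- nd[["N_gln_CMPNeu5Ac"]]
    NGtGm <- nd[["N_GTP_GDPMan"]]; NUtUg <- nd[["N_UTP_UDPGlc"]]
    NUtGn <- nd[["N_UTP_UDPGlcNAc"]]; NCtNe <- nd[["N_CTP_CMPNeu5Ac"]]
    NGnNe <- nd[["N_UDPGlcNAc_CMPNeu5Ac"]]
    Vmg <- U * nd[["V_met_glc"]]; Kmg <- nd[["K_met_glc"]]
    Vmq <- U * nd[["V_met_gln"]]; Kmq <- nd[["K_met_gln"]]
    qs <- nd[["q_gln_syn_frac"]]; Vcell <- nd[["V_cell"]]
    NglycCell <- nd[["N_glyc_cell"]]; NglycMab <- nd[["N_glyc_mAb"]]
  }

  function(t, y, parms) {
    y <- pmax(y, 0)
    # --- culture ---
    Xv <- y[2]; Glc <- y[4]; Lac <- y[5]; Amm <- y[6]
    flim <- (Glc / (K_glc + Glc)) * (Lac / (K_lac + Lac)) *
      (y[7] / (K_asn + y[7])) * (y[10] / (K_glu + y[10]))
    if (!is.finite(flim)) flim <- 0
    finh <- (KI_amm / (KI_amm + Amm)) * (KI_lac / (KI_lac + Lac))
    mu <- mu_max * flim * finh
    mud <- if (Amm > 0) mu_d_max / (1 + K_d_amm / Amm) else 0

    q_mAb <- 0
    dmab <- NULL
    if (hasMab) {
      s <- y[iMab]
      rTH <- T_H * s[1]; rTL <- T_L * s[2]
      rA1 <- K_A * s[3] * s[3]
      rA2 <- K_A * s[5] * s[4]
      rA3 <- K_A * s[6] * s[4]
      rER <- K_ER * s[7]; rG <- K_G * s[8]
      q_mAb <- rG / .NA_PER_MMOL * MW
      dmab <- c(S_H * N_Hc - (K_H + mu) * s[1],
                S_L * N_Lc - (K_L + mu) * s[2],
                rTH - 2 * rA1 - mu * s[3],
                rTL - rA2 - rA3 - mu * s[4],
                rA1 - rA2 - mu * s[5],
                rA2 - rA3 - mu * s[6],
                rA3 - rER - mu * s[7],
                rER - rG - mu * s[8])
    }

    q_glc <- -mu / Y_xv_glc - m_glc
    q_lac <- -q_glc * Y_lac_glc -
      (mu / Y_xv_lac + k_T_lac * Lac) * Lac / (Lac + .K_LAC_MOD)
    q_mab_mmol <- q_mAb / MW
    q_aa <- -mu / Yaa - maa - nuaa * q_mab_mmol
    q_asp_extra <- (-q_aa[1]) * Y_asp_asn
    q_amm <- -q_aa[5] - q_aa[1] * Y_asp_asn - q_aa[3] + mu / Y_xv_amm
    q_aa[2] <- q_aa[2] + q_asp_extra
    dy <- numeric(length(y))
    dy[2] <- (mu - mud) * Xv
    dy[3] <- mu * Xv - K_lysis * (y[3] - Xv)
    dy[4] <- q_glc * Xv
    dy[5] <- q_lac * Xv
    dy[6] <- q_amm * Xv
    dy[7:13] <- q_aa * Xv
    dy[14] <- q_mAb * Xv
    if (hasMab) dy[iMab] <- dmab

    if (hasIntra) {
      s <- y[iIntra]
      Gi <- s[1]; Qi <- s[2]; ATP <- s[3]; ADP <- s[4]
      GTP <- s[6]; UTP <- s[7]
      r1a <- V1a * (Gi / (K1ag + Gi)) * (Qi / (K1aq + Qi))
      r1b <- V1b * (Gi / (K1bg + Gi)) * (Qi / (K1bq + Qi))
      r2f <- V2f * (ADP / (K2f + ADP))
      r2b <- V2b * (s[5] / (K2b + s[5]))
      r3f <- V3f * (ADP / (K3fa + ADP)) * (Gi / (K3fg + Gi))
      r3b <- V3b * (ATP / (K3b + ATP))
      r4 <- V4 * (Gi / (K4g + Gi)) * (Qi / (K4q + Qi))
      r5 <- V5 * (UTP / (K5u + UTP)) * (Qi / (K5q + Qi))
      rGlcNAc <- Vgn * (Gi / (Kgn_g + Gi)) * (Qi / (Kgn_q + Qi)) *
        (UTP / (Kgn_u + UTP))
      rUGlc <- Vug * (Gi / (Kug_g + Gi)) * (UTP / (Kug_u + UTP))
      rGMan <- Vgm * (Gi / (Kgm_g + Gi)) * (GTP / (Kgm_t + GTP))
      rGalNAc <- Vga * (s[11] / (Kga + s[11]))
      rNeu <- Vne * (s[11] / (Kne_n + s[11])) * (Qi / (Kne_q + Qi)) /
        (1 + s[15] / KiNe)
      rUGal <- Vul * (s[9] / (Kul + s[9]))
      rGFuc <- Vgf * (s[13] / (Kgf + s[13])) * KiGf / (KiGf + s[14])

      host <- mu * NglycCell / Vcell
      mabd <- q_mab_mmol * NglycMab / Vcell
      nsdConc <- s[9:15]
      Fo <- nsdConc / (KTP + nsdConc) * U * (host * Nglyc + mabd * Nmab)
      Fo[7] <- Fo[7] / (1 + s[11] / KiTP)
      supply_glc <- U * max(0, -q_glc) / Vcell
      supply_gln <- U * max(0, -q_aa[5]) / Vcell * (1 + qs)
      rmetg <- Vmg * (Gi / (Kmg + Gi))
      rmetq <- Vmq * (Qi / (Kmq + Qi))
      dy[iIntra] <- c(
        supply_glc - (NgcATP * r3f + NgcGTP * r1b + NgcUTP * r4 +
                        NgcGN * rGlcNAc + NgcUG * rUGlc + NgcGM * rGMan +
                        rmetg) - mu * Gi,
        supply_gln - (NqATP * r3f + NqCTP * r5 + NqGTP * r1b + NqUTP * r4 +
                        NqGN * rGlcNAc + NqNe * rNeu + rmetq) - mu * Qi,
        r3f - r3b - mu * ATP,
        r3b - r3f + r2b - r2f - mu * ADP,
        r1a + r2f - r2b - mu * s[5],
        r1b - NGtGm * rGMan - mu * GTP,
        r4 - r5 - NUtUg * rUGlc - NUtGn * rGlcNAc - mu * UTP,
        r5 - NCtNe * rNeu - mu * s[8],
        rUGlc - rUGal - Fo[1] - mu * s[9],
        rUGal - Fo[2] - mu * s[10],
        rGlcNAc - rGalNAc - NGnNe * rNeu - Fo[3] - mu * s[11],
        rGalNAc - Fo[4] - mu * s[12],
        rGMan - rGFuc - Fo[5] - mu * s[13],
        rGFuc - Fo[6] - mu * s[14],
        rNeu - Fo[7] - mu * s[15])
    }
    list(dy)
  }
}

# Forced intracellular-only RHS with hoisted constants: same kinetics as
# intracellularRHS() (a consistency test pins them together), driven by
# interpolated culture forcings.
.makeIntraRHS <- function(params, fmu, fqg, fqq, fqm) {
  nd <- params@nsd
  MW <- params@mab[["MW"]]
  U <- .UM_PER_MM
  V1a <- U * nd[["V_max_1a"]]; V1b <- U * nd[["V_max_1b"]]
  V2b <- U * nd[["V_max_2b"]]; V2f <- U * nd[["V_max_2f"]]
  V3b <- U * nd[["V_max_3b"]]; V3f <- U * nd[["V_max_3f"]]
  V4 <- U * nd[["V_max_4"]]; V5 <- U * nd[["V_max_5"]]
  K1ag <- nd[["K_1a_glc"]]; K1aq <- nd[["K_1a_gln"]]
  K1bg <- nd[["K_1b_glc"]]; K1bq <- nd[["K_1b_gln"]]
  K2f <- nd[["K_2f_adp"]]; K2b <- nd[["K_2b_amp"]]
  K3fa <- nd[["K_3f_adp"]]; K3fg <- nd[["K_3f_glc"]]; K3b <- nd[["K_3b_atp"]]
  K4g <- nd[["K_4_glc"]]; K4q <- nd[["K_4_gln"]]
  K5u <- nd[["K_5_utp"]]; K5q <- nd[["K_5_gln"]]
  Vgn <- U * nd[["V_max_UDPGlcNAc"]]; Vug <- U * nd[["V_max_UDPGlc"]]
  Vgm <- U * nd[["V_max_GDPMan"]]; Vga <- U * nd[["V_max_UDPGalNAc"]]
  Vne <- U * nd[["V_max_CMPNeu5Ac"]]; Vul <- U * nd[["V_max_UDPGal"]]
  Vgf <- U * nd[["V_max_GDPFuc"]]
  Kgn_g <- nd[["K_UDPGlcNAc_glc"]]; Kgn_q <- nd[["K_UDPGlcNAc_gln"]]
  Kgn_u <- nd[["K_UDPGlcNAc_utp"]]
  Kug_g <- nd[["K_UDPGlc_glc"]]; Kug_u <- nd[["K_UDPGlc_utp"]]
  Kgm_g <- nd[["K_GDPMan_glc"]]; Kgm_t <- nd[["K_GDPMan_gtp"]]
  Kga <- nd[["K_UDPGalNAc_UDPGlcNAc"]]
  Kne_n <- nd[["K_CMPNeu5Ac_UDPGlcNAc"]]; Kne_q <- nd[["K_CMPNeu5Ac_gln"]]
  Kul <- nd[["K_UDPGal_UDPGlc"]]; Kgf <- nd[["K_GDPFuc_GDPMan"]]
  KiNe <- nd[["Ki_CMPNeu5Ac"]]; KiGf <- nd[["Ki_GDPFuc"]]
  KTP <- unname(nd[paste0("K_TP_", .NSD_SPECIES)])
  Nglyc <- unname(nd[paste0("N_glyc_", .NSD_SPECIES)])
  Nmab <- numeric(7)
  Nmab[match(.NSD_MAB_TRANSPORT, .NSD_SPECIES)] <-
    unname(nd[paste0("N_mab_", .NSD_MAB_TRANSPORT)])
  KiTP <- nd[["Ki_CMPNeu5Ac_UDPGlcNAc_TP"]]
  NgcATP <- nd[["N_glc_ATP"]]; NgcGTP <- nd[["N_glc_GTP"]]
  NgcUTP <- nd[["N_glc_UTP"]]; NgcGN <- nd[["N_glc_UDPGlcNAc"]]
  NgcUG <- nd[["N_glc_UDPGlc"]]; NgcGM <- nd[["N_glc_GDPMan"]]
  NqATP <- nd[["N_gln_ATP"]]; NqCTP <- nd[["N_gln_CTP"]]
  NqGTP <- nd[["N_gln_GTP"]]; NqUTP <- nd[["N_gln_UTP"]]
  NqGN <- nd[["N_gln_UDPGlcNAc"]]; NqNe <- nd[["N_gln_CMPNeu5Ac"]]
  NGtGm <- nd[["N_GTP_GDPMan"]]; NUtUg <- nd[["N_UTP_UDPGlc"]]
  NUtGn <- nd[["N_UTP_UDPGlcNAc"]]; NCtNe <- nd[["N_CTP_CMPNeu5Ac"]]
  NGnNe <- nd[["N_UDPGlcNAc_CMPNeu5Ac"]]
  Vmg <- U * nd[["V_met_glc"]]; Kmg <- nd[["K_met_glc"]]
  Vmq <- U * nd[["V_met_gln"]]; Kmq <- nd[["K_met_gln"]]
  qs <- nd[["q_gln_syn_frac"]]; Vcell <- nd[["V_cell"]]
  NglycCell <- nd[["N_glyc_cell"]]; NglycMab <- nd[["N_glyc_mAb"]]

  function(t, y, parms) {
    s <- pmax(y, 0)
    mu <- fmu(t)
    q_mab_mmol <- fqm(t) / MW
    Gi <- s[1]; Qi <- s[2]; ATP <- s[3]; ADP <- s[4]
    GTP <- s[6]; UTP <- s[7]
    r1a <- V1a * (Gi / (K1ag + Gi)) * (Qi / (K1aq + Qi))
    r1b <- V1b * (Gi / (K1bg + Gi)) * (Qi / (K1bq + Qi))
    r2f <- V2f * (ADP / (K2f + ADP))
    r2b <- V2b * (s[5] / (K2b + s[5]))
    r3f <- V3f * (ADP / (K3fa + ADP)) * (Gi / (K3fg + Gi))
    r3b <- V3b * (ATP / (K3b + ATP))
    r4 <- V4 * (Gi / (K4g + Gi)) * (Qi / (K4q + Qi))
    r5 <- V5 * (UTP / (K5u + UTP)) * (Qi / (K5q + Qi))
    rGlcNAc <- Vgn * (Gi / (Kgn_g + Gi)) * (Qi / (Kgn_q + Qi)) *
      (UTP / (Kgn_u + UTP))
    rUGlc <- Vug * (Gi / (Kug_g + Gi)) * (UTP / (Kug_u + UTP))
    rGMan <- Vgm * (Gi / (Kgm_g + Gi)) * (GTP / (Kgm_t + GTP))
    rGalNAc <- Vga * (s[11] / (Kga + s[11]))
    rNeu <- Vne * (s[11] / (Kne_n + s[11])) * (Qi / (Kne_q + Qi)) /
      (1 + s[15] / KiNe)
    rUGal <- Vul * (s[9] / (Kul + s[9]))
    rGFuc <- Vgf * (s[13] / (Kgf + s[13])) * KiGf / (KiGf + s[14])
    host <- mu * NglycCell / Vcell
    mabd <- q_mab_mmol * NglycMab / Vcell
    nsdConc <- s[9:15]
    Fo <- nsdConc / (KTP + nsdConc) * U * (host * Nglyc + mabd * Nmab)
    Fo[7] <- Fo[7] / (1 + s[11] / KiTP)
    supply_glc <- U * max(0, -fqg(t)) / Vcell
    supply_gln <- U * max(0, -fqq(t)) / Vcell * (1 + qs)
    rmetg <- Vmg * (Gi / (Kmg + Gi))
    rmetq <- Vmq * (Qi / (Kmq + Qi))
    list(c(
      supply_glc - (NgcATP * r3f + NgcGTP * r1b + NgcUTP * r4 +
                      NgcGN * rGlcNAc + NgcUG * rUGlc + NgcGM * rGMan +
                      rmetg) - mu * Gi,
      supply_gln - (NqATP * r3f + NqCTP * r5 + NqGTP * r1b + NqUTP * r4 +
                      NqGN * rGlcNAc + NqNe * rNeu + rmetq) - mu * Qi,
      r3f - r3b - mu * ATP,
      r3b - r3f + r2b - r2f - mu * ADP,
      r1a + r2f - r2b - mu * s[5],
      r1b - NGtGm * rGMan - mu * GTP,
      r4 - r5 - NUtUg * rUGlc - NUtGn * rGlcNAc - mu * UTP,
      r5 - NCtNe * rNeu - mu * s[8],
      rUGlc - rUGal - Fo[1] - mu * s[9],
      rUGal - Fo[2] - mu * s[10],
      rGlcNAc - rGalNAc - NGnNe * rNeu - Fo[3] - mu * s[11],
      rGalNAc - Fo[4] - mu * s[12],
      rGMan - rGFuc - Fo[5] - mu * s[13],
      rGFuc - Fo[6] - mu * s[14],
      rNeu - Fo[7] - mu * s[15]))
  }
}

# state names for a module selection
.stateNames <- function(modules) {
  c(.STATE_CULTURE,
    if ("mab" %in% modules) .STATE_MAB,
    if ("intracellular" %in% modules) .STATE_INTRA)
}

# Apply one bolus event to the state vector: add volume `vol` with
# composition `comp` (named, mM over culture species). Per-cell and
# intracellular pools are unaffected by medium addition; volumetric
# concentrations (cells, metabolites, titer) are diluted.
.applyBolus <- function(y, stateNames, vol, comp) {
  V <- y[1]
  Vnew <- V + vol
  iconc <- match(setdiff(.STATE_CULTURE, "V"), stateNames)
  added <- numeric(length(iconc))
  names(added) <- setdiff(.STATE_CULTURE, "V")
  if (length(comp)) added[names(comp)] <- comp
  y[iconc] <- (y[iconc] * V + added * vol) / Vnew
  y[1] <- Vnew
  y
}

#' Integrate a fed-batch culture
#'
#' Runs the coupled model over one experiment: stiff adaptive integration
#' (\code{deSolve::lsoda}) between discrete events, instantaneous bolus
#' feeds (dilution and addition), on-demand glucose feeding evaluated at
#' periodic checks, and a parameter-regime switch at the temperature-shift
#' time. State continuity across the shift is exact: only parameters
#' change.
#'
#' @param design an [ExperimentDesign-class].
#' @param params pre-shift (or only) [ParameterSet-class].
#' @param paramsPost post-shift set; required when the design has a shift
#'   time, ignored otherwise.
#' @param modules character subset of
#'   \code{c("culture", "mab", "intracellular")}; \code{"culture"} is
#'   always active. Restricting modules speeds up staged fitting.
#' @param times output time grid (h); defaults to the design's sampling
#'   times.
#' @param rtol,atol solver tolerances.
#' @param feedMode \code{"bolus"} (default) applies feeds as instantaneous
#'   events; \code{"continuous"} spreads each feed over
#'   \code{feedDuration} hours with the inlet-flow terms active.
#' @param feedDuration duration (h) of each feed in continuous mode.
#' @return a [Trajectory-class].
#' @examples
#' des <- defaultDesign(shift = FALSE)
#' tr <- integrateCulture(des, defaultParameters("36.5C"),
#'                        modules = "culture")
#' @export
integrateCulture <- function(design, params, paramsPost = NULL,
                             modules = c("culture", "mab", "intracellular"),
                             times = NULL, rtol = 1e-8, atol = 1e-10,
                             feedMode = c("bolus", "continuous"),
                             feedDuration = 1) {
  feedMode <- match.arg(feedMode)
  modules <- unique(c("culture", match.arg(modules,
    c("culture", "mab", "intracellular"), several.ok = TRUE)))
  validObject(design)
  shift <- design@shiftTime
  if (!is.na(shift) && is.null(paramsPost))
    stop("design has a temperature shift but no post-shift parameter set ",
         "was supplied", call. = FALSE)
  stateNames <- .stateNames(modules)
  y0 <- c(design@initialVolume, design@initialState[stateNames[-1]])
  names(y0) <- stateNames
  if (is.null(times)) times <- design@samplingTimes
  if (!length(times)) stop("no output times requested", call. = FALSE)
  t0 <- 0

  # event table: type feed / glcFeed / glcCheck / shift
  ev <- data.frame(time = numeric(), type = character(), id = character(),
                   vol = numeric(), conc = numeric(),
                   stringsAsFactors = FALSE)
  fe <- design@feedEvents
  if (nrow(fe))
    ev <- rbind(ev, data.frame(time = fe$time, type = "feed",
                               id = as.character(fe$feed_id),
                               vol = fe$volume, conc = NA_real_))
  gf <- design@glucoseFeeds
  if (nrow(gf))
    ev <- rbind(ev, data.frame(time = gf$time, type = "glcFeed", id = "",
                               vol = gf$volume, conc = gf$conc))
  gt <- design@glucoseTrigger
  if (gt[["volume"]] > 0 && gt[["checkEvery"]] > 0) {
    chk <- seq(gt[["checkEvery"]], design@tEnd, by = gt[["checkEvery"]])
    ev <- rbind(ev, data.frame(time = chk, type = "glcCheck", id = "",
                               vol = gt[["volume"]], conc = gt[["conc"]]))
  }
  if (!is.na(shift))
    ev <- rbind(ev, data.frame(time = shift, type = "shift", id = "",
                               vol = NA_real_, conc = NA_real_))
  ev <- ev[order(ev$time, match(ev$type, c("feed", "glcFeed", "glcCheck",
                                           "shift"))), , drop = FALSE]

  if (feedMode == "continuous")
    return(.integrateContinuous(design, params, paramsPost, modules, times,
                                rtol, atol, feedDuration, ev, y0))

  breakTimes <- sort(unique(c(ev$time[ev$time > t0 & ev$time < design@tEnd],
                              design@tEnd)))
  rhs <- .makeRHS(params, modules)
  regimeOf <- function(t) {
    if (is.na(shift) || is.null(paramsPost) || t < shift)
      params@temperature else paramsPost@temperature
  }

  out <- matrix(NA_real_, length(times), length(y0),
                dimnames = list(NULL, stateNames))
  if (times[1] == t0) out[1, ] <- y0
  y <- y0
  cur <- t0
  for (tb in breakTimes) {
    segOut <- times[times > cur & times < tb]
    grid <- sort(unique(c(cur, segOut, tb)))
    sol <- tryCatch(
      deSolve::lsoda(y, grid, rhs, parms = NULL, rtol = rtol, atol = atol,
                     maxsteps = 50000),
      warning = function(w) stop(sprintf(
        "solver failed on [%.2f, %.2f] h: %s", cur, tb,
        conditionMessage(w)), call. = FALSE))
    if (nrow(sol) < length(grid))
      stop(sprintf("solver did not reach %.2f h (failed in [%.2f, %.2f])",
                   tb, cur, tb), call. = FALSE)
    if (length(segOut))
      out[match(segOut, times), ] <- sol[match(segOut, grid), -1, drop = FALSE]
    y <- pmax(sol[nrow(sol), -1], 0)
    names(y) <- stateNames
    # apply the events scheduled at tb
    for (j in which(abs(ev$time - tb) < 1e-9)) {
      tp <- ev$type[j]
      if (tp == "feed") {
        y <- .applyBolus(y, stateNames, ev$vol[j],
                         design@feedCompositions[[ev$id[j]]])
      } else if (tp == "glcFeed") {
        y <- .applyBolus(y, stateNames, ev$vol[j], c(Glc = ev$conc[j]))
      } else if (tp == "glcCheck") {
        if (y[["Glc"]] < gt[["threshold"]])
          y <- .applyBolus(y, stateNames, ev$vol[j], c(Glc = ev$conc[j]))
      } else if (tp == "shift") {
        rhs <- .makeRHS(paramsPost, modules)
      }
    }
    if (tb %in% times) out[match(tb, times), ] <- y
    cur <- tb
  }
  # output times at t0 or beyond last break already filled; any time exactly
  # at a break got the post-event state.
  .buildTrajectory(times, out, design, modules, params, paramsPost,
                   vapply(times, regimeOf, character(1)))
}

# continuous-feed variant: feeds become constant inlet flows over
# [t, t + feedDuration]; Eq-1/Eq-8 style F_in terms are added to the RHS.
.integrateContinuous <- function(design, params, paramsPost, modules, times,
                                 rtol, atol, feedDuration, ev, y0) {
  stateNames <- names(y0)
  shift <- design@shiftTime
  feeds <- ev[ev$type %in% c("feed", "glcFeed"), , drop = FALSE]
  starts <- feeds$time
  ends <- pmin(feeds$time + feedDuration, design@tEnd)
  breakTimes <- sort(unique(c(starts, ends, shift[!is.na(shift)],
                              design@tEnd)))
  breakTimes <- breakTimes[breakTimes > 0]
  iconc <- match(setdiff(.STATE_CULTURE, "V"), stateNames)
  concNames <- setdiff(.STATE_CULTURE, "V")
  out <- matrix(NA_real_, length(times), length(y0),
                dimnames = list(NULL, stateNames))
  if (times[1] == 0) out[1, ] <- y0
  y <- y0; cur <- 0
  p <- params
  for (tb in breakTimes) {
    mid <- (cur + tb) / 2
    if (!is.na(shift) && mid >= shift && !is.null(paramsPost)) p <- paramsPost
    act <- which(starts <= cur + 1e-9 & ends >= tb - 1e-9)
    Fin <- 0
    addRate <- numeric(length(iconc)); names(addRate) <- concNames
    for (j in act) {
      rate <- feeds$vol[j] / feedDuration
      Fin <- Fin + rate
      comp <- if (feeds$type[j] == "feed")
        design@feedCompositions[[feeds$id[j]]] else c(Glc = feeds$conc[j])
      if (length(comp)) addRate[names(comp)] <- addRate[names(comp)] +
          rate * comp
    }
    base <- .makeRHS(p, modules)
    rhs <- function(t, yv, parms) {
      d <- base(t, yv, parms)[[1]]
      if (Fin > 0) {
        V <- yv[1]
        d[1] <- d[1] + Fin
        d[iconc] <- d[iconc] + (addRate - Fin * yv[iconc]) / V
      }
      list(d)
    }
    segOut <- times[times > cur & times < tb]
    grid <- sort(unique(c(cur, segOut, tb)))
    sol <- deSolve::lsoda(y, grid, rhs, parms = NULL, rtol = rtol,
                          atol = atol, maxsteps = 50000)
    if (length(segOut))
      out[match(segOut, times), ] <- sol[match(segOut, grid), -1, drop = FALSE]
    y <- pmax(sol[nrow(sol), -1], 0); names(y) <- stateNames
    if (tb %in% times) out[match(tb, times), ] <- y
    cur <- tb
  }
  regime <- vapply(times, function(t)
    if (is.na(shift) || is.null(paramsPost) || t < shift) params@temperature
    else paramsPost@temperature, character(1))
  .buildTrajectory(times, out, design, modules, params, paramsPost, regime)
}

.buildTrajectory <- function(times, out, design, modules, params, paramsPost,
                             regime) {
  shift <- design@shiftTime
  derived <- t(vapply(seq_along(times), function(i) {
    p <- switchRegime(times[i], shift, params, paramsPost)
    y <- out[i, ]
    mu <- specificGrowthRate(y[.STATE_CULTURE[-1]], p@growth)
    mud <- specificDeathRate(y[["Amm"]], p@growth)
    q_mAb <- if ("mab" %in% modules)
      p@mab[["K_G"]] * max(y[["GolgiMab"]], 0) / .NA_PER_MMOL * p@mab[["MW"]]
    else 0
    q <- metaboliteRates(y[.STATE_CULTURE[-1]], mu, p@metabolism,
                         q_mAb = q_mAb, MW = p@mab[["MW"]])
    c(mu = mu, mud = mud, q_glc = q[["Glc"]], q_lac = q[["Lac"]],
      q_amm = q[["Amm"]], q_gln = q[["Gln"]], q_mAb = q_mAb)
  }, numeric(7)))
  colnames(derived) <- c("mu", "mud", "q_glc", "q_lac", "q_amm", "q_gln",
                         "q_mAb")
  new("Trajectory", times = times, states = pmax(out, 0), derived = derived,
      design = design, modules = modules, regime = regime)
}

#' Simulate the intracellular module driven by recorded culture outputs
#'
#' Integrates the nucleotide/NSD balances alone, with growth rate, glucose
#' and glutamine uptake and specific productivity supplied as interpolated
#' forcing functions — the staged coupling used when fitting the
#' intracellular module against NSD measurements.
#'
#' @param forcings data.frame with columns \code{time_h}, \code{mu},
#'   \code{q_glc}, \code{q_gln}, \code{q_mAb} (see [cultureForcings()]).
#' @param params a [ParameterSet-class] (slot \code{nsd} is used).
#' @param times output times (h).
#' @param y0 named initial intracellular state (uM); defaults to the
#'   intracellular entries of [defaultDesign()].
#' @param rtol,atol solver tolerances.
#' @return matrix of intracellular states (rows = times).
#' @export
simulateIntracellular <- function(forcings, params, times, y0 = NULL,
                                  rtol = 1e-8, atol = 1e-10) {
  need <- c("time_h", "mu", "q_glc", "q_gln", "q_mAb")
  stopifnot(all(need %in% names(forcings)))
  if (is.null(y0)) y0 <- defaultDesign()@initialState[.STATE_INTRA]
  y0 <- y0[.STATE_INTRA]
  fmu <- stats::approxfun(forcings$time_h, forcings$mu, rule = 2)
  fqg <- stats::approxfun(forcings$time_h, forcings$q_glc, rule = 2)
  fqq <- stats::approxfun(forcings$time_h, forcings$q_gln, rule = 2)
  fqm <- stats::approxfun(forcings$time_h, forcings$q_mAb, rule = 2)
  rhs <- .makeIntraRHS(params, fmu, fqg, fqq, fqm)
  y <- y0
  grid <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::lsoda(y, grid, rhs, parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  m <- sol[match(times, grid), -1, drop = FALSE]
  colnames(m) <- .STATE_INTRA
  pmax(m, 0)
}

#' Extract forcing functions for staged intracellular simulation
#'
#' @param trajectory a [Trajectory-class] from [integrateCulture()].
#' @return data.frame of time_h, mu, q_glc, q_gln, q_mAb.
#' @export
cultureForcings <- function(trajectory) {
  d <- trajectory@derived
  data.frame(time_h = trajectory@times, mu = d[, "mu"],
             q_glc = d[, "q_glc"], q_gln = d[, "q_gln"],
             q_mAb = d[, "q_mAb"])
}
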