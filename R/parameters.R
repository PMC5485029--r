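# Parameter registry. Values marked "reported" below are the published
# two-temperature estimates; everything else is a reconstructed default
# (supplement-only in the original study) chosen once to place simulated
# trajectories in physiological ranges. See the methods vignette.

.PARAM_NAMES <- list(
  growth = c("mu_max", "mu_d_max", "K_lysis",
             "K_glc", "K_lac", "K_asn", "K_glu",
             "KI_amm", "KI_lac", "K_d_amm"),
  metabolism = c("Y_xv_glc", "Y_xv_lac", "Y_xv_amm", "Y_lac_glc",
                 "Y_asp_asn", "m_glc", "k_T_lac",
                 paste0("Y_xv_", tolower(.AMINO_ACIDS)),
                 paste0("m_", tolower(.AMINO_ACIDS)),
                 paste0("nu_", tolower(.AMINO_ACIDS))),
  mab = c("S_H", "S_L", "T_H", "T_L", "K_H", "K_L",
          "K_A", "K_ER", "K_G", "N_H", "N_L", "epsilon2", "MW"),
  nsd = c(
    # de novo nucleotide synthesis (V_max reported; K reconstructed)
    "V_max_1a", "V_max_1b", "V_max_2b", "V_max_2f",
    "V_max_3b", "V_max_3f", "V_max_4", "V_max_5",
    "K_1a_glc", "K_1a_gln", "K_1b_glc", "K_1b_gln",
    "K_2f_adp", "K_2b_amp",
    "K_3f_adp", "K_3f_glc", "K_3b_atp",
    "K_4_glc", "K_4_gln", "K_5_utp", "K_5_gln",
    # NSD synthesis (V_max reported except CMP-Neu5Ac; K reconstructed)
    "V_max_UDPGlc", "V_max_UDPGal", "V_max_UDPGlcNAc", "V_max_UDPGalNAc",
    "V_max_GDPMan", "V_max_GDPFuc", "V_max_CMPNeu5Ac",
    "K_UDPGlcNAc_glc", "K_UDPGlcNAc_gln", "K_UDPGlcNAc_utp",
    "K_UDPGlc_glc", "K_UDPGlc_utp",
    "K_GDPMan_glc", "K_GDPMan_gtp",
    "K_UDPGalNAc_UDPGlcNAc",
    "K_CMPNeu5Ac_UDPGlcNAc", "K_CMPNeu5Ac_gln",
    "K_UDPGal_UDPGlc", "K_GDPFuc_GDPMan",
    "Ki_CMPNeu5Ac", "Ki_GDPFuc",
    # Golgi transport of NSDs
    paste0("K_TP_", .NSD_SPECIES),
    "Ki_CMPNeu5Ac_UDPGlcNAc_TP",
    paste0("N_glyc_", .NSD_SPECIES),
    paste0("N_mab_", .NSD_MAB_TRANSPORT),
    "N_glyc_cell", "N_glyc_mAb",
    # nucleotide/NSD stoichiometric demands on intracellular pools
    "N_glc_ATP", "N_glc_GTP", "N_glc_UTP",
    "N_glc_UDPGlcNAc", "N_glc_UDPGlc", "N_glc_GDPMan",
    "N_gln_ATP", "N_gln_CTP", "N_gln_GTP", "N_gln_UTP",
    "N_gln_UDPGlcNAc", "N_gln_CMPNeu5Ac",
    "N_GTP_GDPMan", "N_UTP_UDPGlc", "N_UTP_UDPGlcNAc",
    "N_CTP_CMPNeu5Ac", "N_UDPGlcNAc_CMPNeu5Ac",
    # non-glycosylation metabolic drains and glutamine synthesis
    "V_met_glc", "K_met_glc", "V_met_gln", "K_met_gln",
    "q_gln_syn_frac", "V_cell"),
  golgi = c(paste0("E_", c("ManI", "ManII", "GnTI", "GnTII", "GalT", "FucT")),
            paste0("kcat_", c("ManI", "ManII", "GnTI", "GnTII", "GalT", "FucT")),
            "Kd_ManI", "Kd_ManII", "Kd_GnTI", "Kd_GnTII",
            "Kd_GalT_a1A", "Kd_GalT_a1B", "Kd_GalT_a2A", "Kd_FucT",
            "Km_GnTI_UDPGlcNAc", "Km_GnTII_UDPGlcNAc",
            "Km_GalT_UDPGal", "Km_FucT_GDPFuc",
            "tau", "inletConc", "volumeScale")
)

.param_defaults <- function(regime = c("36.5C", "32C")) {
  regime <- match.arg(regime)
  hot <- regime == "36.5C"
  pick <- function(a, b) if (hot) a else b

  growth <- c(
    mu_max   = pick(6.50e-2, 2.86e-2),   # reported
    mu_d_max = pick(4.00e-1, 1.01e-2),   # reported
    K_lysis  = pick(7.78e-2, 2.28e-2),   # reported
    K_glc = 0.5, K_lac = 0.1, K_asn = 0.5, K_glu = 0.3,
    KI_amm = 15.0, KI_lac = 60.0,
    K_d_amm = 200.0)

  aa <- c(
    Y_xv_asn = 3e9,  Y_xv_asp = 6e9, Y_xv_arg = 8e9, Y_xv_glu = 5e9,
    Y_xv_gln = 4e9,  Y_xv_lys = 6e9, Y_xv_pro = 7e9,
    m_asn = 3.0e-13, m_asp = 2e-13, m_arg = 2e-13, m_glu = 3e-13,
    m_gln = 5.0e-13, m_lys = 2e-13, m_pro = 2e-13,
    nu_asn = 25, nu_asp = 25, nu_arg = 20, nu_glu = 15,
    nu_gln = 30, nu_lys = 40, nu_pro = 30)
  metabolism <- c(c(
    Y_xv_glc = 2.0e8,
    Y_xv_lac = pick(5.0e8, 2.0e8),
    Y_xv_amm = 4.0e9,
    Y_lac_glc = pick(1.64, 8.66e-4),     # reported
    Y_asp_asn = 0.8,
    m_glc = 2.0e-11,
    k_T_lac = pick(3.0e-12, 8.0e-12)), aa)

  mab <- c(
    S_H = pick(13.54, 21.09), S_L = pick(85.77, 1.16e2),   # reported
    T_H = pick(1.61, 4.98e2), T_L = pick(4.28e-1, 1.70e2), # reported
    K_H = pick(2.65e-2, 7.66e-3),                          # reported
    K_L = pick(2.07e-2, 5.00e-15),                         # reported
    K_A = pick(1.20e-1, 2.54e-2),                          # reported
    K_ER = pick(5.24e2, 2.89e3), K_G = pick(4.24e3, 9.37e3), # reported
    N_H = 60, N_L = 72,
    epsilon2 = pick(1.0, 0.9),
    MW = 1.5e5)

  nsd <- c(
    V_max_1a = pick(6.59e5, 6.00e6),     # reported
    V_max_1b = pick(1.92e12, 3.28e14),   # reported
    V_max_2b = pick(3.40e6, 3.02e4),     # reported
    V_max_2f = pick(2.20e9, 6.49e7),     # reported
    V_max_3b = pick(1.14, 8.16e-1),      # reported
    V_max_3f = pick(23.71, 29.85),       # reported
    V_max_4  = pick(4.38e2, 1.88e2),     # reported
    V_max_5  = pick(1.22e6, 7.24e4),     # reported
    K_1a_glc = 5e6, K_1a_gln = 5e6,
    K_1b_glc = 1.2e10, K_1b_gln = 1.2e10,
    K_2f_adp = 6.6e13, K_2b_amp = 2.3e9,
    K_3f_adp = 2e3, K_3f_glc = 3e3, K_3b_atp = 1e4,
    K_4_glc = 5e4, K_4_gln = 5e4,
    K_5_utp = 1e7, K_5_gln = 1e7,
    V_max_UDPGlc    = pick(2.00, 1.00e-9),    # reported
    V_max_UDPGal    = pick(4.24e-5, 1.00e-12),# reported
    V_max_UDPGlcNAc = pick(49.73, 2.29),      # reported
    V_max_UDPGalNAc = pick(5.65e-3, 1.46e-3), # reported
    V_max_GDPMan    = pick(8.47, 1.86e-1),    # reported
    V_max_GDPFuc    = pick(11.91, 5.23),      # reported
    V_max_CMPNeu5Ac = pick(5.0e-2, 2.0e-2),
    K_UDPGlcNAc_glc = 3e4, K_UDPGlcNAc_gln = 5e3, K_UDPGlcNAc_utp = 3e3,
    K_UDPGlc_glc = 5e3, K_UDPGlc_utp = 5e4,
    K_GDPMan_glc = 3e4, K_GDPMan_gtp = 2e4,
    K_UDPGalNAc_UDPGlcNAc = 3e2,
    K_CMPNeu5Ac_UDPGlcNAc = 2e3, K_CMPNeu5Ac_gln = 5e3,
    K_UDPGal_UDPGlc = 1e3,
    K_GDPFuc_GDPMan = 3e2,
    Ki_CMPNeu5Ac = 5e2, Ki_GDPFuc = 1e2,
    K_TP_UDPGlc = 500, K_TP_UDPGal = 1000, K_TP_UDPGlcNAc = 500,
    K_TP_UDPGalNAc = 200, K_TP_GDPMan = 200, K_TP_GDPFuc = 200,
    K_TP_CMPNeu5Ac = 200,
    Ki_CMPNeu5Ac_UDPGlcNAc_TP = 2000,
    N_glyc_UDPGlc = 0.2, N_glyc_UDPGal = 2, N_glyc_UDPGlcNAc = 4,
    N_glyc_UDPGalNAc = 0.5, N_glyc_GDPMan = 1.5, N_glyc_GDPFuc = 0.5,
    N_glyc_CMPNeu5Ac = 1,
    N_mab_UDPGlcNAc = 4, N_mab_UDPGlc = 0.1, N_mab_UDPGal = 0.35,
    N_mab_GDPFuc = 0.9, N_mab_GDPMan = 3,
    N_glyc_cell = pick(1.38e-12, 2.07e-12),   # reported
    N_glyc_mAb = 2,                            # reported
    N_glc_ATP = 1, N_glc_GTP = 1, N_glc_UTP = 1,
    N_glc_UDPGlcNAc = 2, N_glc_UDPGlc = 1, N_glc_GDPMan = 1,
    N_gln_ATP = 0.2, N_gln_CTP = 1, N_gln_GTP = 2, N_gln_UTP = 1,
    N_gln_UDPGlcNAc = 1, N_gln_CMPNeu5Ac = 1,
    N_GTP_GDPMan = 1, N_UTP_UDPGlc = 1, N_UTP_UDPGlcNAc = 1,
    N_CTP_CMPNeu5Ac = 1, N_UDPGlcNAc_CMPNeu5Ac = 1,
    V_met_glc = 120, K_met_glc = 2e3,
    V_met_gln = 40, K_met_gln = 2e3,
    q_gln_syn_frac = 0.2,
    V_cell = 2.0e-12)

  golgi <- c(
    E_ManI  = pick(1.38e-1, 3.86e-1),  # reported
    E_ManII = pick(3.42e-1, 60.00),    # reported
    E_GnTI  = pick(1.44e-1, 51.01),    # reported
    E_GnTII = pick(12.94, 12.76),      # reported
    E_GalT  = pick(14.55, 1.93),       # reported
    E_FucT  = pick(6.23, 1.60e2),      # reported
    kcat_ManI = 4000, kcat_ManII = 800, kcat_GnTI = 1.2e4,
    kcat_GnTII = 20, kcat_GalT = 1.2, kcat_FucT = 4e4,
    Kd_ManI  = pick(15.05, 12.75),          # reported
    Kd_ManII = pick(1.12e-6, 3.78e-6),      # reported
    Kd_GnTI  = 100,
    Kd_GnTII = pick(1.00e-1, 5.76e-4),      # reported
    Kd_GalT_a1A = pick(4.66e3, 3.94e3),     # reported
    Kd_GalT_a1B = pick(1.84, 24.47),        # reported
    Kd_GalT_a2A = pick(18.43, 2.85e2),      # reported
    Kd_FucT = 1.34e4,                       # reported (both regimes)
    Km_GnTI_UDPGlcNAc = 0.02, Km_GnTII_UDPGlcNAc = 0.02,
    Km_GalT_UDPGal = 0.2, Km_FucT_GDPFuc = 0.005,
    tau = 0.33, inletConc = 10, volumeScale = 1)

  new("ParameterSet", temperature = regime,
      growth = growth, metabolism = metabolism, mab = mab,
      nsd = nsd, golgi = golgi)
}

#' Default parameter sets for the two temperature regimes
#'
#' Returns the package's built-in parameter set for the physiological
#' (\code{"36.5C"}) or mild-hypothermic (\code{"32C"}) regime. Published
#' two-temperature estimates are used where available (growth/death/lysis
#' rates, lactate yield, antibody synthesis constants, nucleotide and NSD
#' maximum rates, Golgi enzyme concentrations and dissociation constants);
#' the remaining constants are reconstructed defaults documented in the
#' methods vignette.
#'
#' @param regime \code{"36.5C"} or \code{"32C"}.
#' @return a [ParameterSet-class].
#' @examples
#' p36 <- defaultParameters("36.5C")
#' getParam(p36, "growth.mu_max")
#' @export
defaultParameters <- function(regime = c("36.5C", "32C")) {
  obj <- .param_defaults(match.arg(regime))
  validObject(obj)
  obj
}

#' Get or set a parameter by dotted path
#'
#' Parameters are addressed as \code{"module.name"},
#' e.g. \code{"growth.mu_max"} or \code{"golgi.E_GalT"}.
#'
#' @param params a [ParameterSet-class].
#' @param name dotted parameter path (or vector of paths for
#'   \code{getParam}).
#' @param value replacement value (scalar, non-negative).
#' @return \code{getParam}: numeric vector of values; \code{setParam}: the
#'   modified \code{ParameterSet}.
#' @export
getParam <- function(params, name) {
  vapply(name, function(nm) {
    parts <- .split_param(nm)
    v <- slot(params, parts[1])
    if (!parts[2] %in% names(v))
      stop(sprintf("unknown parameter '%s'", nm), call. = FALSE)
    unname(v[parts[2]])
  }, numeric(1))
}

#' @rdname getParam
#' @export
setParam <- function(params, name, value) {
  stopifnot(length(name) == length(value))
  for (i in seq_along(name)) {
    parts <- .split_param(name[i])
    v <- slot(params, parts[1])
    if (!parts[2] %in% names(v))
      stop(sprintf("unknown parameter '%s'", name[i]), call. = FALSE)
    v[parts[2]] <- value[i]
    slot(params, parts[1]) <- v
  }
  validObject(params)
  params
}

.split_param <- function(nm) {
  parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
  if (length(parts) < 2 || !parts[1] %in% c("growth", "metabolism", "mab",
                                            "nsd", "golgi"))
    stop(sprintf("parameter path '%s' must be module.name", nm), call. = FALSE)
  c(parts[1], paste(parts[-1], collapse = "."))
}

#' Units of model parameters
#'
#' @param name dotted parameter path(s); \code{NULL} returns the full table.
#' @return character vector of unit strings, or a data.frame of all
#'   parameters and units.
#' @export
paramUnits <- function(name = NULL) {
  u <- .PARAM_UNITS
  if (is.null(name)) {
    return(data.frame(parameter = names(u), unit = unname(u),
                      row.names = NULL))
  }
  out <- u[name]
  names(out) <- name
  out[is.na(out)] <- "unknown"
  out
}

.PARAM_UNITS <- local({
  u <- c(
    "growth.mu_max" = "h^-1", "growth.mu_d_max" = "h^-1",
    "growth.K_lysis" = "h^-1",
    "growth.K_glc" = "mM", "growth.K_lac" = "mM", "growth.K_asn" = "mM",
    "growth.K_glu" = "mM", "growth.KI_amm" = "mM", "growth.KI_lac" = "mM",
    "growth.K_d_amm" = "mM",
    "metabolism.Y_xv_glc" = "cell mmol^-1",
    "metabolism.Y_xv_lac" = "cell mmol^-1",
    "metabolism.Y_xv_amm" = "cell mmol^-1",
    "metabolism.Y_lac_glc" = "mmol mmol^-1",
    "metabolism.Y_asp_asn" = "mmol mmol^-1",
    "metabolism.m_glc" = "mmol cell^-1 h^-1",
    "metabolism.k_T_lac" = "mmol cell^-1 h^-1 mM^-1",
    "mab.S_H" = "mRNA gene^-1 h^-1", "mab.S_L" = "mRNA gene^-1 h^-1",
    "mab.T_H" = "chain mRNA^-1 h^-1", "mab.T_L" = "chain mRNA^-1 h^-1",
    "mab.K_H" = "h^-1", "mab.K_L" = "h^-1",
    "mab.K_A" = "cell molecule^-1 h^-1",
    "mab.K_ER" = "h^-1", "mab.K_G" = "h^-1",
    "mab.N_H" = "effective gene copies", "mab.N_L" = "effective gene copies",
    "mab.epsilon2" = "dimensionless", "mab.MW" = "g mol^-1",
    "nsd.N_glyc_cell" = "mmol cell^-1", "nsd.N_glyc_mAb" = "mol mol^-1",
    "nsd.V_cell" = "L cell^-1", "nsd.q_gln_syn_frac" = "dimensionless",
    "golgi.tau" = "h", "golgi.inletConc" = "uM",
    "golgi.volumeScale" = "dimensionless")
  for (nm in grep("^V_max_|^V_met_", .PARAM_NAMES$nsd, value = TRUE))
    u[paste0("nsd.", nm)] <- "mmol L_cell^-1 h^-1"
  for (nm in grep("^K", .PARAM_NAMES$nsd, value = TRUE))
    u[paste0("nsd.", nm)] <- "uM"
  for (nm in grep("^N_", .PARAM_NAMES$nsd, value = TRUE))
    if (!paste0("nsd.", nm) %in% names(u))
      u[paste0("nsd.", nm)] <- "mmol mmol^-1"
  for (nm in grep("^E_", .PARAM_NAMES$golgi, value = TRUE))
    u[paste0("golgi.", nm)] <- "uM"
  for (nm in grep("^kcat_", .PARAM_NAMES$golgi, value = TRUE))
    u[paste0("golgi.", nm)] <- "h^-1"
  for (nm in grep("^K[dm]_", .PARAM_NAMES$golgi, value = TRUE))
    u[paste0("golgi.", nm)] <- "uM"
  for (nm in grep("^(Y_xv|m)_", .PARAM_NAMES$metabolism, value = TRUE))
    if (!paste0("metabolism.", nm) %in% names(u))
      u[paste0("metabolism.", nm)] <-
        if (grepl("^Y", nm)) "cell mmol^-1" else "mmol cell^-1 h^-1"
  for (nm in grep("^nu_", .PARAM_NAMES$metabolism, value = TRUE))
    u[paste0("metabolism.", nm)] <- "mmol mmol_mAb^-1"
  u
})

#' Read and write parameter sets as YAML
#'
#' The on-disk layout mirrors the module partition: one mapping per module,
#' plus a \code{temperature} label. Units are checked on load against the
#' package registry (unknown parameter names are rejected).
#'
#' @param params a [ParameterSet-class].
#' @param path file path.
#' @return \code{readParameters} returns a [ParameterSet-class];
#'   \code{writeParameters} returns \code{path} invisibly.
#' @export
writeParameters <- function(params, path) {
  x <- list(temperature = params@temperature)
  for (mod in c("growth", "metabolism", "mab", "nsd", "golgi"))
    x[[mod]] <- as.list(slot(params, mod))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname writeParameters
#' @export
readParameters <- function(path) {
  x <- yaml::read_yaml(path)
  base <- .param_defaults(if (identical(x$temperature, "32C")) "32C" else "36.5C")
  obj <- base
  if (!is.null(x$temperature)) obj@temperature <- x$temperature
  for (mod in c("growth", "metabolism", "mab", "nsd", "golgi")) {
    if (is.null(x[[mod]])) next
    v <- unlist(x[[mod]])
    unknown <- setdiff(names(v), .PARAM_NAMES[[mod]])
    if (length(unknown))
      stop(sprintf("unknown %s parameters in %s: %s", mod, path,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    sv <- slot(obj, mod)
    sv[names(v)] <- v
    slot(obj, mod) <- sv
  }
  validObject(obj)
  obj
}
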