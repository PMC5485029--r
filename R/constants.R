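# Central state-vector layout and unit conversions.
# Time is hours throughout; extracellular concentrations mM; intracellular
# concentrations uM; per-cell antibody species in molecules per cell;
# secreted mAb in mg L^-1; volume in L.

.STATE_CULTURE <- c("V", "Xv", "Xt",
                    "Glc", "Lac", "Amm",
                    "Asn", "Asp", "Arg", "Glu", "Gln", "Lys", "Pro",
                    "mAb")

.STATE_MAB <- c("mRNA_H", "mRNA_L", "HC", "LC", "H2", "H2L", "H2L2",
                "GolgiMab")

.STATE_INTRA <- c("Glc_int", "Gln_int",
                  "ATP", "ADP", "AMP", "GTP", "UTP", "CTP",
                  "UDPGlc", "UDPGal", "UDPGlcNAc", "UDPGalNAc",
                  "GDPMan", "GDPFuc", "CMPNeu5Ac")

.STATE_ALL <- c(.STATE_CULTURE, .STATE_MAB, .STATE_INTRA)

.AMINO_ACIDS <- c("Asn", "Asp", "Arg", "Glu", "Gln", "Lys", "Pro")

.NSD_SPECIES <- c("UDPGlc", "UDPGal", "UDPGlcNAc", "UDPGalNAc",
                  "GDPMan", "GDPFuc", "CMPNeu5Ac")

# NSDs whose Golgi transport serves both host-cell and mAb glycans; the
# remaining two (UDP-GalNAc, CMP-Neu5Ac) serve host-cell glycans only.
.NSD_MAB_TRANSPORT <- c("UDPGlcNAc", "UDPGlc", "UDPGal", "GDPFuc", "GDPMan")

.GLYCOFORMS_REPORTED <- c("Man5", "G0", "G0F", "G1F", "G2F", "other")

# Avogadro's number expressed per mmol: molecules mmol^-1
.NA_PER_MMOL <- 6.02214076e20

# uM per mM
.UM_PER_MM <- 1e3

.VALID_SPECIES <- c(.STATE_ALL,
                    paste0("glyco_", .GLYCOFORMS_REPORTED))

.MEASUREMENT_COLS <- c("time_h", "species", "value", "sd")

# Simple Michaelis-Menten saturation term; returns 0 at s = 0 even when k = 0.
.sat <- function(s, k) {
  r <- s / (k + s)
  r[s <= 0] <- 0
  r
}
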