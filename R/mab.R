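# Structured antibody synthesis: transcription -> translation ->
# HC2-LC-LC assembly -> ER export -> Golgi transit -> secretion.
# Per-cell species (molecules cell^-1) are diluted by growth (-mu * X).

#' Antibody-module right-hand side
#'
#' Mass-action kinetics of the heavy-chain (HC) / light-chain (LC) pathway:
#' transcription from N effective gene copies, first-order mRNA decay,
#' translation proportional to mRNA, bimolecular assembly
#' HC+HC -> H2, H2+LC -> H2L, H2L+LC -> H2L2 sharing a single assembly
#' constant K_A, first-order ER-to-Golgi export (K_ER) and Golgi-to-medium
#' secretion (K_G). All per-cell pools carry a growth-dilution term.
#'
#' @param state named numeric of the per-cell antibody species
#'   (molecules cell^-1).
#' @param mu specific growth rate (h^-1).
#' @param p mAb parameter vector (slot \code{mab} of a
#'   [ParameterSet-class]).
#' @return named derivatives; attribute \code{"q_mAb"} carries the specific
#'   productivity (mg cell^-1 h^-1) implied by the secretion flux.
#' @export
mabRHS <- function(state, mu, p) {
  s <- pmax(state, 0)
  rTH <- p[["T_H"]] * s[["mRNA_H"]]
  rTL <- p[["T_L"]] * s[["mRNA_L"]]
  rA1 <- p[["K_A"]] * s[["HC"]] * s[["HC"]]
  rA2 <- p[["K_A"]] * s[["H2"]] * s[["LC"]]
  rA3 <- p[["K_A"]] * s[["H2L"]] * s[["LC"]]
  rER <- p[["K_ER"]] * s[["H2L2"]]
  rG  <- p[["K_G"]] * s[["GolgiMab"]]
  d <- c(
    mRNA_H = p[["S_H"]] * p[["N_H"]] - (p[["K_H"]] + mu) * s[["mRNA_H"]],
    mRNA_L = p[["S_L"]] * p[["N_L"]] - (p[["K_L"]] + mu) * s[["mRNA_L"]],
    HC = rTH - 2 * rA1 - mu * s[["HC"]],
    LC = rTL - rA2 - rA3 - mu * s[["LC"]],
    H2 = rA1 - rA2 - mu * s[["H2"]],
    H2L = rA2 - rA3 - mu * s[["H2L"]],
    H2L2 = rA3 - rER - mu * s[["H2L2"]],
    GolgiMab = rER - rG - mu * s[["GolgiMab"]])
  # secretion flux in molecules cell^-1 h^-1 -> mg cell^-1 h^-1
  attr(d, "q_mAb") <- rG / .NA_PER_MMOL * p[["MW"]]
  d
}

#' Specific antibody productivity from a trajectory
#'
#' \eqn{q_{mAb}(t) = \frac{d(V \cdot [mAb])/dt}{X_v V}} computed by
#' centered finite differences of the cumulative secreted mass on the
#' trajectory time grid (forward/backward differences at the ends).
#'
#' @param trajectory a [Trajectory-class] containing mAb, Xv and V.
#' @return data.frame with columns \code{time_h} and \code{q_mAb}
#'   (mg cell^-1 h^-1).
#' @export
specificProductivity <- function(trajectory) {
  st <- trajectory@states
  tt <- trajectory@times
  if (length(tt) < 2)
    stop("specificProductivity needs at least two time points", call. = FALSE)
  mass <- st[, "V"] * st[, "mAb"]
  n <- length(tt)
  dmass <- numeric(n)
  dmass[1] <- (mass[2] - mass[1]) / (tt[2] - tt[1])
  dmass[n] <- (mass[n] - mass[n - 1]) / (tt[n] - tt[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    dmass[i] <- (mass[i + 1] - mass[i - 1]) / (tt[i + 1] - tt[i - 1])
  }
  q <- dmass / (st[, "Xv"] * st[, "V"])
  data.frame(time_h = tt, q_mAb = q)
}
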