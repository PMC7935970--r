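# Independent oracles used across the suite. Each is deliberately written
# from first principles (or frozen from an external tool) so it shares no
# code with the implementation it checks.

# Average residue masses frozen from pyteomics (IUPAC element weights),
# independent of the package's internal table.
ORACLE_AA_AVG <- c(
  A = 71.07802, C = 103.14281, D = 115.08757, E = 129.11418, F = 147.17420,
  G = 57.05140, H = 137.13952, I = 113.15787, K = 128.17252, L = 113.15787,
  M = 131.19604, N = 114.10280, P = 97.11537, Q = 128.12942, R = 156.18592,
  S = 87.07742, T = 101.10404, V = 99.13125, W = 186.21031, Y = 163.17360
)
ORACLE_WATER_AVG <- 18.01529

oracle_mass_avg <- function(sequence) {
  sum(ORACLE_AA_AVG[strsplit(sequence, "")[[1]]]) + ORACLE_WATER_AVG
}

# Textbook pooled-variance two-sample t test.
oracle_pooled_t <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * var(g1) + (n2 - 1) * var(g2)) / (n1 + n2 - 2)
  tstat <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tstat, p = 2 * pt(-abs(tstat), df), df = df)
}

# Exact heterodimer equilibrium (quadratic root), written independently.
oracle_dimer_eq <- function(A_tot, B_tot, Kd) {
  # solve d^2 - (A+B+Kd) d + A*B = 0, physical root
  s <- A_tot + B_tot + Kd
  (s - sqrt(s^2 - 4 * A_tot * B_tot)) / 2
}

# Gillespie SSA for the solution scheme A + B <-> AB, B -> Bp.
# Concentrations in uM, omega = copies per uM. Returns matrix of species
# counts (per uM) at the requested times, averaged over nruns.
oracle_gillespie <- function(kon, koff, kp, A0, B0, times, omega = 50,
                             nruns = 10) {
  nt <- length(times)
  acc <- matrix(0, nt, 4, dimnames = list(NULL, c("A", "B", "AB", "Bp")))
  for (run in seq_len(nruns)) {
    nA <- round(A0 * omega); nB <- round(B0 * omega); nAB <- 0L; nBp <- 0L
    t <- times[1]
    out <- matrix(NA_real_, nt, 4)
    i <- 1L
    while (i <= nt) {
      a1 <- (kon / omega) * nA * nB  # association
      a2 <- koff * nAB               # dissociation
      a3 <- kp * nB                  # phosphorylation of free B
      a0 <- a1 + a2 + a3
      t_next <- if (a0 > 0) t + rexp(1, a0) else Inf
      while (i <= nt && times[i] < t_next) {
        out[i, ] <- c(nA, nB, nAB, nBp) / omega
        i <- i + 1L
      }
      if (!is.finite(t_next)) break
      t <- t_next
      u <- runif(1) * a0
      if (u < a1) {
        nA <- nA - 1L; nB <- nB - 1L; nAB <- nAB + 1L
      } else if (u < a1 + a2) {
        nA <- nA + 1L; nB <- nB + 1L; nAB <- nAB - 1L
      } else {
        nB <- nB - 1L; nBp <- nBp + 1L
      }
    }
    acc <- acc + out
  }
  acc / nruns
}

# Trapezoidal integral of (y - straight line through flank medians), using
# pracma's quadrature as the independent integrator.
oracle_peak_area <- function(z, v, window, flank = 3L) {
  lo <- window[1]; hi <- window[length(window)]
  left <- max(1, lo - flank):(lo - 1)
  right <- (hi + 1):min(length(v), hi + flank)
  xl <- median(z[left]); yl <- median(v[left])
  xr <- median(z[right]); yr <- median(v[right])
  base <- yl + (yr - yl) / (xr - xl) * (z[window] - xl)
  pracma::trapz(z[window], v[window] - base)
}

# A small deterministic toy peptide for register tests.
toy_peptide <- function(seq = "AAAAAAA", offset = 0L, ...) {
  registered_peptide("toy", seq, register_offset = offset, ...)
}
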