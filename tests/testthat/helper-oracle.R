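# Independent brute-force oracle for the candidate generator: full enumeration
# of the element lattice with its own mass table and rule logic, written as a
# plain nested filter over expand.grid output. Deliberately naive.

ORACLE_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                 O = 15.9949146221, S = 31.97207069, P = 30.97376151)

oracle_hill <- function(df) {
  ord <- c("C", "H", "N", "O", "P", "S")
  apply(as.matrix(df[ord]), 1L, function(cnt) {
    keep <- cnt > 0
    paste0(ord[keep], ifelse(cnt[keep] == 1, "", cnt[keep]), collapse = "")
  })
}

brute_force_candidates <- function(target_mass, tol_ppm, ranges, rules) {
  g <- expand.grid(C = ranges$C[1]:ranges$C[2], H = ranges$H[1]:ranges$H[2],
                   N = ranges$N[1]:ranges$N[2], O = ranges$O[1]:ranges$O[2],
                   S = ranges$S[1]:ranges$S[2], P = ranges$P[1]:ranges$P[2],
                   KEEP.OUT.ATTRS = FALSE)
  mass <- g$C * ORACLE_MASS["C"] + g$H * ORACLE_MASS["H"] +
    g$N * ORACLE_MASS["N"] + g$O * ORACLE_MASS["O"] +
    g$S * ORACLE_MASS["S"] + g$P * ORACLE_MASS["P"]
  lo <- target_mass * (1 - tol_ppm * 1e-6)
  hi <- target_mass * (1 + tol_ppm * 1e-6)
  keep <- mass >= lo & mass <= hi
  g <- g[keep, , drop = FALSE]
  mass <- mass[keep]

  ok <- g$H <= 2 * g$C + 2 + g$N + g$P
  hc <- g$H / g$C
  ok <- ok & hc >= rules$hc_min & hc <= rules$hc_max
  ok <- ok & g$O / g$C <= rules$oc_max
  ok <- ok & g$N / g$C <= rules$nc_max
  ok <- ok & g$S / g$C <= rules$sc_max
  d <- 1 + g$C - g$H / 2 + g$N / 2 + g$P / 2
  if (rules$require_integer_dbe || rules$parity_rule) ok <- ok & d == floor(d)
  ok <- ok & d >= rules$dbe_min
  g <- g[ok, , drop = FALSE]
  mass <- mass[ok]

  err <- (mass - target_mass) / target_mass * 1e6
  hill <- if (nrow(g)) oracle_hill(g) else character()
  ord <- order(abs(err), g$N + g$S + g$P, g$O, hill)
  data.frame(formula = hill[ord], g[ord, , drop = FALSE],
             calc_mass = mass[ord], error_ppm = err[ord], row.names = NULL)
}

# Small fixture: an exact CH2 ladder of a given base formula, as [M-H]- peaks.
ladder_peaks <- function(base, n, intensity = 100) {
  f <- parse_formula(base)
  counts <- do.call(rbind, lapply(seq_len(n) - 1L, function(k) {
    data.frame(C = f$C + k, H = f$H + 2L * k, N = f$N, O = f$O, S = f$S, P = f$P)
  }))
  data.frame(mz = ion_mz(counts, "neg"),
             intensity = rep_len(intensity, n))
}
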