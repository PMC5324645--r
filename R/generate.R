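#' Element count ranges for the formula generator
#'
#' Inclusive per-element (min, max) count bounds defining the search lattice.
#' Defaults are appropriate for negative-mode natural organic matter work:
#' C 1-100, H 0-200, N 0-5, O 0-30, S 0-2, P 0-0 (phosphorus disabled).
#'
#' @param C,H,N,O,S,P length-2 integer vectors `c(min, max)`.
#' @return An `element_ranges` object.
#' @export
element_ranges <- function(C = c(1, 100), H = c(0, 200), N = c(0, 5),
                           O = c(0, 30), S = c(0, 2), P = c(0, 0)) {
  rng <- list(C = C, H = H, N = N, O = O, S = S, P = P)
  for (el in ELEMENTS) {
    r <- as.integer(rng[[el]])
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < 0) {
      stop(sprintf("invalid range for %s: need c(min, max), 0 <= min <= max", el),
           call. = FALSE)
    }
    rng[[el]] <- r
  }
  if (rng$C[1] < 1L) rng$C[1] <- 1L
  structure(rng, class = "element_ranges")
}

#' Heuristic plausibility rules for candidate formulae
#'
#' Chemical filters applied to every candidate, in the spirit of the
#' heuristic-rule ("seven golden rules" style) filtering used for small-molecule
#' formula assignment: a valence cap H <= 2C + 2 + N + P, elemental ratio
#' windows, integer non-negative DBE, and even-electron neutral parity.
#' Every rule is toggleable; defaults suit natural organic matter.
#'
#' @param hc_min,hc_max H/C ratio bounds (defaults 0.3 and 3.0).
#' @param oc_max O/C upper bound (default 1.2).
#' @param nc_max N/C upper bound (default 0.5).
#' @param sc_max S/C upper bound (default 0.2).
#' @param require_integer_dbe require DBE to be an integer (default TRUE).
#' @param dbe_min minimum DBE (default 0).
#' @param parity_rule enforce even-electron neutral parity, implemented as
#'   "DBE is a non-negative integer" (default TRUE).
#' @return A `heuristic_rules` object.
#' @export
heuristic_rules <- function(hc_min = 0.3, hc_max = 3.0, oc_max = 1.2,
                            nc_max = 0.5, sc_max = 0.2,
                            require_integer_dbe = TRUE, dbe_min = 0,
                            parity_rule = TRUE) {
  stopifnot(hc_min >= 0, hc_min < hc_max, oc_max >= 0, nc_max >= 0, sc_max >= 0)
  structure(list(
    hc_min = hc_min, hc_max = hc_max, oc_max = oc_max,
    nc_max = nc_max, sc_max = sc_max,
    require_integer_dbe = isTRUE(require_integer_dbe),
    dbe_min = dbe_min, parity_rule = isTRUE(parity_rule)
  ), class = "heuristic_rules")
}

# Vectorised rule check on count columns; returns logical.
rules_pass <- function(C, H, N, O, S, P, rules) {
  ok <- H <= 2 * C + 2 + N + P
  hc <- H / C
  ok <- ok & hc >= rules$hc_min & hc <= rules$hc_max
  ok <- ok & O / C <= rules$oc_max
  ok <- ok & N / C <= rules$nc_max
  ok <- ok & S / C <= rules$sc_max
  d <- 1 + C - H / 2 + N / 2 + P / 2
  if (rules$require_integer_dbe || rules$parity_rule) {
    ok <- ok & (d == floor(d))
  }
  ok & d >= rules$dbe_min
}

#' Check formulae against heuristic rules
#'
#' @param f formulae (anything accepted by [as_mol_formula()]).
#' @param rules a [heuristic_rules()] object.
#' @return logical vector, TRUE where every enabled rule passes.
#' @export
passes_rules <- function(f, rules = heuristic_rules()) {
  f <- as_mol_formula(f)
  rules_pass(f$C, f$H, f$N, f$O, f$S, f$P, rules)
}

#' Generate candidate molecular formulae for a neutral mass
#'
#' Enumerates every formula in the element-range lattice whose exact mass lies
#' within `tol_ppm` of `target_mass` and which passes every enabled heuristic
#' rule. Heteroatom counts are iterated and the admissible hydrogen count range
#' is solved analytically from the mass window, which is output-equivalent to
#' full enumeration.
#'
#' @param target_mass target neutral mass, Da.
#' @param tol_ppm mass tolerance in ppm (> 0).
#' @param ranges an [element_ranges()] object.
#' @param rules a [heuristic_rules()] object.
#' @param cap maximum number of candidates before a `vankrev_cap_exceeded`
#'   condition is signalled (default 10000); bounds pathological tolerances.
#' @return data frame of candidates sorted by `|error_ppm|` ascending (ties:
#'   fewer heteroatoms N+S+P, then fewer O, then Hill string), with columns
#'   `formula`, `C`..`P`, `calc_mass`, `error_ppm`.
#' @export
generate_candidates <- function(target_mass, tol_ppm,
                                ranges = element_ranges(),
                                rules = heuristic_rules(),
                                cap = 10000L) {
  stopifnot(length(target_mass) == 1L, target_mass > 0, tol_ppm > 0)
  lo <- target_mass * (1 - tol_ppm * 1e-6)
  hi <- target_mass * (1 + tol_ppm * 1e-6)

  grid <- expand.grid(
    C = seq.int(ranges$C[1], ranges$C[2]),
    N = seq.int(ranges$N[1], ranges$N[2]),
    O = seq.int(ranges$O[1], ranges$O[2]),
    S = seq.int(ranges$S[1], ranges$S[2]),
    P = seq.int(ranges$P[1], ranges$P[2]),
    KEEP.OUT.ATTRS = FALSE
  )
  rest <- as.numeric(as.matrix(grid) %*% ISOTOPE_MASS[c("C", "N", "O", "S", "P")])
  mh <- ISOTOPE_MASS[["H"]]
  h_lo <- pmax(ranges$H[1], ceiling((lo - rest) / mh - 1e-12))
  h_hi <- pmin(ranges$H[2], floor((hi - rest) / mh + 1e-12))
  keep <- which(h_lo <= h_hi)

  cols <- c("C", "H", "N", "O", "S", "P")
  if (length(keep) == 0L) {
    out <- data.frame(formula = character(), C = integer(), H = integer(),
                      N = integer(), O = integer(), S = integer(), P = integer(),
                      calc_mass = numeric(), error_ppm = numeric())
    return(out)
  }

  nh <- h_hi[keep] - h_lo[keep] + 1L
  idx <- rep.int(keep, nh)
  H <- unlist(lapply(seq_along(keep), function(i) {
    seq.int(h_lo[keep[i]], h_hi[keep[i]])
  }), use.names = FALSE)
  cand <- grid[idx, , drop = FALSE]
  cand$H <- as.integer(H)
  mass <- rest[idx] + H * mh
  in_win <- mass >= lo & mass <= hi
  cand <- cand[in_win, , drop = FALSE]
  mass <- mass[in_win]

  ok <- rules_pass(cand$C, cand$H, cand$N, cand$O, cand$S, cand$P, rules)
  cand <- cand[ok, , drop = FALSE]
  mass <- mass[ok]

  if (nrow(cand) > cap) {
    cond <- structure(
      class = c("vankrev_cap_exceeded", "error", "condition"),
      list(message = sprintf(
        "candidate cap exceeded: %d candidates > cap %d at mass %.5f, tol %.3g ppm",
        nrow(cand), cap, target_mass, tol_ppm), call = sys.call(-1))
    )
    stop(cond)
  }

  err <- (mass - target_mass) / target_mass * 1e6
  hill <- if (nrow(cand)) format_formula(cand[cols]) else character()
  ord <- order(abs(err), cand$N + cand$S + cand$P, cand$O, hill)
  out <- data.frame(
    formula = hill[ord],
    cand[ord, cols, drop = FALSE],
    calc_mass = mass[ord],
    error_ppm = err[ord],
    row.names = NULL
  )
  out
}

#' Minimum candidate spacing at a given m/z
#'
#' Generates all rule-passing candidates within `window_ppm` of the neutral
#' mass corresponding to `target_mz` and returns the smallest pairwise mass
#' difference between distinct candidates. This is the key diagnostic for
#' choosing an assignment error threshold: a tolerance safely below the
#' minimum spacing makes the assignment unambiguous at that m/z.
#'
#' @param target_mz target m/z, Th.
#' @param mode ionisation mode passed to [neutral_mass()], or `"neutral"` to
#'   treat `target_mz` as a neutral mass directly.
#' @param window_ppm half-width of the search window in ppm.
#' @param ranges,rules,cap see [generate_candidates()].
#' @return A list with `spacing_da` and `spacing_ppm` (both `Inf` when fewer
#'   than two candidates survive), the achieving `pair` of Hill strings (or
#'   NULL), `n_candidates`, and the `candidates` table itself.
#' @export
min_candidate_spacing <- function(target_mz, mode = "neg", window_ppm = 20,
                                  ranges = element_ranges(),
                                  rules = heuristic_rules(),
                                  cap = 10000L) {
  stopifnot(window_ppm > 0)
  target <- if (identical(mode, "neutral")) target_mz else neutral_mass(target_mz, mode)
  cand <- generate_candidates(target, window_ppm, ranges, rules, cap)
  if (nrow(cand) < 2L) {
    return(list(spacing_da = Inf, spacing_ppm = Inf, pair = NULL,
                n_candidates = nrow(cand), candidates = cand))
  }
  m <- sort(cand$calc_mass)
  gaps <- diff(m)
  i <- which.min(gaps)
  ord <- order(cand$calc_mass)
  list(
    spacing_da = gaps[i],
    spacing_ppm = gaps[i] / target * 1e6,
    pair = cand$formula[ord][c(i, i + 1L)],
    n_candidates = nrow(cand),
    candidates = cand
  )
}
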