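#' Specification of a synthetic SRFA-like mixture
#'
#' Parameters for [make_mixture()], which emulates a negative-mode ESI-FTICR
#' centroid spectrum of a complex natural-organic-matter sample such as
#' Suwannee River Fulvic Acid: many CH2-homologous CHO/CHNO/CHOS series
#' between m/z 200 and 700, ppm-scale Gaussian mass error, 13C1 isotopologue
#' satellites, a log-normal intensity distribution (a few dominant peaks over
#' dense low-abundance "grass"), and unassignable noise peaks.
#'
#' @param n_series number of CH2 homologous series.
#' @param series_len length-2 range of members per series.
#' @param class_weights named sampling weights for the CHO, CHNO and CHOS
#'   compound classes.
#' @param mz_range m/z window, Th.
#' @param sigma_ppm Gaussian mass-error standard deviation, ppm.
#' @param isotopologues emit one 13C1 satellite per parent peak?
#' @param iso_ratio_sd log-scale noise on the satellite/parent intensity ratio.
#' @param n_noise number of unassignable noise peaks.
#' @param intensity_meanlog,intensity_sdlog log-normal intensity parameters
#'   (arbitrary units).
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return A `mixture_spec` object.
#' @export
mixture_spec <- function(n_series = 50, series_len = c(5, 15),
                         class_weights = c(CHO = 0.7, CHNO = 0.2, CHOS = 0.1),
                         mz_range = c(200, 700), sigma_ppm = 0.2,
                         isotopologues = TRUE, iso_ratio_sd = 0.05,
                         n_noise = 100,
                         intensity_meanlog = log(1e5), intensity_sdlog = 1.2,
                         seed = 1L) {
  stopifnot(n_series >= 1, length(series_len) == 2L,
            series_len[1] >= 1, series_len[1] <= series_len[2],
            length(mz_range) == 2L, mz_range[1] > 0, mz_range[1] < mz_range[2],
            sigma_ppm >= 0, n_noise >= 0)
  structure(list(
    n_series = as.integer(n_series), series_len = as.integer(series_len),
    class_weights = class_weights, mz_range = as.numeric(mz_range),
    sigma_ppm = sigma_ppm, isotopologues = isTRUE(isotopologues),
    iso_ratio_sd = iso_ratio_sd, n_noise = as.integer(n_noise),
    intensity_meanlog = intensity_meanlog, intensity_sdlog = intensity_sdlog,
    seed = as.integer(seed)
  ), class = "mixture_spec")
}

# KMD shift of a 13C1 satellite relative to its parent (satellites occupy the
# adjacent z* stratum, displaced by this amount).
SATELLITE_KMD_SHIFT <- 1 - C13_DELTA * 14 / CH2_MASS

#' Generate a synthetic mixture with known ground truth
#'
#' Draws `n_series` CH2 homologous series from the rule-passing CHNOS formula
#' lattice (each series one heteroatom class, members differing by CH2),
#' converts to negative-mode ion m/z, perturbs every emitted peak by Gaussian
#' ppm error, optionally adds one 13C1 satellite per parent at
#' `C * 1.07% * parent intensity` (log-normal ratio noise), and adds uniform
#' noise peaks constrained to be unassignable (no rule-passing candidate
#' within 2 ppm, and at least 3 ppm from every emitted true peak). Series are
#' sampled so that their (z*, KMD) strata — and those of their satellites —
#' are mutually separated, as distinct homologous series are in real spectra.
#'
#' @param spec a [mixture_spec()].
#' @return list of class `synthetic_mixture` with `peaks` (data frame `mz`,
#'   `intensity`, sorted by m/z) and `truth` (one row per peak: `mz`,
#'   `mz_true`, `intensity`, `kind` in parent/isotopologue/noise, `formula`
#'   Hill string or NA, `series` id or NA, `parent_row` row index of a
#'   satellite's parent or NA).
#' @export
make_mixture <- function(spec = mixture_spec()) {
  stopifnot(inherits(spec, "mixture_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  rules <- heuristic_rules()
  lo <- spec$mz_range[1]; hi <- spec$mz_range[2]
  classes <- names(spec$class_weights)

  occupied <- data.frame(z = integer(), kmd = numeric())
  slot_free <- function(z, kmd) {
    same <- occupied$z == z
    !any(same & abs(occupied$kmd - kmd) < 0.002)
  }
  wrap_z <- function(z) as.integer((z %% 14) - 14)

  emitted <- character()
  series_list <- list()
  tries <- 0L
  while (length(series_list) < spec$n_series) {
    tries <- tries + 1L
    if (tries > 20000L) {
      cond <- structure(
        class = c("vankrev_infeasible", "error", "condition"),
        list(message = "mixture spec infeasible: could not place requested series",
             call = sys.call(-1)))
      stop(cond)
    }
    cls <- sample(classes, 1L, prob = spec$class_weights)
    L <- sample(seq.int(spec$series_len[1], spec$series_len[2]), 1L)
    C0 <- sample(6:30, 1L)
    O0 <- sample(2:16, 1L)
    N0 <- if (cls == "CHNO") sample(1:3, 1L) else 0L
    S0 <- if (cls == "CHOS") sample(1:2, 1L) else 0L
    d <- sample(0:15, 1L)
    H0 <- 2L + 2L * C0 + N0 - 2L * d
    if (H0 < 1L) next
    k <- seq_len(L) - 1L
    counts <- data.frame(C = C0 + k, H = H0 + 2L * k, N = N0, O = O0, S = S0,
                         P = 0L)
    if (!all(rules_pass(counts$C, counts$H, counts$N, counts$O, counts$S,
                        counts$P, rules))) next
    mz <- ion_mz(counts, "neg")
    if (mz[1] < lo || mz[L] > hi) next
    hill <- format_formula(counts)
    if (any(hill %in% emitted)) next
    kc <- kendrick(mz[1])
    if (!slot_free(kc$z_star, kc$kmd)) next
    sat_z <- wrap_z(kc$z_star + 1L)
    sat_kmd <- kc$kmd - SATELLITE_KMD_SHIFT
    if (spec$isotopologues && !slot_free(sat_z, sat_kmd)) next

    occupied <- rbind(occupied, data.frame(z = c(kc$z_star, sat_z),
                                           kmd = c(kc$kmd, sat_kmd)))
    emitted <- c(emitted, hill)
    series_list[[length(series_list) + 1L]] <-
      list(counts = counts, mz = mz, hill = hill)
  }

  rows <- list()
  for (si in seq_along(series_list)) {
    s <- series_list[[si]]
    L <- nrow(s$counts)
    int <- stats::rlnorm(L, spec$intensity_meanlog, spec$intensity_sdlog)
    rows[[si]] <- data.frame(
      mz_true = s$mz, intensity = int, kind = "parent",
      formula = s$hill, series = si, parent_key = NA_integer_,
      C = s$counts$C
    )
  }
  truth <- do.call(rbind, rows)
  truth$key <- seq_len(nrow(truth))

  if (spec$isotopologues) {
    par <- truth
    sat <- data.frame(
      mz_true = par$mz_true + C13_DELTA,
      intensity = par$C * C13_ABUNDANCE * par$intensity *
        exp(stats::rnorm(nrow(par), 0, spec$iso_ratio_sd)),
      kind = "isotopologue", formula = NA_character_,
      series = par$series, parent_key = par$key, C = NA_integer_
    )
    sat$key <- max(truth$key) + seq_len(nrow(sat))
    truth <- rbind(truth, sat)
  }

  if (spec$n_noise > 0) {
    noise_mz <- numeric(0)
    guard <- 0L
    while (length(noise_mz) < spec$n_noise) {
      guard <- guard + 1L
      if (guard > 200L * spec$n_noise) {
        stop("could not place unassignable noise peaks", call. = FALSE)
      }
      m <- stats::runif(1L, lo, hi)
      if (any(abs(m - truth$mz_true) / truth$mz_true < 3e-6)) next
      if (length(noise_mz) &&
          any(abs(m - noise_mz) / noise_mz < 3e-6)) next
      cand <- generate_candidates(neutral_mass(m, "neg"), 2, element_ranges(),
                                  rules, cap = 100000L)
      if (nrow(cand) > 0L) next
      noise_mz <- c(noise_mz, m)
    }
    noise <- data.frame(
      mz_true = noise_mz,
      intensity = stats::rlnorm(spec$n_noise, spec$intensity_meanlog - 1.5,
                                spec$intensity_sdlog / 2),
      kind = "noise", formula = NA_character_, series = NA_integer_,
      parent_key = NA_integer_, C = NA_integer_
    )
    noise$key <- max(truth$key) + seq_len(nrow(noise))
    truth <- rbind(truth, noise)
  }

  truth$mz <- truth$mz_true * (1 + stats::rnorm(nrow(truth), 0, spec$sigma_ppm) * 1e-6)
  ord <- order(truth$mz)
  truth <- truth[ord, , drop = FALSE]
  truth$parent_row <- match(truth$parent_key, truth$key)
  truth$key <- NULL
  truth$C <- NULL
  row.names(truth) <- NULL
  truth <- truth[c("mz", "mz_true", "intensity", "kind", "formula", "series",
                   "parent_row")]

  structure(list(
    peaks = data.frame(mz = truth$mz, intensity = truth$intensity),
    truth = truth,
    spec = spec
  ), class = "synthetic_mixture")
}

#' @export
print.synthetic_mixture <- function(x, ...) {
  tab <- table(x$truth$kind)
  cat("<synthetic_mixture> ", nrow(x$peaks), " peaks (",
      paste(names(tab), as.integer(tab), sep = ": ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
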