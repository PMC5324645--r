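#' Coerce to a centroid peak list
#'
#' @param x a data frame (or matrix) whose first two columns, or columns named
#'   `mz` and `intensity`, give centroid m/z (Th) and intensity.
#' @return data frame with numeric columns `mz` and `intensity`.
#' @export
as_peaks <- function(x) {
  x <- as.data.frame(x)
  if (!all(c("mz", "intensity") %in% names(x))) {
    if (ncol(x) < 2L) stop("peak list needs columns mz and intensity", call. = FALSE)
    names(x)[1:2] <- c("mz", "intensity")
  }
  out <- data.frame(mz = as.numeric(x$mz), intensity = as.numeric(x$intensity))
  if (anyNA(out)) stop("peak list contains non-numeric values", call. = FALSE)
  if (any(out$mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
  if (any(out$intensity < 0)) stop("peak intensity must be non-negative", call. = FALSE)
  out
}

#' Assignment configuration
#'
#' Bundles every tunable of the homologous-series assigner.
#'
#' @param tol_ppm_seed ppm tolerance used when generating candidate formulae
#'   for series seeding (default 0.5; must not exceed `tol_ppm_member`).
#' @param tol_ppm_member ppm tolerance for accepting a propagated +/- CH2
#'   assignment, and for isotopologue matching (default 1.0).
#' @param kmd_tol Kendrick mass defect link threshold for single-linkage series
#'   clustering within a z* stratum (default 0.0005).
#' @param mode ionisation mode, `"neg"` or `"pos"` (see [ion_mz()]).
#' @param ranges an [element_ranges()] object.
#' @param rules a [heuristic_rules()] object.
#' @param min_rel_intensity peaks below this fraction of the base peak are not
#'   considered for assignment. Default 0: the low-abundance "grass" carries
#'   most of the chemical diversity of a complex mixture, so it is kept.
#' @param cap generator candidate cap, see [generate_candidates()].
#' @return An `assignment_config` object.
#' @export
assignment_config <- function(tol_ppm_seed = 0.5, tol_ppm_member = 1.0,
                              kmd_tol = 0.0005, mode = "neg",
                              ranges = element_ranges(),
                              rules = heuristic_rules(),
                              min_rel_intensity = 0, cap = 10000L) {
  stopifnot(tol_ppm_seed > 0, tol_ppm_member > 0, tol_ppm_seed <= tol_ppm_member,
            kmd_tol > 0, min_rel_intensity >= 0, min_rel_intensity < 1)
  structure(list(
    tol_ppm_seed = tol_ppm_seed, tol_ppm_member = tol_ppm_member,
    kmd_tol = kmd_tol, mode = normalize_mode(mode),
    ranges = ranges, rules = rules,
    min_rel_intensity = min_rel_intensity, cap = as.integer(cap)
  ), class = "assignment_config")
}

#' Group peaks into CH2 homologous series
#'
#' Computes Kendrick coordinates for every peak, stratifies by z*, and
#' single-linkage clusters the Kendrick mass defects within each stratum
#' (in one dimension this is: sort by KMD and cut where consecutive values
#' differ by more than `kmd_tol`). Every peak lands in exactly one series;
#' singleton series are allowed.
#'
#' @param peaks a peak list (see [as_peaks()]).
#' @param cfg an [assignment_config()].
#' @return list of series; each has `z_star`, `kmd_centroid` (mean member KMD)
#'   and `members`, integer row indices into `peaks` ordered by m/z.
#' @export
group_series <- function(peaks, cfg = assignment_config()) {
  peaks <- as_peaks(peaks)
  if (nrow(peaks) == 0L) return(list())
  kc <- kendrick(peaks$mz)
  out <- list()
  for (z in sort(unique(kc$z_star))) {
    idx <- which(kc$z_star == z)
    ord <- idx[order(kc$kmd[idx])]
    kmds <- kc$kmd[ord]
    cut <- c(0L, which(diff(kmds) > cfg$kmd_tol), length(ord))
    for (j in seq_len(length(cut) - 1L)) {
      members <- ord[(cut[j] + 1L):cut[j + 1L]]
      members <- members[order(peaks$mz[members])]
      out[[length(out) + 1L]] <- list(
        z_star = z,
        kmd_centroid = mean(kc$kmd[members]),
        members = members
      )
    }
  }
  out
}

empty_monoisotopic <- function() {
  data.frame(mz = numeric(), intensity = numeric(), formula = character(),
             calc_mz = numeric(), error_ppm = numeric(),
             C = integer(), H = integer(), N = integer(), O = integer(),
             S = integer(), P = integer(),
             dbe = numeric(), ai_mod = numeric(), hc = numeric(), oc = numeric(),
             class = character(), provenance = character())
}

empty_isotopologues <- function() {
  data.frame(mz = numeric(), intensity = numeric(), parent_mz = numeric(),
             parent_formula = character(), isotope = character(),
             ratio_obs_exp = numeric())
}

# Build the monoisotopic assignment rows for given peaks + formula counts.
make_assigned_rows <- function(peaks, idx, counts, provenance, mode) {
  f <- validate_mol_formula(counts)
  calc_mz <- ion_mz(f, mode)
  rat <- elemental_ratios(f)
  data.frame(
    mz = peaks$mz[idx], intensity = peaks$intensity[idx],
    formula = format_formula(f),
    calc_mz = calc_mz,
    error_ppm = ppm_error(peaks$mz[idx], calc_mz),
    f[ELEMENTS],
    dbe = dbe(f), ai_mod = ai_mod(f), hc = rat$hc, oc = rat$oc,
    class = heteroatom_class(f),
    provenance = provenance,
    row.names = NULL
  )
}

#' Assign molecular formulae to a peak list
#'
#' The full Kendrick/z* homologous-series assignment pipeline:
#' \enumerate{
#'   \item group peaks into CH2 homologous series ([group_series()]);
#'   \item within each series, pick as seed the member with the fewest
#'     candidate formulae at `tol_ppm_seed` (ties: most intense, then lowest
#'     m/z) and take the generator's best candidate as the seed formula;
#'   \item propagate the seed formula +/- k CH2 to every other member,
#'     accepting iff the implied formula exists (counts in range), passes every
#'     enabled heuristic rule and matches within `tol_ppm_member`;
#'   \item annotate 13C1 isotopologues among the remaining peaks
#'     ([annotate_isotopologues()]).
#' }
#' The result partitions the input: every peak is exactly one of monoisotopic,
#' isotopologue, or unassigned. The procedure is deterministic for a fixed
#' configuration.
#'
#' @param peaks a peak list (see [as_peaks()]).
#' @param cfg an [assignment_config()].
#' @return An `assignment_set` object: list with data frames `monoisotopic`,
#'   `isotopologues`, `unassigned`, plus the `config` and `n_peaks`.
#' @export
assign_formulas <- function(peaks, cfg = assignment_config()) {
  peaks <- as_peaks(peaks)
  n <- nrow(peaks)
  if (n == 0L) {
    return(new_assignment_set(empty_monoisotopic(), empty_isotopologues(),
                              peaks, cfg, 0L))
  }

  considered <- rep(TRUE, n)
  if (cfg$min_rel_intensity > 0) {
    considered <- peaks$intensity >= cfg$min_rel_intensity * max(peaks$intensity)
  }
  series <- group_series(peaks[considered, , drop = FALSE], cfg)
  considered_idx <- which(considered)

  neutral <- neutral_mass(peaks$mz, cfg$mode)
  assigned <- vector("list", length(series))
  rC <- cfg$ranges$C; rH <- cfg$ranges$H

  for (si in seq_along(series)) {
    members <- considered_idx[series[[si]]$members]
    cands <- lapply(members, function(i) {
      tryCatch(
        generate_candidates(neutral[i], cfg$tol_ppm_seed, cfg$ranges,
                            cfg$rules, cfg$cap),
        vankrev_cap_exceeded = function(e) {
          warning(sprintf("series %d: %s; series left unassigned", si,
                          conditionMessage(e)), call. = FALSE)
          NULL
        }
      )
    })
    if (any(vapply(cands, is.null, logical(1)))) next
    ncand <- vapply(cands, nrow, integer(1))
    eligible <- which(ncand > 0L)
    if (length(eligible) == 0L) next

    # seed: fewest candidates, then most intense, then lowest m/z
    ord <- eligible[order(ncand[eligible], -peaks$intensity[members[eligible]],
                          peaks$mz[members[eligible]])]
    seed_pos <- ord[1L]
    seed_idx <- members[seed_pos]
    seed <- cands[[seed_pos]][1L, , drop = FALSE]

    k <- as.integer(round((neutral[members] - seed$calc_mass) / CH2_MASS))
    C <- seed$C + k; H <- seed$H + 2L * k
    valid <- C >= max(1L, rC[1]) & C <= rC[2] & H >= rH[1] & H <= rH[2]
    counts <- data.frame(C = pmax(C, 1L), H = pmax(H, 0L), N = seed$N,
                         O = seed$O, S = seed$S, P = seed$P)
    calc_neutral <- as.numeric(as.matrix(counts) %*% ISOTOPE_MASS[ELEMENTS])
    calc_mz <- calc_neutral + if (cfg$mode == "neg") -PROTON_MASS else PROTON_MASS
    err <- ppm_error(peaks$mz[members], calc_mz)
    ok <- valid & abs(err) <= cfg$tol_ppm_member &
      rules_pass(counts$C, counts$H, counts$N, counts$O, counts$S, counts$P,
                 cfg$rules)
    if (cfg$mode == "neg") ok <- ok & counts$H >= 1L
    if (!any(ok)) next
    prov <- ifelse(members == seed_idx, "seed", "propagated")
    rows <- make_assigned_rows(peaks, members[ok], counts[ok, , drop = FALSE],
                               prov[ok], cfg$mode)
    rows$.idx <- members[ok]
    assigned[[si]] <- rows
  }

  assigned <- assigned[!vapply(assigned, is.null, logical(1))]
  mono <- if (length(assigned)) do.call(rbind, assigned) else {
    m0 <- empty_monoisotopic(); m0$.idx <- integer(); m0
  }
  mono <- mono[order(mono$mz), , drop = FALSE]
  row.names(mono) <- NULL

  left <- peaks[setdiff(seq_len(n), mono$.idx), , drop = FALSE]
  mono$.idx <- NULL
  iso <- annotate_isotopologues(mono, left, cfg)
  new_assignment_set(mono, iso$isotopologues, iso$unassigned, cfg, n)
}

new_assignment_set <- function(mono, iso, unassigned, cfg, n_peaks) {
  unassigned <- unassigned[, c("mz", "intensity"), drop = FALSE]
  row.names(unassigned) <- NULL
  structure(list(monoisotopic = mono, isotopologues = iso,
                 unassigned = unassigned, config = cfg,
                 n_peaks = as.integer(n_peaks)),
            class = "assignment_set")
}

#' Annotate 13C1 isotopologue satellites
#'
#' For each monoisotopic assignment with `c` carbons, searches the leftover
#' peaks for a satellite at parent m/z + 1.0033548 within `tol_ppm_member`
#' whose intensity lies within `[0.2, 3.0]` times the expected
#' `c * 0.0107 * parent intensity`. The band is deliberately loose because
#' centroid intensities are noisy. Each leftover peak is attached to at most
#' one parent (closest in ppm wins). Second isotopologues (two 13C, one 18O)
#' are not searched and legitimately remain unassigned.
#'
#' @param assigned monoisotopic assignment table (as in an `assignment_set`).
#' @param leftovers peak list of still-unassigned peaks.
#' @param cfg an [assignment_config()].
#' @param ratio_band numeric length-2: acceptance band as multiples of the
#'   expected isotopologue/parent intensity ratio.
#' @return list with `isotopologues` (annotation table) and `unassigned`
#'   (remaining peaks).
#' @export
annotate_isotopologues <- function(assigned, leftovers, cfg = assignment_config(),
                                   ratio_band = c(0.2, 3.0)) {
  leftovers <- as_peaks(leftovers)
  if (nrow(assigned) == 0L || nrow(leftovers) == 0L) {
    return(list(isotopologues = empty_isotopologues(), unassigned = leftovers))
  }
  exp_mz <- assigned$mz + C13_DELTA
  exp_int <- assigned$C * C13_ABUNDANCE * assigned$intensity

  best_parent <- rep(NA_integer_, nrow(leftovers))
  best_ppm <- rep(Inf, nrow(leftovers))
  for (p in seq_len(nrow(assigned))) {
    dppm <- abs(ppm_error(leftovers$mz, exp_mz[p]))
    in_band <- dppm <= cfg$tol_ppm_member &
      leftovers$intensity >= ratio_band[1] * exp_int[p] &
      leftovers$intensity <= ratio_band[2] * exp_int[p]
    better <- in_band & dppm < best_ppm
    best_parent[better] <- p
    best_ppm[better] <- dppm[better]
  }

  hit <- which(!is.na(best_parent))
  iso <- if (length(hit)) {
    p <- best_parent[hit]
    data.frame(
      mz = leftovers$mz[hit], intensity = leftovers$intensity[hit],
      parent_mz = assigned$mz[p], parent_formula = assigned$formula[p],
      isotope = "13C1",
      ratio_obs_exp = leftovers$intensity[hit] / exp_int[p],
      row.names = NULL
    )
  } else empty_isotopologues()
  list(isotopologues = iso,
       unassigned = leftovers[setdiff(seq_len(nrow(leftovers)), hit), ,
                              drop = FALSE])
}

#' @export
print.assignment_set <- function(x, ...) {
  cat("<assignment_set>\n")
  cat(sprintf("  peaks:         %d\n", x$n_peaks))
  cat(sprintf("  monoisotopic:  %d\n", nrow(x$monoisotopic)))
  cat(sprintf("  isotopologues: %d\n", nrow(x$isotopologues)))
  cat(sprintf("  unassigned:    %d\n", nrow(x$unassigned)))
  invisible(x)
}

#' @export
summary.assignment_set <- function(object, ...) {
  mono <- object$monoisotopic
  cat("Formula assignment summary\n")
  print(object)
  if (nrow(mono)) {
    cat(sprintf("  m/z range:     %.4f - %.4f\n", min(mono$mz), max(mono$mz)))
    cat(sprintf("  |error| ppm:   median %.3f, max %.3f\n",
                stats::median(abs(mono$error_ppm)), max(abs(mono$error_ppm))))
    cd <- class_distribution(object)
    cat("  top heteroatom classes:\n")
    print(utils::head(cd, 5))
  }
  invisible(object)
}

#' Plot an assignment set
#'
#' Quick-look base-graphics van Krevelen diagram of the monoisotopic
#' assignments: points sized by relative abundance, coloured by m/z.
#'
#' @param x an `assignment_set`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.assignment_set <- function(x, ...) {
  mono <- x$monoisotopic
  if (nrow(mono) == 0L) {
    graphics::plot(NA, xlim = c(0, 1.3), ylim = c(0, 2.5),
                   xlab = "O/C", ylab = "H/C", main = "van Krevelen (empty)")
    return(invisible(x))
  }
  pal <- grDevices::hcl.colors(100, "viridis")
  col <- pal[cut(mono$mz, 100, labels = FALSE)]
  cex <- 0.3 + 1.7 * sqrt(mono$intensity / max(mono$intensity))
  graphics::plot(mono$oc, mono$hc, col = col, cex = cex, pch = 16,
                 xlab = "O/C", ylab = "H/C", main = "van Krevelen", ...)
  invisible(x)
}
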