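#' Heteroatom class label
#'
#' Canonical label built from the non-CH element counts in element order
#' N, O, S, P, with counts always shown (e.g. `"O5"`, `"N1O3"`). Pure
#' hydrocarbons are labelled `"CH"`.
#'
#' @param f formulae (anything accepted by [as_mol_formula()]).
#' @return character vector of class labels.
#' @export
heteroatom_class <- function(f) {
  f <- as_mol_formula(f)
  els <- c("N", "O", "S", "P")
  m <- as.matrix(f[els])
  out <- apply(m, 1L, function(cnt) {
    keep <- cnt > 0L
    if (!any(keep)) "CH" else paste0(els[keep], cnt[keep], collapse = "")
  })
  as.character(out)
}

#' Heteroatomic class distribution
#'
#' Tabulates the heteroatom classes of a set of assignments, with both the
#' formula count and the summed relative intensity per class (whether a study
#' should weight classes by count or by intensity is sample-dependent, so both
#' are returned). Sorted by count descending, ties by label.
#'
#' @param x an `assignment_set`, or a data frame with columns `class` (or the
#'   element counts to derive it) and optionally `intensity`.
#' @return data frame with columns `class`, `count`, `rel_intensity` (fraction
#'   of total assigned intensity; sums to 1 when any intensity is present).
#' @export
class_distribution <- function(x) {
  if (inherits(x, "assignment_set")) x <- x$monoisotopic
  x <- as.data.frame(x)
  if (nrow(x) == 0L) {
    return(data.frame(class = character(), count = integer(),
                      rel_intensity = numeric()))
  }
  cls <- if (!is.null(x$class)) x$class else heteroatom_class(x)
  int <- if (!is.null(x$intensity)) x$intensity else rep(0, nrow(x))
  agg <- stats::aggregate(list(count = rep(1L, length(cls)), intensity = int),
                          by = list(class = cls), FUN = sum)
  tot <- sum(agg$intensity)
  agg$rel_intensity <- if (tot > 0) agg$intensity / tot else 0
  agg <- agg[order(-agg$count, agg$class), c("class", "count", "rel_intensity")]
  row.names(agg) <- NULL
  agg
}

#' Default van Krevelen compound-class regions
#'
#' Rectangles in (O/C, H/C) space tentatively associated with compound
#' classes. The literature anchors are approximate (lipids around O/C < 0.2
#' with H/C near 2; carbohydrates around O/C 1, H/C 2; condensed aromatics at
#' O/C < 0.2, H/C < 1); the concrete half-open boxes here are this package's
#' defaults and are fully user-configurable. Regions are tested in list order
#' and the first hit wins.
#'
#' @return data frame with columns `label`, `oc_min`, `oc_max`, `hc_min`,
#'   `hc_max`; bounds are half-open `[min, max)`.
#' @export
vk_regions <- function() {
  data.frame(
    label = c("lipid-like", "carbohydrate-like", "condensed-aromatic-like"),
    oc_min = c(0.0, 0.7, 0.0),
    oc_max = c(0.2, 1.3, 0.2),
    hc_min = c(1.7, 1.7, 0.2),
    hc_max = c(2.3, 2.3, 1.0)
  )
}

#' Classify formulae into van Krevelen regions
#'
#' @param f formulae (anything accepted by [as_mol_formula()]), or a data
#'   frame with columns `oc` and `hc`.
#' @param regions region table as produced by [vk_regions()].
#' @return character vector: a region label or `"unclassified"`.
#' @export
vk_region <- function(f, regions = vk_regions()) {
  if (is.data.frame(f) && all(c("oc", "hc") %in% names(f)) &&
      !inherits(f, "mol_formula")) {
    oc <- f$oc; hc <- f$hc
  } else {
    r <- elemental_ratios(f)
    oc <- r$oc; hc <- r$hc
  }
  out <- rep("unclassified", length(oc))
  for (i in rev(seq_len(nrow(regions)))) {
    hit <- oc >= regions$oc_min[i] & oc < regions$oc_max[i] &
      hc >= regions$hc_min[i] & hc < regions$hc_max[i]
    out[hit] <- regions$label[i]
  }
  out
}

#' Glyph size for abundance encoding
#'
#' Maps intensity to display size with square-root scaling, so that glyph
#' area is linear in abundance (the perceptually honest encoding); the base
#' peak maps to `s_max` and zero intensity to `s_min`. Linear scaling is
#' available via `scaling = "linear"`.
#'
#' @param intensity numeric intensities, `0 <= intensity <= max_intensity`.
#' @param max_intensity base peak intensity (> 0).
#' @param s_min,s_max output size range.
#' @param scaling `"sqrt"` (default) or `"linear"`.
#' @return numeric vector of sizes, monotone in intensity.
#' @export
glyph_size <- function(intensity, max_intensity, s_min = 3, s_max = 18,
                       scaling = c("sqrt", "linear")) {
  scaling <- match.arg(scaling)
  stopifnot(max_intensity > 0, all(intensity >= 0),
            all(intensity <= max_intensity))
  frac <- intensity / max_intensity
  if (scaling == "sqrt") frac <- sqrt(frac)
  s_min + (s_max - s_min) * frac
}
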