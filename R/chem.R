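# Monoisotopic masses of the most abundant isotope of each supported element,
# pinned so that results are bit-stable across platforms. 12C is exactly 12 by
# definition of the unified atomic mass scale.
ISOTOPE_MASS <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

# Proton mass (1H minus one electron). Ion/neutral conversion must include the
# electron: FTICR mass accuracy is at the ppb level, where 0.55 mDa matters.
PROTON_MASS <- 1.0072765

# Mass of one CH2 repeat unit, from the pinned table.
CH2_MASS <- ISOTOPE_MASS[["C"]] + 2 * ISOTOPE_MASS[["H"]]

# 13C - 12C mass difference and per-carbon 13C abundance.
C13_DELTA <- 1.0033548
C13_ABUNDANCE <- 0.0107

ELEMENTS <- c("C", "H", "N", "O", "S", "P")

# Hill order: carbon, hydrogen, then remaining elements alphabetically.
HILL_ORDER <- c("C", "H", "N", "O", "P", "S")

#' Construct molecular formulae
#'
#' Creates a `mol_formula` object: a table of element counts (C, H, N, O, S, P)
#' for one or more neutral molecules. All chemistry functions in the package
#' (`exact_mass()`, `dbe()`, `ai_mod()`, ...) accept a `mol_formula`, a Hill
#' notation character vector, or anything coercible via [as_mol_formula()].
#'
#' @param C,H,N,O,S,P integer vectors of element counts, recycled to a common
#'   length. Counts must be non-negative and `C >= 1`.
#' @return A `mol_formula` object (a data frame with one row per formula and
#'   integer columns C, H, N, O, S, P).
#' @examples
#' mol_formula(C = 9, H = 10, O = 5)
#' exact_mass(mol_formula(C = 7, H = 6, O = 2))
#' @export
mol_formula <- function(C, H = 0L, N = 0L, O = 0L, S = 0L, P = 0L) {
  counts <- data.frame(
    C = as.integer(C), H = as.integer(H), N = as.integer(N),
    O = as.integer(O), S = as.integer(S), P = as.integer(P)
  )
  validate_mol_formula(counts)
}

validate_mol_formula <- function(counts) {
  m <- as.matrix(counts[ELEMENTS])
  if (anyNA(m)) stop("element counts must not be NA", call. = FALSE)
  if (any(m < 0)) stop("element counts must be non-negative", call. = FALSE)
  if (any(counts$C < 1)) stop("formulae must contain at least one carbon", call. = FALSE)
  structure(counts, class = c("mol_formula", "data.frame"))
}

#' Coerce to a molecular formula table
#'
#' @param x a `mol_formula`, a character vector of Hill-notation formula
#'   strings (e.g. `"C9H10O5"`), or a data frame with columns C, H, N, O, S, P.
#' @return A `mol_formula` object.
#' @export
as_mol_formula <- function(x) {
  if (inherits(x, "mol_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.data.frame(x)) {
    for (el in ELEMENTS) if (is.null(x[[el]])) x[[el]] <- 0L
    counts <- data.frame(lapply(x[ELEMENTS], as.integer))
    return(validate_mol_formula(counts))
  }
  stop("cannot interpret 'x' as molecular formulae", call. = FALSE)
}

#' Parse Hill-notation formula strings
#'
#' Accepts the package's canonical rendering (count digit omitted when 1,
#' e.g. `"CH4"`) as well as explicit unit counts (`"C1H4"`).
#'
#' @param x character vector of formula strings.
#' @return A `mol_formula` object.
#' @export
parse_formula <- function(x) {
  n <- length(x)
  out <- matrix(0L, n, length(ELEMENTS), dimnames = list(NULL, ELEMENTS))
  for (i in seq_len(n)) {
    s <- x[[i]]
    if (is.na(s) || !nzchar(s)) stop("empty formula string", call. = FALSE)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
    parts <- regmatches(s, list(m))[[1]]
    if (sum(nchar(parts)) != nchar(s)) {
      stop(sprintf("cannot parse formula string '%s'", s), call. = FALSE)
    }
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      if (!el %in% ELEMENTS) {
        stop(sprintf("unsupported element '%s' in '%s'", el, s), call. = FALSE)
      }
      cnt <- sub("^[A-Za-z]+", "", p)
      out[i, el] <- out[i, el] + if (nzchar(cnt)) as.integer(cnt) else 1L
    }
  }
  validate_mol_formula(as.data.frame(out))
}

#' Render formulae in Hill notation
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; elements
#' with count zero are omitted and the digit 1 is omitted for unit counts,
#' so `mol_formula(C = 1, H = 4)` renders as `"CH4"`. `parse_formula()`
#' round-trips this rendering exactly.
#'
#' @param f formulae (anything accepted by [as_mol_formula()]).
#' @return character vector of Hill strings.
#' @export
format_formula <- function(f) {
  f <- as_mol_formula(f)
  m <- unname(as.matrix(f[HILL_ORDER]))
  vapply(seq_len(nrow(m)), function(i) {
    cnt <- m[i, ]
    keep <- cnt > 0L
    paste0(HILL_ORDER[keep],
           ifelse(cnt[keep] == 1L, "", as.character(cnt[keep])),
           collapse = "")
  }, character(1))
}

#' @export
format.mol_formula <- function(x, ...) format_formula(x)

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", nrow(x), " formula(e)\n", sep = "")
  print(format_formula(x))
  invisible(x)
}

#' Neutral monoisotopic exact mass
#'
#' Sum of most-abundant-isotope masses times element counts, using the
#' package's pinned isotope mass table.
#'
#' @param f formulae (anything accepted by [as_mol_formula()]).
#' @return numeric vector of neutral masses in Da.
#' @export
exact_mass <- function(f) {
  f <- as_mol_formula(f)
  as.numeric(as.matrix(f[ELEMENTS]) %*% ISOTOPE_MASS[ELEMENTS])
}

normalize_mode <- function(mode) {
  mode <- match.arg(tolower(mode), c("neg", "pos", "negative", "positive"))
  if (mode %in% c("neg", "negative")) "neg" else "pos"
}

#' Ion m/z of a neutral formula
#'
#' Converts a neutral molecule to its singly charged ESI ion: `[M-H]-` in
#' negative mode, `[M+H]+` in positive mode. The conversion uses the proton
#' mass (i.e. includes the electron), as ppb-level FTICR accuracy requires.
#'
#' @param f formulae (anything accepted by [as_mol_formula()]).
#' @param mode `"neg"` (`[M-H]-`, the default, typical for natural organic
#'   matter) or `"pos"` (`[M+H]+`).
#' @return numeric vector of m/z in Th.
#' @export
ion_mz <- function(f, mode = "neg") {
  f <- as_mol_formula(f)
  mode <- normalize_mode(mode)
  if (mode == "neg" && any(f$H < 1)) {
    stop("[M-H]- requires at least one hydrogen", call. = FALSE)
  }
  exact_mass(f) + if (mode == "neg") -PROTON_MASS else PROTON_MASS
}

#' Neutral mass from ion m/z
#'
#' Exact inverse of [ion_mz()] for the same ionisation mode.
#'
#' @param mz numeric vector of m/z in Th.
#' @param mode see [ion_mz()].
#' @return numeric vector of neutral masses in Da.
#' @export
neutral_mass <- function(mz, mode = "neg") {
  mode <- normalize_mode(mode)
  mz + if (mode == "neg") PROTON_MASS else -PROTON_MASS
}

#' Double bond equivalents
#'
#' DBE = 1 + C - H/2 + N/2 + P/2 (rings plus pi bonds); oxygen and sulfur do
#' not contribute. The value is half-integer for formulae that cannot be
#' even-electron neutral molecules; the formula generator filters those out.
#'
#' @param f formulae (anything accepted by [as_mol_formula()]).
#' @return numeric vector of DBE values.
#' @export
dbe <- function(f) {
  f <- as_mol_formula(f)
  1 + f$C - f$H / 2 + f$N / 2 + f$P / 2
}

#' Modified aromaticity index
#'
#' AI_mod = (1 + C - 0.5 O - S - 0.5 H) / (C - 0.5 O - S - N - P), a
#' conservative formula-level aromaticity estimate that treats half the oxygen
#' as non-pi-bonded (carboxyl-like). Degenerate cases (denominator <= 0 or
#' negative numerator) are clamped to 0 so the index is a total function and
#' plots never receive NaN.
#'
#' @param f formulae (anything accepted by [as_mol_formula()]).
#' @return numeric vector of AI_mod values (>= 0).
#' @export
ai_mod <- function(f) {
  f <- as_mol_formula(f)
  num <- 1 + f$C - 0.5 * f$O - f$S - 0.5 * f$H
  den <- f$C - 0.5 * f$O - f$S - f$N - f$P
  out <- ifelse(den <= 0 | num < 0, 0, num / den)
  as.numeric(out)
}

#' Elemental ratios
#'
#' @param f formulae (anything accepted by [as_mol_formula()]).
#' @return data frame with columns `hc` (H/C), `oc` (O/C), `nc` (N/C).
#' @export
elemental_ratios <- function(f) {
  f <- as_mol_formula(f)
  data.frame(hc = f$H / f$C, oc = f$O / f$C, nc = f$N / f$C)
}

# Round half away from zero for positive x; nominal-mass convention.
round_half_up <- function(x) floor(x + 0.5)

#' Kendrick mass coordinates
#'
#' Rescales IUPAC m/z so that the CH2 repeat unit has integer mass 14:
#' `kendrick_mass = mz * 14 / m(CH2)`. The Kendrick mass defect
#' `kmd = nominal_kendrick_mass - kendrick_mass` (nominal = round half up) is
#' then shared by all members of a CH2 homologous series, as is
#' `z_star = (nominal IUPAC mass mod 14) - 14`. Members of one series are
#' therefore found on a single (z*, KMD) stratum.
#'
#' @param mz numeric vector of m/z in Th.
#' @return data frame with columns `kendrick_mass`, `nominal_kendrick_mass`,
#'   `kmd`, `z_star`.
#' @export
kendrick <- function(mz) {
  stopifnot(all(mz > 0))
  km <- mz * 14 / CH2_MASS
  nkm <- round_half_up(km)
  data.frame(
    kendrick_mass = km,
    nominal_kendrick_mass = as.integer(nkm),
    kmd = nkm - km,
    z_star = as.integer(round_half_up(mz) %% 14 - 14)
  )
}

#' Signed mass error in parts per million
#'
#' @param observed,calculated m/z values in Th (`calculated > 0`).
#' @return `(observed - calculated) / calculated * 1e6`.
#' @export
ppm_error <- function(observed, calculated) {
  stopifnot(all(calculated > 0))
  (observed - calculated) / calculated * 1e6
}
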