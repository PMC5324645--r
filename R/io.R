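# Column schemas of the three-file assignment convention. These are the
# package's interoperability surface: any software emitting these columns
# (comma- or tab-delimited) can feed the report builder.
MONO_COLS <- c("mz", "intensity", "formula", "calc_mz", "error_ppm",
               "C", "H", "N", "O", "S", "P",
               "dbe", "ai_mod", "hc", "oc", "class", "provenance")
ISO_COLS <- c("mz", "intensity", "parent_mz", "parent_formula", "isotope",
              "ratio_obs_exp")
UNASSIGNED_COLS <- c("mz", "intensity")

detect_delim <- function(lines) {
  probe <- lines[nzchar(trimws(lines))][1]
  if (grepl("\t", probe)) "\t" else if (grepl(",", probe)) "," else ""
}

#' Read a centroid peak list from delimited text
#'
#' Reads (m/z, intensity) pairs from comma-, tab- or whitespace-delimited
#' text. A header row is detected and skipped. Rows that fail to parse stop
#' with their line numbers; duplicate m/z values are collapsed to the maximum
#' intensity with a warning.
#'
#' @param path path to the peak list file.
#' @return data frame of peaks in file order (columns `mz`, `intensity`).
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0L) {
    stop(sprintf("empty peak list file: %s", path), call. = FALSE)
  }
  delim <- detect_delim(lines)
  split_row <- function(s) {
    if (delim == "") strsplit(trimws(s), "[ \t]+")[[1]]
    else strsplit(s, delim, fixed = TRUE)[[1]]
  }
  first <- split_row(lines[lines_keep[1]])
  has_header <- suppressWarnings(is.na(as.numeric(first[1])))
  data_lines <- if (has_header) lines_keep[-1] else lines_keep
  if (length(data_lines) == 0L) {
    stop(sprintf("peak list file has a header but no data: %s", path),
         call. = FALSE)
  }
  rows <- lapply(data_lines, function(i) {
    fields <- split_row(lines[i])
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    list(line = i, vals = vals, nf = length(fields))
  })
  bad <- vapply(rows, function(r) r$nf < 2L || anyNA(r$vals), logical(1))
  if (any(bad)) {
    stop(sprintf("unparseable peak rows in %s at line(s): %s", path,
                 paste(vapply(rows[bad], `[[`, 0L, "line"), collapse = ", ")),
         call. = FALSE)
  }
  mz <- vapply(rows, function(r) r$vals[1], numeric(1))
  intensity <- vapply(rows, function(r) r$vals[2], numeric(1))
  if (anyDuplicated(mz)) {
    warning(sprintf("%d duplicate m/z value(s) collapsed to max intensity",
                    sum(duplicated(mz))), call. = FALSE)
    agg <- stats::aggregate(intensity, by = list(mz = mz), FUN = max)
    keep <- !duplicated(mz)
    ord_mz <- mz[keep]
    intensity <- agg$x[match(ord_mz, agg$mz)]
    mz <- ord_mz
  }
  as_peaks(data.frame(mz = mz, intensity = intensity))
}

fmt_num <- function(x, digits) {
  ifelse(is.finite(x), formatC(x, format = "f", digits = digits), as.character(x))
}

format_mono_for_write <- function(mono) {
  extra <- setdiff(names(mono), MONO_COLS)
  out <- data.frame(
    mz = fmt_num(mono$mz, 7), intensity = fmt_num(mono$intensity, 4),
    formula = mono$formula, calc_mz = fmt_num(mono$calc_mz, 7),
    error_ppm = fmt_num(mono$error_ppm, 3),
    mono[c("C", "H", "N", "O", "S", "P")],
    dbe = fmt_num(mono$dbe, 1), ai_mod = fmt_num(mono$ai_mod, 4),
    hc = fmt_num(mono$hc, 4), oc = fmt_num(mono$oc, 4),
    class = mono$class, provenance = mono$provenance,
    check.names = FALSE
  )
  if (length(extra)) out <- cbind(out, mono[extra])
  out
}

#' Write an assignment set as three text files
#'
#' Writes the three-file convention: `<prefix>_assigned.tsv` (monoisotopic
#' peak assignments with formulae and all derived metrics),
#' `<prefix>_isotopologues.tsv` (13C1 annotations) and
#' `<prefix>_unassigned.tsv` (remaining detected peaks). Tab-delimited with
#' header rows; m/z written with 7 decimals (sub-ppb at m/z 700), ppm errors
#' with 3.
#'
#' @param set an `assignment_set`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths (named mono/iso/unassigned).
#' @export
write_assignment_set <- function(set, prefix) {
  stopifnot(inherits(set, "assignment_set"))
  paths <- c(mono = paste0(prefix, "_assigned.tsv"),
             iso = paste0(prefix, "_isotopologues.tsv"),
             unassigned = paste0(prefix, "_unassigned.tsv"))
  utils::write.table(format_mono_for_write(set$monoisotopic), paths["mono"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  iso <- set$isotopologues
  iso_out <- data.frame(
    mz = fmt_num(iso$mz, 7), intensity = fmt_num(iso$intensity, 4),
    parent_mz = fmt_num(iso$parent_mz, 7), parent_formula = iso$parent_formula,
    isotope = iso$isotope, ratio_obs_exp = fmt_num(iso$ratio_obs_exp, 4)
  )
  utils::write.table(iso_out, paths["iso"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  un <- set$unassigned
  un_out <- data.frame(mz = fmt_num(un$mz, 7),
                       intensity = fmt_num(un$intensity, 4))
  utils::write.table(un_out, paths["unassigned"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

read_delim_auto <- function(path) {
  lines <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (length(lines) && grepl("\t", lines[1])) "\t" else ","
  utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read an assignment set from the three-file convention
#'
#' Inverse of [write_assignment_set()]. Accepts a prefix (expecting
#' `<prefix>_assigned.tsv` etc.) or explicit paths. Files may be comma- or
#' tab-delimited, as produced by any assignment software matching the column
#' schema. A missing isotopologue file is treated as empty, since external
#' software may not emit one. Extra columns are preserved as opaque
#' annotations.
#'
#' @param prefix path prefix, or NULL if explicit paths are given.
#' @param mono_path,iso_path,unassigned_path explicit file paths (override the
#'   prefix-derived ones).
#' @return An `assignment_set`.
#' @export
read_assignment_set <- function(prefix = NULL, mono_path = NULL,
                                iso_path = NULL, unassigned_path = NULL) {
  if (!is.null(prefix)) {
    if (is.null(mono_path)) mono_path <- paste0(prefix, "_assigned.tsv")
    if (is.null(iso_path)) iso_path <- paste0(prefix, "_isotopologues.tsv")
    if (is.null(unassigned_path)) unassigned_path <- paste0(prefix, "_unassigned.tsv")
  }
  if (is.null(mono_path) || !file.exists(mono_path)) {
    stop("monoisotopic assignment file not found", call. = FALSE)
  }
  mono <- read_delim_auto(mono_path)
  missing_cols <- setdiff(MONO_COLS, names(mono))
  if (length(missing_cols)) {
    stop(sprintf("monoisotopic file lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  mono <- mono[c(MONO_COLS, setdiff(names(mono), MONO_COLS))]
  if (nrow(mono) == 0L) mono <- empty_monoisotopic()

  iso <- if (!is.null(iso_path) && file.exists(iso_path)) {
    x <- read_delim_auto(iso_path)
    if (nrow(x) == 0L) empty_isotopologues() else x[ISO_COLS]
  } else empty_isotopologues()

  un <- if (!is.null(unassigned_path) && file.exists(unassigned_path)) {
    x <- read_delim_auto(unassigned_path)
    if (nrow(x) == 0L) data.frame(mz = numeric(), intensity = numeric())
    else as_peaks(x[UNASSIGNED_COLS])
  } else data.frame(mz = numeric(), intensity = numeric())

  new_assignment_set(mono, iso, un, assignment_config(),
                     nrow(mono) + nrow(iso) + nrow(un))
}

#' Export the report data table
#'
#' Writes the plot-ready record table (one row per monoisotopic assignment,
#' all hover fields, stable column order) as delimited text — the same table
#' embedded in the HTML report's data-table tab and offered there for
#' download.
#'
#' @param model a `report_model` (see [build_report_model()]).
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @return invisibly, `path`.
#' @export
export_data_table <- function(model, path, sep = "\t") {
  stopifnot(inherits(model, "report_model"))
  utils::write.table(model$records, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
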