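#' ChemSpider search URL for a formula
#'
#' Deterministic search URL embedding the Hill-notation formula (URL-encoded).
#' No network access happens until a user follows the link.
#'
#' @param f formulae (anything accepted by [as_mol_formula()]).
#' @return character vector of URLs.
#' @export
chemspider_url <- function(f) {
  hill <- format_formula(as_mol_formula(f))
  vapply(hill, function(s) {
    paste0("https://www.chemspider.com/Search.aspx?q=",
           utils::URLencode(s, reserved = TRUE))
  }, character(1), USE.NAMES = FALSE)
}

#' Build the plot-ready report model
#'
#' Collapses an `assignment_set` into the single record table that drives
#' every panel of the HTML report and the data-table tab: one record per
#' monoisotopic assignment carrying m/z, intensity, relative intensity,
#' formula, carbon and oxygen numbers, elemental ratios, DBE, AI_mod, ppm
#' error, heteroatom class, van Krevelen region and ChemSpider URL, indexed by
#' a shared integer key used for linked selection. Isotopologue and unassigned
#' peaks ride along as overlay series for the coverage tab.
#'
#' @param set an `assignment_set`.
#' @param regions van Krevelen region table, see [vk_regions()].
#' @return A `report_model`: list with `records`, `isotopologues`,
#'   `unassigned`.
#' @export
build_report_model <- function(set, regions = vk_regions()) {
  stopifnot(inherits(set, "assignment_set"))
  mono <- set$monoisotopic
  n <- nrow(mono)
  base <- if (n > 0 && any(mono$intensity > 0)) max(mono$intensity) else 1
  records <- data.frame(
    index = seq_len(n) - 1L,
    mz = mono$mz,
    intensity = mono$intensity,
    rel_intensity = if (n) mono$intensity / base else numeric(),
    formula = mono$formula,
    C = mono$C, O = mono$O,
    hc = mono$hc, oc = mono$oc,
    dbe = mono$dbe, ai_mod = mono$ai_mod,
    error_ppm = mono$error_ppm,
    class = mono$class,
    region = if (n) vk_region(mono, regions) else character(),
    chemspider = if (n) chemspider_url(mono[ELEMENTS]) else character()
  )
  structure(list(
    records = records,
    isotopologues = set$isotopologues[, c("mz", "intensity"), drop = FALSE],
    unassigned = set$unassigned[, c("mz", "intensity"), drop = FALSE]
  ), class = "report_model")
}

#' Coverage-overlay series for the report's second tab
#'
#' Returns the three spectra overlaid on one m/z axis: monoisotopic
#' assignments, annotated isotopologues and unassigned peaks. Series lengths
#' equal the assignment partition sizes, which is how the overlay communicates
#' assignment coverage at a glance.
#'
#' @param model a `report_model`.
#' @return list of three data frames `monoisotopic`, `isotopologue`,
#'   `unassigned`, each with columns `mz`, `intensity`.
#' @export
coverage_overlay <- function(model) {
  stopifnot(inherits(model, "report_model"))
  list(
    monoisotopic = data.frame(mz = model$records$mz,
                              intensity = model$records$intensity),
    isotopologue = model$isotopologues,
    unassigned = model$unassigned
  )
}

# Hover fields shown for each record, in display order.
HOVER_FIELDS <- c("formula", "mz", "intensity", "error_ppm", "dbe", "ai_mod",
                  "class")

#' Build the standalone interactive HTML report
#'
#' Writes a single self-contained HTML document with three tabs:
#' \enumerate{
#'   \item four linked panels — van Krevelen diagram (x = O/C, y = H/C,
#'     colour = m/z, size = relative abundance), centroid mass spectrum,
#'     DBE vs carbon number (colour = oxygen number) and AI_mod vs carbon
#'     number (colour = oxygen number);
#'   \item the assignment-coverage spectrum overlay (monoisotopic /
#'     isotopologue / unassigned);
#'   \item the interactive data table, downloadable as a text file.
#' }
#' All panels and the table are rendered from one embedded JSON record store,
#' so brushing a selection in any panel highlights the same record indices
#' everywhere, including the table. Panels offer drag-to-select, wheel zoom,
#' pan, and a hover readout of each record's key fields; clicking a selected
#' glyph follows its ChemSpider formula-search hyperlink. The document renders
#' without any network access.
#'
#' @param model a `report_model` (an `assignment_set` is accepted and
#'   converted).
#' @param out_path output HTML path.
#' @param title report title.
#' @return invisibly, `out_path`.
#' @export
build_report <- function(model, out_path, title = "Interactive van Krevelen report") {
  if (inherits(model, "assignment_set")) model <- build_report_model(model)
  stopifnot(inherits(model, "report_model"))
  payload <- list(
    records = model$records,
    isotopologues = model$isotopologues,
    unassigned = model$unassigned,
    hover_fields = HOVER_FIELDS
  )
  json <- jsonlite::toJSON(payload, dataframe = "columns", digits = NA,
                           auto_unbox = TRUE)
  html <- paste0(
    report_html_head(title),
    '<script id="vk-records" type="application/json">', json, "</script>\n",
    report_html_body(nrow(model$records)),
    "<script>\n", report_js(), "\n</script>\n</body>\n</html>\n"
  )
  writeLines(html, out_path, useBytes = TRUE)
  invisible(out_path)
}

report_html_head <- function(title) {
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n<title>",
    title, "</title>\n<style>\n",
    "body{font-family:sans-serif;margin:0.5em}\n",
    ".vk-tabbar button{padding:0.4em 1em;margin-right:0.3em;cursor:pointer}\n",
    ".vk-tabbar button.active{font-weight:bold;border-bottom:2px solid #346}\n",
    ".vk-tab{display:none}.vk-tab.active{display:block}\n",
    ".vk-grid{display:grid;grid-template-columns:1fr 1fr;gap:8px}\n",
    ".vk-panel svg{border:1px solid #ccc;background:#fff}\n",
    "#vk-tooltip{position:fixed;display:none;background:#223;color:#fff;",
    "padding:4px 7px;border-radius:4px;font-size:12px;pointer-events:none;",
    "z-index:10}\n",
    "table.vk-table{border-collapse:collapse;font-size:12px}\n",
    "table.vk-table td,table.vk-table th{border:1px solid #ccc;padding:2px 6px}\n",
    "table.vk-table tr.sel{background:#fda}\n",
    "</style>\n</head>\n<body>\n"
  )
}

report_html_body <- function(n_records) {
  notice <- if (n_records == 0L) {
    "<p class=\"vk-empty-notice\">No assigned formulae: panels are empty.</p>\n"
  } else ""
  paste0(
    "<div class=\"vk-tabbar\">\n",
    "<button data-tab=\"tab-main\" class=\"active\">Linked plots</button>\n",
    "<button data-tab=\"tab-coverage\">Assignment coverage</button>\n",
    "<button data-tab=\"tab-table\">Data table</button>\n",
    "</div>\n", notice,
    "<div id=\"tab-main\" class=\"vk-tab active\">\n<div class=\"vk-grid\">\n",
    "<div class=\"vk-panel\" data-panel=\"van_krevelen\"></div>\n",
    "<div class=\"vk-panel\" data-panel=\"spectrum\"></div>\n",
    "<div class=\"vk-panel\" data-panel=\"dbe_vs_c\"></div>\n",
    "<div class=\"vk-panel\" data-panel=\"aimod_vs_c\"></div>\n",
    "</div>\n</div>\n",
    "<div id=\"tab-coverage\" class=\"vk-tab\">\n",
    "<div class=\"vk-panel\" data-panel=\"coverage\"></div>\n",
    "<p>Monoisotopic (blue), isotopologue (green), unassigned (red).</p>\n",
    "</div>\n",
    "<div id=\"tab-table\" class=\"vk-tab\">\n",
    "<p><button id=\"vk-download\">Download table (TSV)</button></p>\n",
    "<div id=\"vk-table-holder\"></div>\n",
    "</div>\n",
    "<div id=\"vk-tooltip\"></div>\n"
  )
}

# The embedded JavaScript: reads the single JSON record store, renders four
# linked SVG panels + the coverage overlay + the table, and keeps one shared
# selection (a set of record indices) synchronised across all views.
report_js <- function() {
  paste(readLines(system.file("report", "report.js", package = "vankrev"),
                  warn = FALSE), collapse = "\n")
}

#' Batch publication-quality static plots
#'
#' Renders the van Krevelen diagram and the DBE vs carbon number plot as
#' static figures with the same visual encodings as the interactive panels
#' (size = relative abundance; colour = m/z for the van Krevelen, oxygen
#' number for DBE vs C#). Vector (`svg`, `pdf`) and raster (`png`) formats
#' are supported; output is deterministic for a fixed model.
#'
#' @param model a `report_model` (an `assignment_set` is accepted).
#' @param out_dir output directory (created if needed).
#' @param formats character vector among `"svg"`, `"png"`, `"pdf"`.
#' @return invisibly, character vector of file paths written.
#' @export
batch_static_plots <- function(model, out_dir, formats = c("svg", "png")) {
  if (inherits(model, "assignment_set")) model <- build_report_model(model)
  stopifnot(inherits(model, "report_model"))
  formats <- match.arg(formats, c("svg", "png", "pdf"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- model$records
  pal <- grDevices::hcl.colors(100, "viridis")
  paths <- character()
  for (kind in c("van_krevelen", "dbe_vs_c")) {
    for (fmt in formats) {
      path <- file.path(out_dir, paste0(kind, ".", fmt))
      switch(fmt,
        svg = grDevices::svg(path, width = 7, height = 5.5),
        pdf = grDevices::pdf(path, width = 7, height = 5.5),
        png = grDevices::png(path, width = 1400, height = 1100, res = 200,
                             type = "cairo"))
      tryCatch({
        if (kind == "van_krevelen") {
          if (nrow(rec)) {
            col <- pal[pmax(1L, ceiling(99 * (rec$mz - min(rec$mz)) /
                                          max(1e-12, diff(range(rec$mz)))))]
            graphics::plot(rec$oc, rec$hc, pch = 16, col = col,
                           cex = 0.3 + 1.7 * sqrt(rec$rel_intensity),
                           xlab = "O/C", ylab = "H/C",
                           main = "van Krevelen diagram")
          } else {
            graphics::plot(NA, xlim = c(0, 1.3), ylim = c(0, 2.5),
                           xlab = "O/C", ylab = "H/C",
                           main = "van Krevelen diagram")
          }
        } else {
          if (nrow(rec)) {
            omax <- max(rec$O, 1L)
            colo <- pal[pmax(1L, ceiling(99 * rec$O / omax))]
            graphics::plot(rec$C, rec$dbe, pch = 16, col = colo,
                           cex = 0.3 + 1.7 * sqrt(rec$rel_intensity),
                           xlab = "Carbon number", ylab = "DBE",
                           main = "DBE vs carbon number")
          } else {
            graphics::plot(NA, xlim = c(0, 50), ylim = c(0, 25),
                           xlab = "Carbon number", ylab = "DBE",
                           main = "DBE vs carbon number")
          }
        }
      }, finally = grDevices::dev.off())
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}
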