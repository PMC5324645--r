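fixture_set <- function(seed = 19, n_series = 5, n_noise = 6) {
  mix <- make_mixture(mixture_spec(n_series = n_series, n_noise = n_noise,
                                   seed = seed))
  assign_formulas(mix$peaks)
}

test_that("the report model carries one indexed record per assignment", {
  set <- fixture_set()
  model <- build_report_model(set)
  rec <- model$records
  expect_identical(nrow(rec), nrow(set$monoisotopic))
  expect_identical(rec$index, seq_len(nrow(rec)) - 1L)
  expect_true(all(c("mz", "intensity", "rel_intensity", "formula", "C", "O",
                    "hc", "oc", "dbe", "ai_mod", "error_ppm", "class",
                    "region", "chemspider") %in% names(rec)))
  expect_equal(max(rec$rel_intensity), 1)
  # derived fields equal fresh recomputation
  f <- parse_formula(rec$formula)
  expect_equal(rec$dbe, dbe(f))
  expect_equal(rec$ai_mod, ai_mod(f))
})

test_that("ChemSpider URLs are deterministic Hill-notation searches", {
  u <- chemspider_url(parse_formula("C6H6"))
  expect_match(u, "^https://www\\.chemspider\\.com/Search\\.aspx\\?q=C6H6$")
  expect_identical(u, chemspider_url(parse_formula("C6H6")))
  all6 <- mol_formula(C = 5, H = 5, N = 1, O = 2, S = 1, P = 1)
  expect_match(chemspider_url(all6), "C5H5NO2PS")
})

test_that("coverage overlay series lengths equal the partition sizes", {
  set <- fixture_set()
  model <- build_report_model(set)
  ov <- coverage_overlay(model)
  expect_identical(nrow(ov$monoisotopic), nrow(set$monoisotopic))
  expect_identical(nrow(ov$isotopologue), nrow(set$isotopologues))
  expect_identical(nrow(ov$unassigned), nrow(set$unassigned))
})

test_that("the HTML report is self-contained with three tabs and one store", {
  set <- fixture_set()
  model <- build_report_model(set)
  d <- withr::local_tempdir()
  path <- file.path(d, "report.html")
  build_report(model, path)
  html <- paste(readLines(path, warn = FALSE), collapse = "\n")

  # no external fetches: all refs are inline or chemspider hyperlinks
  expect_false(grepl("<script[^>]+src=", html))
  expect_false(grepl("<link[^>]+href=", html))

  doc <- xml2::read_html(path)
  tabs <- xml2::xml_find_all(doc, "//div[contains(@class,'vk-tab') and not(contains(@class,'vk-tabbar'))]")
  expect_identical(length(tabs), 3L)

  store <- xml2::xml_find_first(doc, "//script[@id='vk-records']")
  expect_false(inherits(store, "xml_missing"))
  payload <- jsonlite::fromJSON(xml2::xml_text(store))
  expect_identical(length(payload$records$index), nrow(model$records))

  # four linked panels plus coverage panel reference the single store
  panels <- xml2::xml_attr(xml2::xml_find_all(doc, "//div[@data-panel]"),
                           "data-panel")
  expect_true(all(c("van_krevelen", "spectrum", "dbe_vs_c", "aimod_vs_c",
                    "coverage") %in% panels))

  # hover fields and chemspider links live in the shared store
  expect_true(all(c("formula", "mz", "intensity", "error_ppm", "dbe",
                    "ai_mod", "class") %in% payload$hover_fields))
  expect_identical(payload$records$chemspider, model$records$chemspider)
})

test_that("embedded record values equal the exported data table", {
  set <- fixture_set(seed = 23)
  model <- build_report_model(set)
  d <- withr::local_tempdir()
  html_path <- file.path(d, "r.html")
  tsv_path <- file.path(d, "r.tsv")
  build_report(model, html_path)
  export_data_table(model, tsv_path)
  doc <- xml2::read_html(html_path)
  payload <- jsonlite::fromJSON(
    xml2::xml_text(xml2::xml_find_first(doc, "//script[@id='vk-records']")))
  tab <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expect_identical(payload$records$formula, tab$formula)
  expect_equal(payload$records$mz, tab$mz, tolerance = 1e-12)
  expect_equal(payload$records$ai_mod, tab$ai_mod, tolerance = 1e-12)
})

test_that("an empty model still renders a valid document with a notice", {
  set <- assign_formulas(data.frame(mz = numeric(), intensity = numeric()))
  d <- withr::local_tempdir()
  path <- file.path(d, "empty.html")
  build_report(build_report_model(set), path)
  doc <- xml2::read_html(path)
  expect_identical(
    length(xml2::xml_find_all(doc, "//div[contains(@class,'vk-tab') and not(contains(@class,'vk-tabbar'))]")),
    3L)
  expect_false(inherits(
    xml2::xml_find_first(doc, "//p[@class='vk-empty-notice']"), "xml_missing"))
})

test_that("batch static plots render both panels in every requested format", {
  set <- fixture_set(seed = 29)
  d <- withr::local_tempdir()
  paths <- batch_static_plots(set, d, formats = c("svg", "png"))
  expect_identical(length(paths), 4L)
  expect_true(all(file.exists(paths)))
  expect_setequal(basename(paths),
                  c("van_krevelen.svg", "van_krevelen.png",
                    "dbe_vs_c.svg", "dbe_vs_c.png"))
  # determinism contract for vector output
  d2 <- withr::local_tempdir()
  batch_static_plots(set, d2, formats = "svg")
  for (kind in c("van_krevelen", "dbe_vs_c")) {
    a <- readBin(file.path(d, paste0(kind, ".svg")), "raw", 5e6)
    b <- readBin(file.path(d2, paste0(kind, ".svg")), "raw", 5e6)
    expect_identical(a, b)
  }
  # empty model: files with axes and no glyphs
  empty <- assign_formulas(data.frame(mz = numeric(), intensity = numeric()))
  d3 <- withr::local_tempdir()
  p3 <- batch_static_plots(empty, d3, formats = "svg")
  expect_true(all(file.size(p3) > 0))
})
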