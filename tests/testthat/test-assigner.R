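test_that("an exact CH2 ladder groups into one homologous series", {
  peaks <- ladder_peaks("C9H10O5", 3)
  series <- group_series(peaks)
  expect_length(series, 1L)
  expect_identical(series[[1]]$members, 1:3)
  kc <- kendrick(peaks$mz)
  expect_true(all(kc$z_star == kc$z_star[1]))
})

test_that("a single peak forms a singleton series", {
  series <- group_series(data.frame(mz = 301.1234, intensity = 5))
  expect_length(series, 1L)
  expect_identical(series[[1]]$members, 1L)
})

test_that("disjoint exact series are recovered with correct memberships", {
  bases <- c("C10H12O4", "C11H12O5", "C12H14O6", "C13H16O7", "C9H8O3",
             "C14H18O8", "C10H11NO4", "C12H16O2", "C15H22O9", "C11H14O3")
  sets <- lapply(bases, ladder_peaks, n = 4)
  peaks <- do.call(rbind, sets)
  truth <- rep(seq_along(bases), each = 4)
  series <- group_series(peaks)
  expect_length(series, 10L)
  got <- integer(nrow(peaks))
  for (si in seq_along(series)) got[series[[si]]$members] <- si
  # same partition as the truth (series ids may be permuted)
  expect_identical(length(unique(got)), 10L)
  for (si in unique(truth)) {
    expect_identical(length(unique(got[truth == si])), 1L)
  }
})

test_that("zero-error peak lists are recovered completely and exactly", {
  mix <- make_mixture(mixture_spec(n_series = 12, sigma_ppm = 0,
                                   isotopologues = FALSE, n_noise = 0,
                                   seed = 101))
  set <- assign_formulas(mix$peaks)
  expect_identical(nrow(set$monoisotopic), nrow(mix$peaks))
  m <- merge(mix$truth, set$monoisotopic, by = "mz")
  expect_identical(m$formula.x, m$formula.y)
  expect_true(all(abs(m$error_ppm) < 1e-6))
})

test_that("pure noise peak lists end up entirely unassigned", {
  mix <- make_mixture(mixture_spec(n_series = 1, sigma_ppm = 0,
                                   isotopologues = FALSE, n_noise = 40,
                                   seed = 33))
  noise <- mix$truth[mix$truth$kind == "noise", ]
  set <- assign_formulas(data.frame(mz = noise$mz, intensity = noise$intensity))
  expect_identical(nrow(set$monoisotopic), 0L)
  expect_identical(nrow(set$unassigned), nrow(noise))
})

test_that("the three parts partition the input on every run", {
  for (seed in c(5, 6)) {
    mix <- make_mixture(mixture_spec(n_series = 8, n_noise = 20, seed = seed))
    set <- assign_formulas(mix$peaks)
    expect_identical(
      nrow(set$monoisotopic) + nrow(set$isotopologues) + nrow(set$unassigned),
      nrow(mix$peaks)
    )
  }
})

test_that("assignment is deterministic for identical inputs and config", {
  mix <- make_mixture(mixture_spec(n_series = 8, n_noise = 10, seed = 2))
  a <- assign_formulas(mix$peaks)
  b <- assign_formulas(mix$peaks)
  expect_identical(a$monoisotopic, b$monoisotopic)
  expect_identical(a$isotopologues, b$isotopologues)
  expect_identical(a$unassigned, b$unassigned)
})

test_that("unambiguous generator hits agree with the assigner's formula", {
  mix <- make_mixture(mixture_spec(n_series = 6, sigma_ppm = 0.1,
                                   isotopologues = FALSE, n_noise = 0,
                                   seed = 17))
  cfg <- assignment_config()
  set <- assign_formulas(mix$peaks, cfg)
  for (i in seq_len(nrow(set$monoisotopic))) {
    row <- set$monoisotopic[i, ]
    cand <- generate_candidates(neutral_mass(row$mz, cfg$mode),
                                cfg$tol_ppm_member, cfg$ranges, cfg$rules)
    if (nrow(cand) == 1L) expect_identical(row$formula, cand$formula)
  }
})

test_that("every assigned formula passes every enabled heuristic rule", {
  mix <- make_mixture(mixture_spec(n_series = 10, seed = 9))
  set <- assign_formulas(mix$peaks)
  mono <- set$monoisotopic
  expect_gt(nrow(mono), 0)
  expect_true(all(passes_rules(mono[c("C", "H", "N", "O", "S", "P")])))
  # derived metrics equal fresh chem_core recomputation
  f <- as_mol_formula(mono[c("C", "H", "N", "O", "S", "P")])
  expect_equal(mono$dbe, dbe(f))
  expect_equal(mono$ai_mod, ai_mod(f))
  expect_equal(mono$hc, elemental_ratios(f)$hc)
  expect_identical(mono$formula, format_formula(f))
})

test_that("recovery is monotone non-increasing in injected mass error", {
  rec <- vapply(c(0, 0.5, 3), function(sig) {
    mix <- make_mixture(mixture_spec(n_series = 10, sigma_ppm = sig,
                                     isotopologues = FALSE, n_noise = 0,
                                     seed = 21))
    set <- assign_formulas(mix$peaks)
    m <- merge(mix$truth, set$monoisotopic, by = "mz")
    sum(m$formula.x == m$formula.y) / nrow(mix$truth)
  }, numeric(1))
  expect_true(all(diff(rec) <= 1e-9))
  expect_identical(rec[1], 1)
})

test_that("empty input gives an empty assignment set", {
  set <- assign_formulas(data.frame(mz = numeric(), intensity = numeric()))
  expect_identical(set$n_peaks, 0L)
  expect_identical(nrow(set$monoisotopic), 0L)
})

test_that("13C1 satellites are annotated when mass and intensity are in band", {
  parent <- ladder_peaks("C10H12O5", 1, intensity = 1000)
  cfg <- assignment_config()
  assigned <- assign_formulas(parent, cfg)$monoisotopic
  expect_identical(assigned$formula, "C10H12O5")
  sat <- data.frame(mz = parent$mz + 1.0033548, intensity = 107)  # 10 x 1.07%
  res <- annotate_isotopologues(assigned, sat, cfg)
  expect_identical(nrow(res$isotopologues), 1L)
  expect_identical(res$isotopologues$parent_formula, "C10H12O5")
  expect_identical(res$isotopologues$isotope, "13C1")
  expect_equal(res$isotopologues$ratio_obs_exp, 1, tolerance = 1e-6)
  expect_identical(nrow(res$unassigned), 0L)
})

test_that("satellites with out-of-band intensity are not annotated", {
  parent <- ladder_peaks("C10H12O5", 1, intensity = 1000)
  cfg <- assignment_config()
  assigned <- assign_formulas(parent, cfg)$monoisotopic
  sat_hot <- data.frame(mz = parent$mz + 1.0033548, intensity = 900) # 0.9 > 3 x 0.107
  res <- annotate_isotopologues(assigned, sat_hot, cfg)
  expect_identical(nrow(res$isotopologues), 0L)
  expect_identical(nrow(res$unassigned), 1L)
  sat_cold <- data.frame(mz = parent$mz + 1.0033548, intensity = 10)  # below 0.2 band
  res2 <- annotate_isotopologues(assigned, sat_cold, cfg)
  expect_identical(nrow(res2$isotopologues), 0L)
})

test_that("a parent with no nearby leftover gets no isotopologue record", {
  parent <- ladder_peaks("C10H12O5", 1, intensity = 1000)
  assigned <- assign_formulas(parent)$monoisotopic
  far <- data.frame(mz = parent$mz + 5, intensity = 107)
  res <- annotate_isotopologues(assigned, far)
  expect_identical(nrow(res$isotopologues), 0L)
  expect_identical(nrow(res$unassigned), 1L)
})

test_that("each leftover peak is attached to at most one parent (closest ppm)", {
  p1 <- ladder_peaks("C10H12O5", 1, intensity = 1000)
  p2 <- data.frame(mz = p1$mz + 2e-4, intensity = 1000)  # near-coincident parent
  peaks <- rbind(p1, p2)
  cfg <- assignment_config(tol_ppm_member = 2)
  # hand-build two assigned parents sharing the satellite window
  assigned <- rbind(
    assign_formulas(p1, cfg)$monoisotopic,
    transform(assign_formulas(p1, cfg)$monoisotopic, mz = p2$mz)
  )
  sat <- data.frame(mz = p1$mz + 1.0033548, intensity = 107)
  res <- annotate_isotopologues(assigned, sat, cfg)
  expect_identical(nrow(res$isotopologues), 1L)
  expect_equal(res$isotopologues$parent_mz, p1$mz, tolerance = 1e-9)
})
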