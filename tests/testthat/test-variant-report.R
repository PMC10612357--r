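test_that("variants classify into CD-site groups from the packaged table", {
  expect_identical(classify_variant("MAPK1", "E81K"), "I")
  expect_identical(classify_variant("MAPK1", "P319S"), "II")
  expect_identical(classify_variant("MAPK1", "E322V"), "II")
  expect_identical(classify_variant("MAPK1", "E33Q"), "III")
  expect_identical(classify_variant("MAPK3", "I73M"), "III")
  expect_identical(classify_variant("MAPK3", "E98K"), "I")
  expect_identical(classify_variant("MAPK3", "A300T"), "Unclassified")
})

test_that("substitution parsing validates format and position", {
  p <- parse_substitution("E81K", "MAPK1")
  expect_identical(p, list(wt = "E", position = 81L, mut = "K"))
  expect_error(parse_substitution("81K"), class = "kinstab_parse_error")
  expect_error(parse_substitution("EK"), class = "kinstab_parse_error")
  expect_error(parse_substitution("E400K", "MAPK1"),
               class = "kinstab_parse_error")
  # 379 is a valid MAPK3 position but not a valid MAPK1 one
  expect_silent(parse_substitution("R379W", "MAPK3"))
  expect_error(parse_substitution("R379W", "MAPK1"),
               class = "kinstab_parse_error")
})

test_that("wild-type self-comparison gives null deltas and unit ratio", {
  wt <- variant_record("MAPK1", "WT", tm_NP = 55, tm_P = 55,
                       efficiency = 1.22, tmax = 30, Ea = 9.95)
  row <- compare_to_wildtype(wt, wt)
  expect_equal(row$delta_tm_NP, 0)
  expect_equal(row$delta_tm_P, 0)
  expect_equal(row$efficiency_ratio, 1)
  expect_equal(row$delta_tmax, 0)
  expect_equal(row$delta_Ea, 0)
})

test_that("comparison is antisymmetric under argument swap", {
  a <- variant_record("MAPK3", "E98K", tm_NP = 52, tm_P = 47.1,
                      efficiency = 1.08, tmax = 25, Ea = 5.88)
  b <- variant_record("MAPK3", "WT", tm_NP = 46, tm_P = 47.1,
                      efficiency = 0.65, tmax = 37, Ea = 4.28)
  ab <- compare_to_wildtype(a, b)
  ba <- compare_to_wildtype(b, a)
  for (f in c("delta_tm_NP", "delta_tm_P", "delta_tmax", "delta_Ea")) {
    expect_equal(ab[[f]], -ba[[f]])
  }
  expect_equal(ab$efficiency_ratio, 1 / ba$efficiency_ratio)
})

test_that("missing upstream fits are reported by name", {
  v <- variant_record("MAPK1", "E81K", tm_NP = 55)
  wt <- variant_record("MAPK1", "WT", tm_NP = 55, tm_P = 55,
                       efficiency = 1.22, tmax = 30, Ea = 9.95)
  err <- tryCatch(compare_to_wildtype(v, wt), error = function(e) e)
  expect_s3_class(err, "kinstab_incomplete_record")
  expect_match(conditionMessage(err), "tm_P")
  expect_match(conditionMessage(err), "efficiency")
})

test_that("the assembled ledger reproduces the cross-checkable cells", {
  rows <- build_comparison_table("both")
  get <- function(p, v) rows[[paste(p, v, sep = ".")]]

  # efficiency ratios derived from the reported efficiency columns
  expect_equal(signif(get("MAPK1", "D162G")$efficiency_ratio, 3), 5.33e-4)
  expect_equal(signif(get("MAPK3", "E98K")$efficiency_ratio, 3), 1.66)
  expect_equal(signif(get("MAPK1", "R191H")$efficiency_ratio, 3), 2.98e-4)
  expect_equal(signif(get("MAPK1", "Y316F")$efficiency_ratio, 3), 3.57)

  # activation-energy and Tmax deltas
  expect_equal(get("MAPK1", "E322V")$delta_Ea, 3.99 - 9.95)
  expect_equal(get("MAPK1", "E81K")$delta_Ea, -3.05)
  expect_equal(get("MAPK1", "E81K")$delta_tmax, 5)
  expect_equal(get("MAPK1", "D162G")$delta_tmax, 10)
  expect_equal(get("MAPK3", "V290A")$delta_tmax, -17)

  # melting-temperature deltas
  expect_equal(get("MAPK3", "E98K")$delta_tm_NP, 6.0)
  expect_equal(get("MAPK3", "R152W")$delta_tm_NP, 3.0)
  expect_equal(get("MAPK1", "E81K")$delta_tm_P, -0.9)
})

test_that("report rendering is deterministic and styled", {
  rows <- build_comparison_table("MAPK1")
  df <- render_report(rows)
  expect_identical(nrow(df), length(rows))
  expect_identical(df$substitution,
                   unname(vapply(rows, `[[`, character(1), "substitution")))
  # scientific notation below 1e-2, 3 significant figures
  expect_match(df$efficiency_ratio[df$substitution == "D162G"], "5.33e-04")
  csv <- render_report(rows, "csv")
  expect_identical(csv, render_report(rows, "csv"))
  expect_length(csv, length(rows) + 1L)
  txt <- render_report(rows, "text")
  expect_length(txt, length(rows) + 1L)
  expect_error(render_report(list()), class = "kinstab_empty_report")
})
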