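# Virtual screening: universe generation, batch scoring, compound filtering,
# score binning, CSV export, combinatorics.

test_that("generate_universe: sizes, ranges, marker inclusion near k/N", {
  world <- fx_world()
  u <- generate_universe(5000L, world$library, seed = 41L)
  expect_identical(u$size, 5000L)
  expect_true(all(u$k %in% 3:5))
  expect_true(all(u$coef[!is.na(u$coef)] %in% 1:10))
  # E[k]/N = 4/198 inclusion probability, binomial 3-sigma band
  frac <- universe_contains_fraction(u, world$marker)
  p <- 4 / 198
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 5000))
  # k fixed at 3 over a 6-compound library: inclusion probability 3/6
  lib6 <- world$library[1:6, ]
  u6 <- generate_universe(4000L, lib6, seed = 42L, k_range = 3L)
  expect_lt(abs(universe_contains_fraction(u6, world$marker) - 0.5),
            3 * sqrt(0.25 / 4000))
  # empty universe; oversized k errors
  expect_identical(generate_universe(0L, world$library)$size, 0L)
  expect_error(generate_universe(10L, world$library[1:4, ]), "at least 5")
})

test_that("universe encoding round-trips and persists one mixture per line", {
  world <- fx_world()
  u <- generate_universe(50L, world$library, seed = 43L)
  enc <- encode_universe(u)
  expect_length(enc, 50L)
  for (i in c(1L, 25L, 50L)) {
    m <- decode_mixture(enc[i], world$library)
    ki <- u$k[i]
    expect_identical(sort(m$smiles), sort(world$library$smiles[u$comp[i, 1:ki]]))
  }
  path <- withr::local_tempfile()
  write_universe(u, path)
  expect_identical(readLines(path), enc)
})

test_that("screen_universe preserves cardinality and order, independent of batch size", {
  fit <- fx_classifier()
  u <- generate_universe(100L, fx_world()$library, seed = 44L)
  s1 <- screen_universe(fit$classifier, u, batch_size = 1L)
  s64 <- screen_universe(fit$classifier, u, batch_size = 64L)
  expect_identical(nrow(s1), 100L)
  expect_identical(s1$encoded, encode_universe(u))
  expect_equal(s1$score, s64$score, tolerance = 1e-12)
  # label is exactly the strict threshold rule
  expect_identical(sum(s1$label), sum(s1$score > 0.5))
  # screening from a persisted universe file gives the same result
  path <- withr::local_tempfile()
  write_universe(u, path)
  sf <- screen_universe(fit$classifier, path)
  expect_equal(sf$score, s1$score, tolerance = 1e-12)
  # malformed universe line is reported with its line number
  writeLines(c(encode_universe(u)[1:2], "not-a-mixture"), path)
  expect_error(screen_universe(fit$classifier, path), "line 3")
})

test_that("filter_by_compound: membership, canonical query, score-then-lexicographic order", {
  scored <- data.frame(
    encoded = c("[R1]CCO.[R1]O", "[R2]CCN.[R1]O", "[R1]CCO.[R3]N",
                "[R1]C.[R1]CC", "[R2]CCO.[R2]O"),
    score = c(0.9, 0.831, 0.831, 0.2, 0.831),
    label = c(1L, 1L, 1L, 0L, 1L), stringsAsFactors = FALSE)
  out <- filter_by_compound(scored, "CCO")
  expect_identical(out$encoded, c("[R1]CCO.[R1]O", "[R1]CCO.[R3]N", "[R2]CCO.[R2]O"))
  expect_identical(filter_by_compound(scored, "CCCCCC")$encoded, character(0))
  # ties at equal score are broken by byte order of the encoded string
  tied <- filter_by_compound(scored, "O")
  expect_identical(tied$encoded[2:3], sort(c("[R2]CCN.[R1]O", "[R2]CCO.[R2]O")))
  # query canonicalization: "OCC" matches records encoded with rdkit-canonical "CCO"
  out2 <- filter_by_compound(scored, "OCC", canonicalizer = rdkit_canonicalizer())
  expect_identical(out2$encoded, out$encoded)
})

test_that("bin_scores uses left-open 5-point bins above 50%", {
  sc <- data.frame(score = c(0.801, 0.84, 0.86, 0.85, 0.12, 0.5))
  h <- bin_scores(sc)
  expect_identical(h$count[h$bin == "80.1-85"], 3L)   # 0.801, 0.84 and edge 0.85
  expect_identical(h$count[h$bin == "85.1-90"], 1L)
  expect_identical(attr(h, "total"), 4L)              # 0.12 and exact 0.5 excluded
  # all scores <= 0.5 -> empty histogram
  h0 <- bin_scores(data.frame(score = c(0.1, 0.5)))
  expect_true(all(h0$count == 0L))
  # counts agree with a brute-force recount on random scores
  set.seed(45)
  s <- data.frame(score = runif(500))
  h2 <- bin_scores(s)
  brute <- vapply(seq_along(SCORE_BIN_LABELS), function(i) {
    lo <- SCORE_BIN_BREAKS[i]; hi <- SCORE_BIN_BREAKS[i + 1L]
    sum(s$score * 100 > lo & s$score * 100 <= hi)
  }, integer(1L))
  expect_identical(h2$count, brute)
  expect_identical(sum(h2$count), attr(h2, "total"))
})

test_that("export_results_csv writes the fixed header, 4-decimal scores, byte-stable", {
  scored <- data.frame(
    encoded = c("[R2]CCO.[R1]O", "[R1]CCN"),
    score = c(0.87654, 0.3), label = c(1L, 0L), stringsAsFactors = FALSE)
  f1 <- withr::local_tempfile(fileext = ".csv")
  export_results_csv(scored, f1)
  lines <- readLines(f1)
  expect_identical(lines[1L], "components,ratios,encoded,score,label")
  expect_identical(lines[2L], "CCO;O,2:1,[R2]CCO.[R1]O,0.8765,1")
  expect_identical(lines[3L], "CCN,1,[R1]CCN,0.3000,0")
  # empty input -> header-only file; re-export is byte-identical
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_results_csv(scored[0, ], f2)
  expect_identical(readLines(f2), "components,ratios,encoded,score,label")
  f3 <- withr::local_tempfile(fileext = ".csv")
  export_results_csv(scored, f3)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f3, "raw", file.size(f3)))
})

test_that("count_ternary_combinations is exact and matches brute-force enumeration", {
  expect_identical(count_ternary_combinations(3), 1)
  expect_identical(count_ternary_combinations(10), 120)
  for (n in 3:25)
    expect_identical(count_ternary_combinations(n), ncol(utils::combn(n, 3L)) * 1)
  expect_error(count_ternary_combinations(2), "at least 3")
  expect_error(count_ternary_combinations(2.5), "integer")
})
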