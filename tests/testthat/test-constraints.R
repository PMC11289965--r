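# Hard constraints: parsing, O(1) predicates, folding behavior, and the
# random pseudoknot-free constraint generator.

test_that("constraint parsing accepts the dialect and validates pairs", {
  cs <- parse_constraints("...........", "GGGAAAACCCC")
  expect_true(all(cs$partner == 0))
  cs2 <- parse_constraints("(.........)", "GGGAAAACCCC")
  expect_identical(cs2$partner[1], 11L)
  expect_identical(cs2$partner[11], 1L)
  cs3 <- parse_constraints("x.x........", "GGGAAAACCCC")
  expect_identical(cs3$partner[c(1, 3)], c(-1L, -1L))
  expect_error(parse_constraints("(....)", "AAAAAA"), "not canonical")
  expect_error(parse_constraints("((...", "GGGCC"), "unbalanced")
  expect_error(parse_constraints("...)", "GGCC"), "unbalanced")
  expect_error(parse_constraints("(..)", "GCGC"), "minimum hairpin")
  expect_error(parse_constraints("..*.", "GCGC"), "invalid constraint")
  expect_error(parse_constraints("...", "GCGC"), "length")
})

test_that("pair_allowed and region_unpaired_ok match a naive scan", {
  set.seed(5)
  for (k in 1:10) {
    s <- random_sequence(40, seed = 3000 + k)
    cs <- random_constraints(s, seed = 3100 + k)
    forced <- which(cs$partner > 0)
    for (r in 1:30) {
      ij <- sort(sample.int(40, 2))
      naive_region <- !any(seq(ij[1], ij[2]) %in% forced)
      expect_identical(region_unpaired_ok(ij[1], ij[2], cs), naive_region)
      naive_pair <- cs$partner[ij[1]] != -1 && cs$partner[ij[2]] != -1 &&
        (cs$partner[ij[1]] %in% c(0L, ij[2])) &&
        (cs$partner[ij[2]] %in% c(0L, ij[1]))
      expect_identical(pair_allowed(ij[1], ij[2], cs), naive_pair)
    }
    expect_true(region_unpaired_ok(7, 3, cs))  # empty region
  }
})

test_that("every forced pair appears in the folded structure", {
  for (k in 1:6) {
    s <- random_sequence(80, seed = 3200 + k)
    cs <- random_constraints(s, seed = 3300 + k)
    op <- which(cs$partner > seq_len(80))
    for (eng in c("sparse", "dense")) {
      f <- fold_rna(s, model = "d1", engine = eng, constraints = cs)
      expect_identical(f$pt[op], cs$partner[op])
      expect_true(all(f$pt[cs$partner == -1] == 0))
    }
  }
})

test_that("forced-unpaired positions never pair", {
  s <- "GGGAAAACCCC"
  f <- fold_rna(s, model = "d1", constraints = "..x........")
  expect_identical(f$pt[3], 0L)
  expect_equal(evaluate_structure(s, f$structure, model = "d1"), f$mfe)
})

test_that("the random generator honors the cap, spacing and determinism", {
  s1024 <- random_sequence(1024, seed = 42)
  cs <- random_constraints(s1024, seed = 7)
  expect_lte(sum(cs$partner > 0) / 2, 5)  # floor(0.5 * log2(1024)) = 5
  s16 <- random_sequence(16, seed = 43)
  cs16 <- random_constraints(s16, seed = 7)
  expect_lte(sum(cs16$partner > 0) / 2, 2)
  # determinism
  expect_identical(random_constraints(s1024, seed = 7)$text, cs$text)
  # canonical, spaced, non-crossing
  bases <- strsplit(s1024, "")[[1]]
  op <- which(cs$partner > seq_along(cs$partner))
  for (i in op) {
    j <- cs$partner[i]
    expect_false(is.na(pair_type(bases[i], bases[j])))
    expect_gt(j - i, 3)
  }
  expect_silent(parse_constraints(cs$text, s1024))  # non-crossing by dialect
})
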