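# Thermodynamic building blocks: parameter loading, pair classification,
# single-loop energies, dangle lookups, structure evaluation.

test_that("parameter loading matches an independent re-parse of the fixture", {
  ml <- as.integer(fixture_section("ML_params"))
  expect_identical(params$ml_base, ml[1])     # c
  expect_identical(params$ml_closing, ml[3])  # a
  expect_identical(params$ml_intern, ml[5])   # b

  stack <- as.integer(fixture_section("stack"))
  # pair order CG GC GU UG AU UA NN; CG/CG is the first cell
  expect_identical(params$stack[1], stack[1])
  expect_identical(interior_energy("CGCG", 1, 4, 2, 3), stack[1])

  ninio <- as.integer(fixture_section("NINIO"))
  expect_identical(params$ninio, ninio[1])
  expect_identical(params$max_ninio, ninio[3])
  misc <- as.integer(fixture_section("Misc"))
  expect_identical(params$terminal_AU, misc[3])
})

test_that("malformed parameter input raises a parse error naming the problem", {
  tmp <- withr::local_tempfile(lines = c(
    "## RNAfold parameter file v2.0", "# stack", "1 2 3", "#END"))
  expect_error(read_energy_params(tmp), "stack")
  tmp2 <- withr::local_tempfile(lines = "just text")
  expect_error(read_energy_params(tmp2), "parameter file")
})

test_that("pair_type classifies exactly the six canonical ordered pairs", {
  expect_identical(pair_type("G", "C"), "GC")
  expect_identical(pair_type("g", "u"), "GU")
  expect_true(is.na(pair_type("A", "G")))
  bases <- c("A", "C", "G", "U")
  grid <- expand.grid(b5 = bases, b3 = bases, stringsAsFactors = FALSE)
  types <- mapply(pair_type, grid$b5, grid$b3)
  expect_identical(sum(!is.na(types)), 6L)
  expect_setequal(types[!is.na(types)], c("CG", "GC", "GU", "UG", "AU", "UA"))
  expect_error(pair_type("B", "C"), "invalid")
})

test_that("hairpin energies respect the minimum loop size and closing pair", {
  # loop of m-1 unpaired bases is forbidden
  expect_gte(hairpin_energy("GAAC", 1, 4), energy_inf())
  # size m = 3 is the smallest allowed loop
  expect_lt(hairpin_energy("GAAAC", 1, 5), energy_inf() / 2)
  # non-canonical closing pair
  expect_gte(hairpin_energy("GAAAG", 1, 5), energy_inf())
  # the inner hairpin of the worked 11-mer: initiation + GC/A/A mismatch
  toks <- fixture_section("hairpin")
  hp_init <- ifelse(toks == "INF", energy_inf(), suppressWarnings(as.integer(toks)))
  e <- hairpin_energy("GGGAAAACCCC", 3, 8)
  expect_lt(e, energy_inf() / 2)
  expect_identical(e, hp_init[5] + -110L)  # hairpin[4] + mismatch[GC][A][A]
})

test_that("interior loop energies follow the parameter-file semantics", {
  # stack (p,q) = (i+1, j-1): direct stack-table entry
  stack <- as.integer(fixture_section("stack"))
  expect_identical(interior_energy("GGCC", 1, 4, 2, 3), stack[(2 - 1) * 7 + 1])
  # loop size beyond the bound M is forbidden
  s <- paste0("G", strrep("A", 20), "GAAAAC", strrep("A", 20), "C")
  n <- nchar(s)
  expect_gte(interior_energy(s, 1, n, 22, 27), energy_inf())
  # symmetric 1x1 loop reads the int11 table: closing C.G, inner G.C
  # (seen from the far side: CG,CG), mismatch bases A/A
  int11 <- as.integer(fixture_section("int11"))
  expect_identical(interior_energy("CAGAAACAG", 1, 9, 3, 7),
                   int11[(0 * 7 + 0) * 25 + 1 * 5 + 1 + 1])
  # pure function: identical on repeated evaluation
  expect_identical(interior_energy("GGGAAAACCCC", 1, 11, 2, 10),
                   interior_energy("GGGAAAACCCC", 1, 11, 2, 10))
})

test_that("dangle terms come from the tables and vanish off-sequence", {
  d3 <- as.integer(fixture_section("dangle3"))
  # C dangling 3' of a G.C pair: row GC, column C
  expect_identical(dangle_terms("GGGAAAACCCC", kind = "d3", pair = c(1, 10)),
                   d3[(2 - 1) * 5 + 2 + 1])
  # dangling position 0 (off the 5' end) contributes 0
  expect_identical(dangle_terms("GGGAAAACCCC", kind = "d5", pair = c(1, 10),
                                dangling = 0), 0L)
  # the both-sides sum mapping is additive in its single-sided components
  s <- "AGGGAAAACCCCA"
  expect_identical(
    dangle_terms(s, kind = "d53", pair = c(2, 12), sum53 = TRUE),
    dangle_terms(s, kind = "d5", pair = c(2, 12)) +
      dangle_terms(s, kind = "d3", pair = c(2, 12)))
  # the default both-sides mapping reads the mismatch table, which differs
  # between exterior and multiloop context only if the file's tables do
  mm_ext <- dangle_terms(s, kind = "d53", pair = c(2, 12))
  expect_true(is.numeric(mm_ext))
})

test_that("hairpin energies are infinite whenever j - i <= m", {
  s <- random_sequence(30, seed = 1)
  for (i in 1:26) for (j in (i + 1):min(i + params$m, 30))
    expect_gte(hairpin_energy(s, i, j), energy_inf())
})

test_that("structure evaluation reproduces the worked example", {
  expect_equal(evaluate_structure("GGGAAAACCCC", "(((....))).", model = "d1"),
               -2.9)
  expect_equal(evaluate_structure("GGGAAAACCCC", "(((.....)))", model = "d1"),
               -2.4)
  expect_equal(evaluate_structure("AAAAAAAA", "........", model = "d2"), 0)
})

test_that("d0 and d1 evaluation agree when no dangle case is selectable", {
  # helix flush against both sequence ends: no adjacent unpaired bases
  s <- "GGGGGAAAACCCCC"
  db <- "(((((....)))))"
  expect_equal(evaluate_structure(s, db, model = "d0"),
               evaluate_structure(s, db, model = "d1"))
})

test_that("crossing pairs are rejected by the evaluator", {
  pt <- c(3L, 4L, 1L, 2L, 0L, 0L, 0L, 0L)
  expect_error(evaluate_structure("GGGAAACC", pt), "hairpin|crossing")
  pt2 <- c(6L, 8L, 0L, 0L, 0L, 1L, 0L, 2L)
  expect_error(evaluate_structure("GAGAAACU", pt2), "crossing")
})
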