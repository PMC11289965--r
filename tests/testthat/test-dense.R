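# Dense reference engine: worked example, matrix invariants, model
# orderings, and exact agreement with the external ViennaRNA oracle.

test_that("the worked 11-mer folds to the printed energies and structure", {
  f <- fold_rna("GGGAAAACCCC", model = "d1", engine = "dense")
  expect_equal(f$mfe, -2.9)
  expect_identical(f$structure, "(((....))).")
  fc <- fold_rna("GGGAAAACCCC", model = "d1", engine = "dense",
                 constraints = "(.........)")
  expect_equal(fc$mfe, -2.4)
  expect_identical(fc$pt[1], 11L)
})

test_that("a pair-free sequence folds to zero energy and all dots", {
  for (m in models) {
    f <- fold_dense("AAAAAAAA", model = m)
    expect_equal(f$mfe, 0)
    expect_identical(f$structure, strrep(".", 8))
    V <- f$matrices$V
    expect_true(all(V[upper.tri(V)] >= energy_inf() / 2))
  }
})

test_that("matrix initialization and the W triangle inequality hold", {
  s <- random_sequence(40, seed = 31)
  f <- fold_dense(s, model = "d2")
  M <- f$matrices
  n <- nchar(s)
  expect_true(all(diag(M$W) == 0))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j - i <= params$m) {
      expect_gte(M$V[i, j], energy_inf())
      expect_gte(M$WM[i, j], energy_inf())
    }
    if (j - i < 2 * params$m + 3) expect_gte(M$WM2[i, j], energy_inf())
    expect_identical(M$W[i, j], pmin(M$Wp[i, j], M$Vd[i, j]))
  }
  # triangle inequality for W, exhaustively over all i < k <= j
  Wfull <- M$W
  Wfull[is.na(Wfull)] <- 0  # W(i,j) = 0 for j < i
  viol <- 0L
  for (i in 1:(n - 1)) for (k in (i + 1):n) {
    j <- k:n
    viol <- viol + sum(Wfull[i, j] > Wfull[i, k - 1] + Wfull[k, j])
  }
  expect_identical(viol, 0L)
})

test_that("dangle-model orderings hold across a random panel", {
  for (s in seq_panel(12, 20, 50, offset = 300)) {
    e0 <- fold_rna(s, model = "d0", engine = "dense")$mfe
    e1 <- fold_rna(s, model = "d1", engine = "dense")$mfe
    expect_lte(e1, e0)  # the exclusive minimum includes the no-dangle case
    # if every dangle/mismatch entry is <= 0, always-dangle can only help
    neg <- all(params$dangle5 <= 0) && all(params$dangle3 <= 0) &&
      all(params$mismatch_exterior <= 0) && all(params$mismatch_multi <= 0)
    if (neg) {
      e2 <- fold_rna(s, model = "d2", engine = "dense")$mfe
      expect_lte(e2, e0)
    }
  }
})

test_that("any added constraint can only raise the minimum free energy", {
  for (k in 1:6) {
    s <- random_sequence(40, seed = 400 + k)
    cs <- random_constraints(s, seed = 500 + k)
    for (m in models) {
      e0 <- fold_rna(s, model = m, engine = "dense")$mfe
      ec <- fold_rna(s, model = m, engine = "dense", constraints = cs)$mfe
      expect_gte(ec, e0 - 1e-12)
    }
  }
})

test_that("traced structures re-evaluate exactly to the reported MFE", {
  for (s in seq_panel(10, 20, 60, offset = 700)) {
    for (m in models) {
      f <- fold_rna(s, model = m, engine = "dense")
      expect_equal(evaluate_structure(s, f$structure, model = m, params = params),
                   f$mfe)
    }
  }
})

test_that("dense MFEs agree exactly with the external ViennaRNA oracle", {
  skip_if(!rnafold_available(), "RNAfold not on PATH")
  for (s in seq_panel(12, 20, 60, offset = 900)) {
    for (m in models) {
      mine <- fold_rna(s, model = m, engine = "dense")$mfe
      expect_equal(mine, rnafold_mfe(s, m), tolerance = 1e-9)
    }
  }
})

test_that("invalid sequences are rejected", {
  expect_error(fold_rna("ACGX"), "invalid residue")
  expect_error(fold_rna(""), "length >= 1")
})
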