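# Sparse engine: cell-level equality with the dense oracle, candidate-set
# correctness, interior-loop scans, and the space contract.

test_that("sparse and dense recursions agree cell by cell", {
  for (k in 1:4) {
    s <- random_sequence(34 + k, seed = 1100 + k)
    for (m in models) {
      fs <- fold_rna(s, model = m, keep_matrices = TRUE)
      fd <- fold_dense(s, model = m)
      ix <- upper.tri(fs$matrices$W)
      for (nm in c("W", "Wp", "V", "WM", "WM2")) {
        expect_identical(fs$matrices[[nm]][ix], fd$matrices[[nm]][ix],
                         label = paste("matrix", nm, "model", m))
      }
    }
  }
})

test_that("the candidate set equals the dense-matrix inequality set", {
  # a span is a candidate iff its context stem energy beats the optimally
  # decomposable alternative in either the external (Vd < Wp) or the
  # multiloop (WMd < WMp, branch penalty included in WMd) context
  for (k in 1:4) {
    s <- random_sequence(28 + 3 * k, seed = 1200 + k)
    for (m in models) {
      fs <- fold_rna(s, model = m)
      M <- fold_dense(s, model = m)$matrices
      dens <- which(M$Vd < M$Wp | M$WMd < M$WMp, arr.ind = TRUE)
      dens <- dens[dens[, 2] > dens[, 1], , drop = FALSE]
      expect_setequal(paste(fs$candidates[, "i"], fs$candidates[, "j"]),
                      paste(dens[, 1], dens[, 2]))
    }
  }
})

test_that("short spans are never candidates and the worked span is one", {
  f <- fold_rna("GGGAAAACCCC", model = "d1")
  cm <- f$candidates
  expect_true(all(cm[, "j"] - cm[, "i"] > params$m))
  # the full span of the 11-mer beats any decomposition under exclusive
  # dangles, so it is an ed-candidate
  expect_true(any(cm[, "i"] == 1 & cm[, "j"] == 11))
})

test_that("interior-loop minimization uses the raw V payload, not the dangled value", {
  # reconstructed context of the printed subsequence: a 1x1 interior loop
  # C3.G17 around the 11-mer span 5..15 (A mismatches on both sides)
  s <- "AACAGGGAAAACCCCAGAA"
  fd <- fold_dense(s, model = "d1")
  M <- fd$matrices
  expect_identical(M$V[5, 15], -240L)   # -2.4 kcal/mol
  expect_identical(M$Vd[5, 15], -290L)  # -2.9 with the 3' dangle
  expect_identical(M$V[3, 17],
                   interior_energy(s, 3, 17, 5, 15) + M$V[5, 15])
  expect_identical(M$V[3, 17], -150L)   # -1.5 kcal/mol
  # the sparse candidate for span [5,15] must carry the raw V, not the
  # dangled -2.9: using Vd would wrongly shift the inner pair to 5.14
  for (st in strategies) {
    f <- fold_rna(s, model = "d1", strategy = st)
    cm <- f$candidates
    row <- cm[, "i"] == 5 & cm[, "j"] == 15
    expect_true(any(row))
    expect_identical(unname(cm[row, "V"]), -240L)
    expect_equal(f$mfe, fd$mfe)
    expect_identical(f$pt[5], 15L)
    expect_false(f$pt[5] == 14L)
    expect_equal(evaluate_structure(s, f$structure, model = "d1"), f$mfe)
  }
  # forcing the outer pair makes the interior-loop route to 5.15 optimal
  forced <- paste0("..(", strrep(".", 13), ")..")
  for (st in strategies) {
    fcon <- fold_rna(s, model = "d1", strategy = st, constraints = forced)
    expect_identical(fcon$pt[3], 17L)
    expect_identical(fcon$pt[5], 15L)
    expect_equal(evaluate_structure(s, fcon$structure, model = "d1"),
                 fcon$mfe)
  }
})

test_that("sparse equals dense under a nonzero multiloop unpaired penalty", {
  # the bundled set has c = 0; a modified set exercises the c-dependent
  # candidate terms in WM^p and WM2
  p2 <- params
  p2$ml_base <- 40L
  for (k in 1:4) {
    s <- random_sequence(45, seed = 1300 + k)
    for (m in models) for (st in strategies) {
      fs <- fold_rna(s, model = m, strategy = st, params = p2)
      fd <- fold_rna(s, model = m, engine = "dense", params = p2)
      expect_equal(fs$mfe, fd$mfe)
      expect_equal(evaluate_structure(s, fs$structure, model = m, params = p2),
                   fs$mfe)
    }
  }
})

test_that("no quadratic energy table is allocated and Z stays sub-quadratic", {
  cells_per_base <- c()
  for (n in c(50, 100, 200)) {
    s <- random_sequence(n, seed = 1400 + n)
    f <- fold_rna(s, model = "d1")
    st <- f$stats
    expect_lt(st$Z, n * (n - 1) / 2)
    expect_identical(sum(st$candidates_per_column), as.integer(st$Z))
    expect_gte(st$z_ratio, 0)
    cells_per_base <- c(cells_per_base, st$peak_dense_cells / n)
  }
  # rolling storage is a bounded multiple of n: the V band (M+2 rows) plus
  # a fixed number of rows; the per-base cost must not grow with n
  expect_lt(max(cells_per_base), params$M + 10)
  expect_lt(diff(range(cells_per_base)), 2)
})

test_that("constraints never increase the candidate count", {
  for (k in 1:5) {
    s <- random_sequence(60, seed = 1500 + k)
    cs <- random_constraints(s, seed = 1600 + k)
    for (m in models) {
      z0 <- fold_rna(s, model = m)$stats$Z
      zc <- fold_rna(s, model = m, constraints = cs)$stats$Z
      expect_lte(zc, z0)
    }
  }
})

test_that("trivial inputs produce empty candidate structure", {
  f <- fold_rna("AAAA")
  expect_equal(f$mfe, 0)
  expect_identical(f$structure, "....")
  expect_identical(nrow(f$candidates), 0L)
  expect_identical(f$stats$trace_arrows_peak, 0)
})
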