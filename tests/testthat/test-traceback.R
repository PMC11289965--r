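# Space-efficient traceback: strategy agreement, dangle-direction recovery,
# trace-arrow bookkeeping and garbage collection.

test_that("all three strategies reproduce the same MFE and valid traces", {
  for (s in seq_panel(10, 20, 60, offset = 2000)) {
    for (m in models) {
      es <- vapply(strategies, function(st) {
        f <- fold_rna(s, model = m, strategy = st)
        expect_equal(evaluate_structure(s, f$structure, model = m), f$mfe)
        f$mfe
      }, numeric(1))
      expect_identical(length(unique(es)), 1L)
    }
  }
})

test_that("a 3' dangle on a shifted outer pair is traced correctly", {
  # search seeded 12-mers for an optimum whose top-level case leaves the
  # last base unpaired and dangling on a pair ending one short of the end
  found <- NULL
  for (k in 1:200) {
    s <- random_sequence(12, seed = 2100 + k)
    f <- fold_rna(s, model = "d1", engine = "dense")
    n <- nchar(s)
    if (f$pt[n] == 0 && any(f$pt == n - 1) &&
        f$mfe < fold_rna(s, model = "d0", engine = "dense")$mfe) {
      found <- s
      break
    }
  }
  expect_false(is.null(found))
  fd <- fold_rna(found, model = "d1", engine = "dense")
  for (st in strategies) {
    f <- fold_rna(found, model = "d1", strategy = st)
    expect_equal(f$mfe, fd$mfe)
    expect_equal(evaluate_structure(found, f$structure, model = "d1"), f$mfe)
  }
})

test_that("ed-trace-arrows exist exactly under the trace strategy", {
  s <- random_sequence(60, seed = 2300)
  for (m in models) for (st in strategies) {
    f <- fold_rna(s, model = m, strategy = st)
    if (m == "d1" && st == "trace") {
      # one ed-trace-arrow per ed-candidate
      expect_identical(f$stats$ed_trace_arrows, f$stats$Z)
    } else {
      expect_identical(f$stats$ed_trace_arrows, 0)
    }
  }
})

test_that("candidate payload accounting orders triplet below standard", {
  s <- random_sequence(50, seed = 2400)
  pay <- vapply(strategies, function(st)
    fold_rna(s, model = "d1", strategy = st)$stats$candidate_payload_bytes,
    numeric(1))
  expect_lt(pay[["triplet"]], pay[["standard"]])
  # d0/d2 candidates carry only (start, V)
  expect_identical(fold_rna(s, model = "d2")$stats$candidate_payload_bytes, 8L)
})

test_that("garbage collection removes arrows yet traceback still succeeds", {
  removed <- 0
  for (k in 1:5) {
    s <- random_sequence(150, seed = 2500 + k)
    for (m in models) {
      f <- fold_rna(s, model = m, strategy = "trace")
      st <- f$stats
      removed <- removed + st$trace_arrows_removed
      expect_gte(st$trace_arrows_peak, st$trace_arrows_live)
      expect_gte(st$trace_arrows_removed, 0)
      expect_equal(evaluate_structure(s, f$structure, model = m), f$mfe)
    }
  }
  expect_gt(removed, 0)  # GC actually fires on helix-rich inputs
})

test_that("traceback respects hard constraints in every strategy", {
  for (k in 1:4) {
    s <- random_sequence(64, seed = 2600 + k)
    cs <- random_constraints(s, seed = 2700 + k)
    op <- which(cs$partner > seq_len(nchar(s)))
    for (st in strategies) {
      f <- fold_rna(s, model = "d1", strategy = st, constraints = cs)
      expect_identical(f$pt[op], cs$partner[op])
      expect_equal(evaluate_structure(s, f$structure, model = "d1"), f$mfe)
    }
  }
})
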