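# Deterministic input generators.

test_that("random sequences are deterministic and respect composition", {
  expect_identical(random_sequence(30, seed = 9), random_sequence(30, seed = 9))
  expect_identical(random_sequence(12, seed = 1, composition = c(1, 0, 0, 0)),
                   strrep("A", 12))
  s <- random_sequence(1e5, seed = 11,
                       composition = c(A = 0.1, C = 0.2, G = 0.3, U = 0.4))
  freq <- table(strsplit(s, "")[[1]])[c("A", "C", "G", "U")] / 1e5
  expect_true(all(abs(freq - c(0.1, 0.2, 0.3, 0.4)) < 0.01))
  expect_error(random_sequence(10, 1, composition = c(0.5, 0.5, 0.5, -0.5)),
               "non-negative")
  expect_error(random_sequence(10, 1, composition = c(0.5, 0.5, 0.1, 0.1)),
               "sum to 1")
  # generators leave the caller's RNG state untouched
  set.seed(123); before <- .Random.seed
  random_sequence(50, seed = 4)
  expect_identical(.Random.seed, before)
})

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  table(paste0(ch[-length(ch)], ch[-1]))
}

test_that("dinucleotide shuffle preserves the dinucleotide multiset", {
  expect_identical(dinucleotide_shuffle("AAAAAA", seed = 3), "AAAAAA")
  for (k in 1:50) {
    s <- random_sequence(sample(10:80, 1), seed = 4000 + k)
    sh <- dinucleotide_shuffle(s, seed = k)
    expect_identical(dinuc_counts(sh), dinuc_counts(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, nchar(sh), nchar(sh)),
                     substr(s, nchar(s), nchar(s)))
  }
  # deterministic, and usually a genuine rearrangement
  s <- random_sequence(60, seed = 4200)
  expect_identical(dinucleotide_shuffle(s, seed = 5),
                   dinucleotide_shuffle(s, seed = 5))
  sh <- vapply(1:10, function(k) dinucleotide_shuffle(s, seed = k), "")
  expect_gt(length(unique(sh)), 1)
})

test_that("small-case enumeration: shuffles of ACGU keep all 3 dinucleotides", {
  for (k in 1:10) {
    sh <- dinucleotide_shuffle("ACGU", seed = k)
    expect_identical(dinuc_counts(sh), dinuc_counts("ACGU"))
  }
})

test_that("fixtures carry the expected energies and fold accordingly", {
  fx <- fold_fixtures()
  for (f in fx) {
    res <- fold_rna(f$seq, model = f$model, constraints = f$constraints)
    expect_equal(res$mfe, f$mfe)
    expect_identical(res$structure, f$structure)
  }
})

test_that("the shipped fixture manifest matches the in-code fixtures", {
  dir <- system.file("extdata", "fixtures", package = "sparsefold")
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  fa <- read_fasta_rna(file.path(dir, "fixtures.fa"))
  fx <- fold_fixtures()
  expect_setequal(names(man), names(fx))
  expect_setequal(fa$name, names(fx))
  for (nm in names(fx)) {
    rec <- fa[fa$name == nm, ]
    expect_identical(rec$seq, fx[[nm]]$seq)
    res <- fold_rna(rec$seq, model = man[[nm]]$model,
                    constraints = if (is.na(rec$constraint)) NULL
                                  else rec$constraint)
    expect_equal(res$mfe, man[[nm]]$mfe)
    expect_identical(res$structure, man[[nm]]$structure)
  }
})
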