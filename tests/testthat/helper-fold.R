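# shared helpers: seeded sequence panels and the optional external oracle

params <- turner2004_params()

# fixed panel of seeded random sequences used across suites
seq_panel <- function(k, nmin = 20, nmax = 60, offset = 0) {
  lapply(seq_len(k), function(i) {
    n <- nmin + ((i * 7 + offset) %% (nmax - nmin + 1))
    random_sequence(n, seed = 10000 + offset + i)
  })
}

models <- c("d0", "d1", "d2")
strategies <- c("trace", "standard", "triplet")

rnafold_available <- function() nzchar(Sys.which("RNAfold"))

# MFE from the ViennaRNA reference implementation (same Turner 2004 set)
rnafold_mfe <- function(seq, model) {
  d <- substring(model, 2)
  out <- system2("RNAfold", c(paste0("-d", d), "--noPS"),
                 input = seq, stdout = TRUE)
  as.numeric(regmatches(out[2],
                        regexec("\\(\\s*(-?[0-9.]+)\\)$", out[2]))[[1]][2])
}

# independent line-oriented re-parse of one section of the bundled
# parameter fixture (deliberately separate from read_energy_params)
fixture_section <- function(section) {
  dir <- system.file("extdata", "turner2004", package = "sparsefold")
  lines <- unlist(lapply(sort(list.files(dir, full.names = TRUE)), readLines))
  hdr <- grep("^# ", lines)
  start <- grep(paste0("^# ", section, "$"), lines)
  stopifnot(length(start) == 1)
  stop_at <- c(hdr[hdr > start], length(lines) + 1L)[1]
  body <- lines[(start + 1):(stop_at - 1)]
  body <- gsub("/\\*.*?\\*/", " ", body)
  toks <- unlist(strsplit(trimws(body), "\\s+"))
  toks[nzchar(toks)]
}
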