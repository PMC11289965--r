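# Reading Vienna-dialect nearest-neighbor parameter files.
#
# Energies are integers in dekacal/mol (0.01 kcal/mol), the native unit of the
# file format and of all internal dynamic programming; conversion to kcal/mol
# happens only at the user-facing boundary.  "INF" entries mark forbidden
# states and parse to `ENERGY_INF`.

ENERGY_INF <- 10000000L

# Section table dimensions (number of integers expected).
# Pair order in all tables: CG GC GU UG AU UA NN (indices 1..7).
# Base order: N A C G U (indices 0..4); int22 omits N and the NN pair.
.par_sections <- list(
  stack                = 7L * 7L,
  mismatch_hairpin     = 7L * 5L * 5L,
  mismatch_interior    = 7L * 5L * 5L,
  mismatch_interior_1n = 7L * 5L * 5L,
  mismatch_interior_23 = 7L * 5L * 5L,
  mismatch_multi       = 7L * 5L * 5L,
  mismatch_exterior    = 7L * 5L * 5L,
  dangle5              = 7L * 5L,
  dangle3              = 7L * 5L,
  int11                = 7L * 7L * 5L * 5L,
  int21                = 7L * 7L * 5L * 5L * 5L,
  int22                = 6L * 6L * 4L * 4L * 4L * 4L,
  hairpin              = 31L,
  bulge                = 31L,
  interior             = 31L,
  ML_params            = 6L,
  NINIO                = 3L,
  Misc                 = 4L
)

# the file dialect spells some sections differently from our canonical names
.par_aliases <- c(
  mismatch_internal    = "mismatch_interior",
  mismatch_internal_1n = "mismatch_interior_1n",
  mismatch_internal_23 = "mismatch_interior_23",
  internal             = "interior"
)

#' Read a Vienna-dialect nearest-neighbor parameter file
#'
#' Parses the free-energy sections of an \code{## RNAfold parameter file v2.0}
#' document into the table set used by the folding engines: stacking,
#' hairpin/bulge/interior initiations, all mismatch tables, 1x1/2x1/2x2
#' special interior loops, dangling ends, multiloop constants and special
#' hairpin loops.  Enthalpy sections are ignored (folding is done at 37
#' degrees C).
#'
#' @param files Character vector of one or more file paths.  When several
#'   paths are given they are concatenated in order before parsing, so a
#'   parameter set may be shipped as consecutive text chunks.
#' @param m Minimum hairpin loop size (unpaired bases); pairs i.j require
#'   j - i > m.  Default 3, the community standard.
#' @param M Maximum interior loop size bound on p - i + j - q - 2.
#'   Default 30.
#' @return An object of class \code{rna_params}: a list of integer tables
#'   (energies in dekacal/mol) plus the model constants \code{ml_closing}
#'   (a), \code{ml_intern} (b), \code{ml_base} (c), \code{terminal_AU},
#'   \code{ninio}, \code{max_ninio}, \code{lxc}, \code{m}, \code{M} and
#'   \code{INF}.
#' @examples
#' p <- turner2004_params()
#' p$ml_closing  # multiloop initiation penalty a
#' @seealso [turner2004_params()] for the bundled Turner 2004 set.
#' @export
read_energy_params <- function(files, m = 3L, M = 30L) {
  lines <- unlist(lapply(files, function(f) {
    if (!file.exists(f)) stop("parameter file not found: ", f)
    readLines(f, warn = FALSE)
  }), use.names = FALSE)
  if (!length(lines) || !grepl("^## RNAfold parameter file", lines[[1]]))
    stop("not a Vienna parameter file: missing '## RNAfold parameter file' header")

  # split into sections, tracking line numbers for error messages
  sec_names <- character(0)
  sec_tokens <- list()
  sec_line <- integer(0)
  current <- NULL
  special <- list(Hexaloops = character(0), Tetraloops = character(0),
                  Triloops = character(0))
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (grepl("^##", line)) next
    hdr <- regmatches(line, regexec("^#\\s*([A-Za-z_0-9]+)", line))[[1]]
    if (length(hdr) == 2L) {
      current <- hdr[[2]]
      if (current == "END") current <- NULL
      if (!is.null(current) && !is.null(.par_aliases[current]) &&
          !is.na(.par_aliases[current]))
        current <- .par_aliases[[current]]
      if (!is.null(current) && !(current %in% sec_names) &&
          !grepl("_enthalpies$", current)) {
        sec_names <- c(sec_names, current)
        sec_tokens[[current]] <- character(0)
        sec_line[current] <- ln
      }
      next
    }
    if (is.null(current) || grepl("_enthalpies$", current)) next
    body <- gsub("/\\*.*?\\*/", " ", line)
    toks <- strsplit(trimws(body), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) next
    if (current %in% names(special)) {
      special[[current]] <- c(special[[current]], paste(toks, collapse = " "))
    } else {
      sec_tokens[[current]] <- c(sec_tokens[[current]], toks)
    }
  }

  num <- function(name) {
    want <- .par_sections[[name]]
    toks <- sec_tokens[[name]]
    if (is.null(toks))
      stop("parameter file: missing section '", name, "'")
    vals <- suppressWarnings(ifelse(toks == "INF", ENERGY_INF,
                                    as.integer(toks)))
    if (anyNA(vals))
      stop("parameter file: non-numeric entry in section '", name,
           "' (starting at line ", sec_line[[name]], ")")
    if (length(vals) != want)
      stop("parameter file: section '", name, "' (line ", sec_line[[name]],
           ") has ", length(vals), " entries, expected ", want)
    as.integer(vals)
  }

  loops <- function(name, width) {
    rows <- special[[name]]
    if (!length(rows)) return(stats::setNames(integer(0), character(0)))
    parts <- strsplit(rows, "\\s+")
    bad <- vapply(parts, function(p) length(p) < 2L || nchar(p[[1]]) != width,
                  logical(1))
    if (any(bad))
      stop("parameter file: malformed ", name, " entry: ",
           rows[which(bad)[1]])
    stats::setNames(as.integer(vapply(parts, `[[`, "", 2L)),
                    vapply(parts, `[[`, "", 1L))
  }

  # validate all numeric sections in declared order so errors point at the
  # first offending section
  for (nm in names(.par_sections)) num(nm)

  ml <- num("ML_params")
  ninio <- num("NINIO")
  misc <- num("Misc")

  p <- list(
    stack = num("stack"),
    mismatch_hairpin = num("mismatch_hairpin"),
    mismatch_interior = num("mismatch_interior"),
    mismatch_interior_1n = num("mismatch_interior_1n"),
    mismatch_interior_23 = num("mismatch_interior_23"),
    mismatch_multi = num("mismatch_multi"),
    mismatch_exterior = num("mismatch_exterior"),
    dangle5 = num("dangle5"),
    dangle3 = num("dangle3"),
    int11 = num("int11"),
    int21 = num("int21"),
    int22 = num("int22"),
    hairpin_init = num("hairpin"),
    bulge_init = num("bulge"),
    interior_init = num("interior"),
    tetraloops = loops("Tetraloops", 6L),
    triloops = loops("Triloops", 5L),
    hexaloops = loops("Hexaloops", 8L),
    ml_base = ml[[1]],      # c: unpaired-base penalty in a multiloop
    ml_closing = ml[[3]],   # a: multiloop initiation penalty
    ml_intern = ml[[5]],    # b: penalty per multiloop branch
    ninio = ninio[[1]],
    max_ninio = ninio[[3]],
    terminal_AU = misc[[3]],
    lxc = 107.856,          # loop-size extrapolation beyond 30 unpaired
    m = as.integer(m),
    M = as.integer(M),
    INF = ENERGY_INF
  )
  class(p) <- "rna_params"
  p
}

#' Bundled Turner 2004 parameter set
#'
#' Loads the Turner 2004 free-energy parameters shipped with the package
#' (Vienna text dialect, 37 degrees C free energies; identical values to the
#' set distributed with the ViennaRNA package, enthalpy sections omitted).
#' The set is stored as consecutive text chunks which are concatenated before
#' parsing.  The result is cached for the session.
#'
#' @inheritParams read_energy_params
#' @return An \code{rna_params} object; see [read_energy_params()].
#' @examples
#' p <- turner2004_params()
#' c(a = p$ml_closing, b = p$ml_intern, c = p$ml_base)
#' @export
turner2004_params <- function(m = 3L, M = 30L) {
  key <- paste0("turner2004_", m, "_", M)
  cached <- .sparsefold_cache[[key]]
  if (!is.null(cached)) return(cached)
  dir <- system.file("extdata", "turner2004", package = "sparsefold")
  files <- sort(list.files(dir, pattern = "\\.par$", full.names = TRUE))
  if (!length(files)) stop("bundled Turner 2004 parameter files not found")
  p <- read_energy_params(files, m = m, M = M)
  assign(key, p, envir = .sparsefold_cache)
  p
}

.sparsefold_cache <- new.env(parent = emptyenv())

#' @export
print.rna_params <- function(x, ...) {
  cat("Nearest-neighbor RNA energy parameters (dekacal/mol)\n")
  cat(sprintf("  multiloop: a = %d, b = %d, c = %d\n",
              x$ml_closing, x$ml_intern, x$ml_base))
  cat(sprintf("  terminal AU/GU penalty: %d; NINIO %d (max %d)\n",
              x$terminal_AU, x$ninio, x$max_ninio))
  cat(sprintf("  special hairpins: %d tetra, %d tri, %d hexa\n",
              length(x$tetraloops), length(x$triloops), length(x$hexaloops)))
  cat(sprintf("  m = %d (min hairpin loop), M = %d (max interior loop)\n",
              x$m, x$M))
  invisible(x)
}
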