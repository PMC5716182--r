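# Internal helpers: seeded RNG scopes, random sequence generation, logging.

#' @importFrom stats rbinom runif setNames
#' @importFrom utils head tail modifyList write.table read.delim
NULL

# Evaluate `expr` under a given integer seed without disturbing the caller's
# RNG stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

# Leveled logger; quiet unless option trapforge.verbose is TRUE, except
# warnings/errors which always surface through the condition system.
tfLog <- function(level = c("info", "warn", "error"), ...) {
  level <- match.arg(level)
  msg <- paste0("[", level, "] ", ...)
  if (level == "warn") warning(paste0(...), call. = FALSE)
  else if (isTRUE(getOption("trapforge.verbose", FALSE))) message(msg)
  invisible(msg)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# All 61 sense codons.
senseCodons <- function() {
  nt <- c("A", "C", "G", "T")
  cod <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  setdiff(cod, STOP_CODONS)
}

# Uniform random DNA of length n (character scalar). Caller controls the seed.
randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate away every occurrence of `motif` (and, for non-palindromes, its
# reverse complement) in `x` so synthetic backgrounds carry no spurious sites.
scrubMotif <- function(x, motif = "GTTTAAAC") {
  pats <- unique(c(motif, revcompChar(motif)))
  repeat {
    hit <- FALSE
    for (p in pats) {
      i <- as.integer(gregexpr(p, x, fixed = TRUE)[[1]])
      i <- i[i > 0]
      if (length(i)) {
        hit <- TRUE
        # flip the base in the middle of each occurrence to C (or A if C)
        for (j in i) {
          pos <- j + floor(nchar(p) / 2)
          b <- substr(x, pos, pos)
          substr(x, pos, pos) <- if (b == "C") "A" else "C"
        }
      }
    }
    if (!hit) return(x)
  }
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Random stop-free open reading frame of `ncodons` codons (no ATG/stop
# added). Scrubbed of the PmeI motif; the scrub substitutes a C, which can
# never create a stop codon, so frame-0 stop-freedom is preserved.
randomORF <- function(ncodons) {
  scrubMotif(paste(sample(senseCodons(), ncodons, replace = TRUE),
                   collapse = ""))
}

# Random DNA that is motif-free AND starts with G / ends with C. Because the
# PmeI motif GTTTAAAC has its only G first and its only C last, no junction
# between a guarded block and any neighbour can ever assemble the motif
# across the boundary.
guardedDNA <- function(n) {
  stopifnot(n >= 2L)
  # scrub after adding the guards: the guard bases themselves could
  # complete a motif with the interior's edge, and the scrub only ever
  # substitutes a mid-motif base, so the G/C guards survive it
  scrubMotif(paste0("G", randomDNA(n - 2L), "C"))
}

# Translate a DNA string from `from` (0-based) in-frame; returns the aa string
# up to (not including) the first stop, and whether a stop was seen.
translateToStop <- function(dna, from = 0L) {
  s <- substr(dna, from + 1L, nchar(dna))
  s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
  if (nchar(s) < 3L) return(list(aa = "", stopped = FALSE))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(s), no.init.codon = TRUE)))
  stop.at <- regexpr("*", aa, fixed = TRUE)
  if (stop.at > 0) list(aa = substr(aa, 1L, stop.at - 1L), stopped = TRUE)
  else list(aa = aa, stopped = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
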