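# shared internal helpers

.ACGT <- c("A", "C", "G", "T")
# IUPAC nucleotide alphabet accepted on input; only A/C/G/T can ever match
.IUPAC_DNA <- c(.ACGT, "U", "M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "N")
.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

.norm_seq <- function(x) toupper(gsub("[[:space:]]", "", x))

# validate characters of a single sequence; returns the character vector
.check_alphabet <- function(seq, allowed, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), allowed)
  if (length(bad) > 0) {
    stop(sprintf("invalid character(s) in %s: %s", what,
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(chars)
}

# reverse complement preserving IUPAC degeneracy codes
.revcomp <- function(x) {
  comp <- chartr("ACGTUMRWSYKVHDBN", "TGCAAKYWSRMBDHVN", .norm_seq(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.random_dna <- function(len) {
  paste(sample(.ACGT, len, replace = TRUE), collapse = "")
}

# evaluate code under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# validation failures get their own condition class so the CLI can map them
# to a dedicated exit code
.validation_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("vitiflora_validation_error", "error")))
}

.assert <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) .validation_error(fmt, ...)
  invisible(TRUE)
}
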