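# translate a vector of codons; codons containing N (or any non-ACGT) give X
.translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

.scan_orf_strand <- function(s) {
  n <- nchar(s)
  candidates <- list()
  for (fr in 0:2) {
    m <- (n - fr) %/% 3
    if (m < 2) next
    starts_nt <- fr + 3 * (seq_len(m) - 1) + 1
    codons <- substring(s, starts_nt, starts_nt + 2)
    is_start <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    open <- NA_integer_
    for (i in seq_len(m)) {
      if (is_stop[i]) {
        if (!is.na(open)) {
          candidates[[length(candidates) + 1]] <-
            list(start = fr + 3L * (open - 1L),     # 0-based, half-open
                 end = fr + 3L * i,                 # includes the stop codon
                 frame = fr,
                 protein = paste(.translate_codons(codons[open:(i - 1)]),
                                 collapse = ""))
        }
        open <- NA_integer_
      } else if (is_start[i] && is.na(open)) {
        open <- i
      }
    }
  }
  candidates
}

#' Find the longest ATG-initiated, stop-terminated open reading frame
#'
#' Scans the three forward reading frames (cloned cDNA inserts have a known
#' orientation; set `both_strands = TRUE` for raw inputs) for ORFs that start
#' at an ATG and end at an in-frame stop codon. The longest ORF wins; ties
#' are broken by the smallest start position (forward strand first when both
#' are scanned).
#'
#' @param seq Nucleotide sequence over A/C/G/T/N (case-insensitive).
#' @param both_strands Also scan the reverse complement (default `FALSE`).
#' @return `NULL` when no ORF exists, otherwise a list with `start`, `end`
#'   (0-based, half-open, including the stop codon, on the reported
#'   `strand`), `frame` (0-2), `strand` (`"+"`/`"-"`), and `protein`
#'   (stop codon not included; internal N codons translate to `X`).
#' @export
find_longest_orf <- function(seq, both_strands = FALSE) {
  stopifnot(length(seq) == 1)
  s <- .norm_seq(seq)
  .check_alphabet(s, c(.ACGT, "N"), "sequence")
  cands <- lapply(.scan_orf_strand(s), c, strand = "+")
  if (both_strands) {
    cands <- c(cands, lapply(.scan_orf_strand(.revcomp(s)), c, strand = "-"))
  }
  if (length(cands) == 0) return(NULL)
  len <- vapply(cands, function(x) nchar(x$protein), integer(1))
  minus <- vapply(cands, function(x) x$strand == "-", logical(1))
  start <- vapply(cands, `[[`, integer(1), "start")
  cands[[order(-len, minus, start)[1]]]
}

#' Classify an isolate protein as full length or prematurely stopped
#'
#' A transcript whose translated product falls well short of its reference
#' gene model's protein — here, below `min_fraction` of the reference length
#' — is treated as carrying a premature stop codon, the most common
#' loss-of-function lesion among cultivar TPS variants. The boundary is
#' inclusive: exactly `min_fraction` counts as full length.
#'
#' @param isolate_protein,reference_protein Non-empty amino-acid strings.
#' @param min_fraction Length fraction below which the isolate is called
#'   `premature_stop` (default 0.9; an operational cutoff, not a biological
#'   constant).
#' @return List with `status` (`"full_length"` or `"premature_stop"`),
#'   `fraction` and `min_fraction`.
#' @export
classify_cds <- function(isolate_protein, reference_protein,
                         min_fraction = 0.9) {
  .assert(nzchar(isolate_protein) && nzchar(reference_protein),
          "both proteins must be non-empty")
  fraction <- nchar(isolate_protein) / nchar(reference_protein)
  list(status = if (fraction >= min_fraction) "full_length" else
         "premature_stop",
       fraction = fraction, min_fraction = min_fraction)
}

#' Default terpene synthase motif patterns
#'
#' Regular expressions for the canonical TPS motifs: the N-terminal
#' `RRx8W` motif (two arginines, any eight residues, tryptophan), the
#' C-terminal aspartate-rich `DDxxD` metal-binding motif, and an explicit
#' simplification of the second metal-binding (`NSE/DTE`) consensus,
#' `[ND]D[LIV]x[ST]xxxE`. Override by passing your own named pattern vector
#' to [scan_tps_motifs()].
#'
#' @return Named character vector of regular expressions.
#' @export
tps_motif_patterns <- function() {
  c("RRx8W" = "RR.{8}W",
    "DDxxD" = "DD..D",
    "NSE/DTE" = "[ND]D[LIV].[ST]...E")
}

#' Scan a protein for terpene synthase motifs
#'
#' Reports every (possibly overlapping) match of each motif pattern, with
#' 0-based start positions on the protein.
#'
#' @param protein Amino-acid string (20-letter alphabet plus `X` and `*`).
#' @param patterns Named character vector of regular expressions (default
#'   [tps_motif_patterns()]).
#' @return Tibble with `motif`, `start` (0-based) and `match`.
#' @export
scan_tps_motifs <- function(protein, patterns = tps_motif_patterns()) {
  stopifnot(length(protein) == 1)
  protein <- toupper(trimws(protein))
  .check_alphabet(protein, .AA_ALPHABET, "protein")
  .assert(!is.null(names(patterns)) && all(nzchar(names(patterns))),
          "patterns must be named")
  out <- lapply(names(patterns), function(nm) {
    # zero-width lookahead captures overlapping matches
    m <- gregexpr(paste0("(?=(", patterns[[nm]], "))"), protein,
                  perl = TRUE)[[1]]
    if (m[1] == -1) {
      return(tibble::tibble(motif = character(), start = integer(),
                            match = character()))
    }
    cs <- attr(m, "capture.start")[, 1]
    cl <- attr(m, "capture.length")[, 1]
    tibble::tibble(motif = nm, start = as.integer(cs - 1L),
                   match = substring(protein, cs, cs + cl - 1))
  })
  dplyr::bind_rows(out)
}
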