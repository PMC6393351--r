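#' Find all full-length placements of a probe on a gene within k mismatches
#'
#' Slides the probe (and, by default, its reverse complement) along the gene
#' and reports every ungapped full-length placement whose Hamming distance is
#' at most `max_mm`. This is the exact, exhaustive replacement for a
#' short-oligo homology search: at two mismatches over a 60-mer no gapped
#' alignment can satisfy a full-length rule, so the scan loses nothing.
#'
#' `N` and any other IUPAC degeneracy code count as a mismatch wherever they
#' occur (even `N` against `N`): a degenerate base cannot support confident
#' hybridization, so the rule is conservative and deterministic.
#'
#' @param probe Probe sequence (character scalar, case-insensitive,
#'   IUPAC nucleotide alphabet).
#' @param gene Gene model cDNA sequence (same alphabet).
#' @param max_mm Maximum number of mismatches allowed (default 2).
#' @param orientations `"both"` (default) to scan the probe and its reverse
#'   complement, or `"forward"` for the given orientation only.
#' @return A tibble with one row per placement: `offset` (0-based start on
#'   the gene's given strand), `orientation` (`"forward"` or `"revcomp"`),
#'   and `mismatches`. Rows are ordered forward-before-revcomp, then by
#'   offset. Empty when the probe is longer than the gene.
#' @examples
#' hamming_matches("ACGT", "ACGTTT", max_mm = 0)
#' @export
hamming_matches <- function(probe, gene, max_mm = 2,
                            orientations = c("both", "forward")) {
  orientations <- match.arg(orientations)
  stopifnot(length(probe) == 1, length(gene) == 1, max_mm >= 0)
  probe <- .norm_seq(probe)
  gene <- .norm_seq(gene)
  if (!nzchar(probe)) stop("probe must be non-empty", call. = FALSE)
  .check_alphabet(probe, .IUPAC_DNA, "probe")
  gc <- .check_alphabet(gene, .IUPAC_DNA, "gene")

  empty <- tibble::tibble(offset = integer(), orientation = character(),
                          mismatches = integer())
  L <- nchar(probe)
  n <- nchar(gene)
  if (n == 0 || L > n) return(empty)

  gene_ok <- gc %in% .ACGT
  W <- n - L + 1L
  idx <- seq_len(W)

  scan_one <- function(p, label) {
    pc <- strsplit(p, "", fixed = TRUE)[[1]]
    pc_ok <- pc %in% .ACGT
    mm <- integer(W)
    for (j in seq_len(L)) {
      pos <- idx + j - 1L
      hit <- pc_ok[j] & gene_ok[pos] & gc[pos] == pc[j]
      mm <- mm + as.integer(!hit)
    }
    offs <- which(mm <= max_mm)
    tibble::tibble(offset = offs - 1L, orientation = label,
                   mismatches = mm[offs])
  }

  out <- scan_one(probe, "forward")
  if (orientations == "both") {
    out <- dplyr::bind_rows(out, scan_one(.revcomp(probe), "revcomp"))
  }
  out
}

#' Build a probe-to-gene cross-hybridization map
#'
#' Scans every probe against every gene model with [hamming_matches()] and
#' records, for each (probe, gene) pair with at least one placement, a single
#' minimal-mismatch hit. Ties for the minimal mismatch count within one gene
#' are broken by smallest offset, then forward orientation before reverse
#' complement, so the map is deterministic regardless of input order.
#'
#' @param probes A data frame with columns `probe_id` and `sequence`, or a
#'   named character vector of probe sequences.
#' @param genes A named character vector of gene model sequences, a
#'   `DNAStringSet`, or a data frame with columns `gene_id` and `sequence`.
#' @param max_mm Maximum mismatches for a placement to count (default 2).
#' @param orientations Passed to [hamming_matches()].
#' @return An object of class `probe_gene_map`: a list with `hits` (tibble of
#'   `probe_id`, `gene_id`, `mismatches`, `offset`, `orientation`, sorted by
#'   probe then gene), `probe_ids`, `gene_ids`, `max_mm`, `orientations`.
#' @export
build_probe_gene_map <- function(probes, genes, max_mm = 2,
                                 orientations = c("both", "forward")) {
  orientations <- match.arg(orientations)
  probes <- .as_probe_table(probes)
  genes <- .as_gene_vector(genes)
  .assert(nrow(probes) > 0, "probe table is empty")
  .assert(length(genes) > 0, "gene set is empty")

  dup_p <- unique(probes$probe_id[duplicated(probes$probe_id)])
  .assert(length(dup_p) == 0, "duplicate probe_id(s): %s",
          paste(dup_p, collapse = ", "))
  dup_g <- unique(names(genes)[duplicated(names(genes))])
  .assert(length(dup_g) == 0, "duplicate gene_id(s): %s",
          paste(dup_g, collapse = ", "))

  rows <- vector("list", nrow(probes) * length(genes))
  k <- 0L
  for (i in seq_len(nrow(probes))) {
    for (g in names(genes)) {
      hits <- hamming_matches(probes$sequence[i], genes[[g]],
                              max_mm = max_mm, orientations = orientations)
      if (nrow(hits) == 0) next
      ord <- order(hits$mismatches, hits$offset, hits$orientation != "forward")
      best <- hits[ord[1], ]
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        probe_id = probes$probe_id[i], gene_id = g,
        mismatches = best$mismatches, offset = best$offset,
        orientation = best$orientation
      )
    }
  }
  hits <- if (k > 0) dplyr::bind_rows(rows[seq_len(k)]) else
    tibble::tibble(probe_id = character(), gene_id = character(),
                   mismatches = integer(), offset = integer(),
                   orientation = character())
  hits <- dplyr::arrange(hits, .data$probe_id, .data$gene_id)

  structure(
    list(hits = hits,
         probe_ids = sort(probes$probe_id),
         gene_ids = sort(names(genes)),
         max_mm = max_mm, orientations = orientations),
    class = "probe_gene_map"
  )
}

#' @export
print.probe_gene_map <- function(x, ...) {
  cat(sprintf(
    "probe_gene_map: %d hit(s); %d probe(s) x %d gene(s); max_mm = %d (%s)\n",
    nrow(x$hits), length(x$probe_ids), length(x$gene_ids), x$max_mm,
    x$orientations))
  invisible(x)
}

.as_probe_table <- function(probes) {
  if (is.character(probes)) {
    .assert(!is.null(names(probes)), "probe vector must be named by probe_id")
    probes <- tibble::tibble(probe_id = names(probes),
                             sequence = unname(probes))
  }
  .assert(is.data.frame(probes) && all(c("probe_id", "sequence") %in%
                                         names(probes)),
          "probes must have columns 'probe_id' and 'sequence'")
  tibble::as_tibble(probes[, c("probe_id", "sequence")])
}

.as_gene_vector <- function(genes) {
  if (inherits(genes, "DNAStringSet")) {
    genes <- setNames(as.character(genes), names(genes))
  } else if (is.data.frame(genes)) {
    .assert(all(c("gene_id", "sequence") %in% names(genes)),
            "gene table must have columns 'gene_id' and 'sequence'")
    genes <- setNames(genes$sequence, genes$gene_id)
  }
  .assert(is.character(genes) && !is.null(names(genes)) &&
            all(nzchar(names(genes))),
          "genes must be a named character vector, data frame or DNAStringSet")
  genes
}

#' Classify probes as unique, ambiguous or unmapped
#'
#' Partitions the probe universe of a [build_probe_gene_map()] result:
#' probes hitting exactly one gene model are *unique*, probes hitting two or
#' more are *ambiguous* (cross-hybridizing; their signal cannot be attributed
#' to a single gene), and the rest are *unmapped*. Ambiguity is reported both
#' as a gene count and as a `"1:n"` ratio label.
#'
#' @param map A `probe_gene_map`.
#' @return An object of class `probe_classification`: list with `unique`
#'   (character vector), `ambiguous` (named integer, gene counts >= 2),
#'   `unmapped` (character vector), `ratios` (named `"1:n"` labels for every
#'   mapped probe) and `counts` (summary list).
#' @export
classify_probes <- function(map) {
  stopifnot(inherits(map, "probe_gene_map"))
  degree <- table(factor(map$hits$probe_id, levels = map$probe_ids))
  degree <- setNames(as.integer(degree), names(degree))
  unique_p <- sort(names(degree)[degree == 1])
  ambiguous <- degree[degree >= 2]
  ambiguous <- ambiguous[order(names(ambiguous))]
  unmapped <- sort(names(degree)[degree == 0])
  mapped <- degree[degree >= 1]
  ratios <- setNames(sprintf("1:%d", mapped), names(mapped))
  ratios <- ratios[order(names(ratios))]

  structure(
    list(unique = unique_p, ambiguous = ambiguous, unmapped = unmapped,
         ratios = ratios,
         counts = list(total = length(map$probe_ids),
                       mapped = length(mapped),
                       unique = length(unique_p),
                       ambiguous = length(ambiguous),
                       unmapped = length(unmapped))),
    class = "probe_classification"
  )
}

#' @export
print.probe_classification <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "probe_classification: %d probe(s) | mapped %d | unique %d | ambiguous %d | unmapped %d\n",
    total, mapped, unique, ambiguous, unmapped)))
  if (length(x$ambiguous) > 0) {
    rng <- range(x$ambiguous)
    cat(sprintf("  ambiguity ratios between 1:%d and 1:%d\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' Count probes per gene model
#'
#' @param map A `probe_gene_map`.
#' @param classification The matching [classify_probes()] result; required
#'   when `unique_only = TRUE`.
#' @param unique_only Count only uniquely binding probes (default `TRUE`).
#'   With `FALSE`, counts equal each gene's degree in the map.
#' @return Named integer vector over every gene in the map's universe
#'   (genes without hits get 0), sorted by gene id.
#' @export
probes_per_gene <- function(map, classification = NULL, unique_only = TRUE) {
  stopifnot(inherits(map, "probe_gene_map"))
  hits <- map$hits
  if (unique_only) {
    .assert(inherits(classification, "probe_classification"),
            "unique_only = TRUE requires a probe_classification")
    hits <- hits[hits$probe_id %in% classification$unique, , drop = FALSE]
  }
  counts <- table(factor(hits$gene_id, levels = map$gene_ids))
  setNames(as.integer(counts), names(counts))
}
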