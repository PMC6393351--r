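# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results through different code paths than
# the package (naive double loops, direct enumeration) so agreement is a
# real check, not a tautology.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# naive position-by-position scan over both orientations; N never matches
bf_matches <- function(probe, gene, max_mm) {
  pl <- nchar(probe)
  gl <- nchar(gene)
  out <- data.frame(offset = integer(), orientation = character(),
                    mismatches = integer())
  if (pl > gl) return(out)
  for (orient in c("forward", "revcomp")) {
    p <- if (orient == "forward") probe else rc_oracle(probe)
    pc <- strsplit(p, "")[[1]]
    for (off in 0:(gl - pl)) {
      mm <- 0L
      for (j in seq_len(pl)) {
        gch <- substr(gene, off + j, off + j)
        if (!(gch %in% c("A", "C", "G", "T")) ||
            !(pc[j] %in% c("A", "C", "G", "T")) || gch != pc[j]) {
          mm <- mm + 1L
        }
      }
      if (mm <= max_mm) {
        out <- rbind(out, data.frame(offset = off, orientation = orient,
                                     mismatches = mm))
      }
    }
  }
  out
}

# direct enumeration of every ATG..stop span over the three forward frames
bf_longest_orf <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (start in seq_len(max(0, n - 5))) {
    if (substr(seq, start, start + 2) != "ATG") next
    pos <- start + 3
    while (pos + 2 <= n) {
      codon <- substr(seq, pos, pos + 2)
      if (codon %in% c("TAA", "TAG", "TGA")) {
        plen <- (pos - start) / 3
        if (is.null(best) || plen > best$plen ||
            (plen == best$plen && start < best$start)) {
          best <- list(start = start - 1L, end = pos + 2L, plen = plen)
        }
        break
      }
      pos <- pos + 3
    }
  }
  best
}

# sliding-window motif checker with explicit per-position character tests
bf_motif_positions <- function(protein, motif) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  check <- switch(motif,
    "RRx8W" = function(w) length(w) == 11 && w[1] == "R" && w[2] == "R" &&
      w[11] == "W",
    "DDxxD" = function(w) length(w) == 5 && w[1] == "D" && w[2] == "D" &&
      w[5] == "D",
    "NSE/DTE" = function(w) length(w) == 9 && w[1] %in% c("N", "D") &&
      w[2] == "D" && w[3] %in% c("L", "I", "V") &&
      w[5] %in% c("S", "T") && w[9] == "E")
  width <- switch(motif, "RRx8W" = 11, "DDxxD" = 5, "NSE/DTE" = 9)
  hits <- integer(0)
  if (n >= width) {
    for (i in 1:(n - width + 1)) {
      if (check(chars[i:(i + width - 1)])) hits <- c(hits, i - 1L)
    }
  }
  hits
}

# tiny long-form concentration table for cascade/composition tests
make_conc <- function(values, cultivar = "MA", stage = "EL-18",
                      replicate = 1, sample_id = "s1") {
  tibble::tibble(sample_id = sample_id, cultivar = cultivar, stage = stage,
                 replicate = replicate, compound = names(values),
                 concentration = unname(values))
}
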