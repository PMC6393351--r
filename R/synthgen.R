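#' Generate a probe/gene design with planted cross-hybridization truth
#'
#' Builds random gene-model cDNA sequences and short probes in which the
#' cross-hybridization structure is planted and therefore known exactly:
#' `n_ambiguous` probes are planted into two or more genes (their ambiguity
#' degree) and every other probe into exactly one, each planting carrying a
#' mismatch count drawn from `mismatch_range`. Background sequence is
#' rejection-sampled so that no unplanted placement within `max(2,
#' mismatch_range[2])` mismatches exists anywhere — the planted truth is an
#' exact oracle for [classify_probes()], not an approximate one.
#'
#' Ambiguous plantings are assigned to the trailing genes first, so a design
#' with `n_ambiguous = k * probes_per_gene` leaves exactly the last `k`
#' genes covered only by ambiguous probes (and hence dropped by
#' [summarize_by_gene()]); their extra targets are drawn from the remaining
#' genes.
#'
#' @param n_genes Number of gene models.
#' @param probes_per_gene Probes planted per gene (home plantings).
#' @param n_ambiguous Number of probes planted into >= 2 genes.
#' @param mismatch_range Inclusive integer pair; each planting's mismatch
#'   count is drawn uniformly from it (default `c(0, 2)`).
#' @param probe_length Probe length in nucleotides (default 24).
#' @param gene_length Gene model length (default 500).
#' @param ambiguity_degrees Optional integer vector of ambiguity degrees
#'   (recycled over ambiguous probes); default draws from
#'   `2:min(n_genes, 6)`.
#' @param seed Integer seed; identical seeds give byte-identical designs.
#' @param max_tries Rejection-sampling attempts before giving up.
#' @return Object of class `probe_design_truth`: list with `genes` (named
#'   character), `probes` (tibble `probe_id`, `sequence`), `planted` (tibble
#'   `probe_id`, `gene_id`, `mismatches`), `expected_unique`,
#'   `expected_ambiguous` (named integer degrees), `params`.
#' @export
gen_probe_design <- function(n_genes, probes_per_gene = 2, n_ambiguous = 0,
                             mismatch_range = c(0, 2), probe_length = 24,
                             gene_length = 500, ambiguity_degrees = NULL,
                             seed = 1, max_tries = 100) {
  .assert(n_genes >= 1 && probes_per_gene >= 1, "need >= 1 gene and probe")
  .assert(probe_length <= gene_length,
          "impossible design: probe_length (%d) exceeds gene_length (%d)",
          probe_length, gene_length)
  .assert(n_ambiguous <= n_genes * probes_per_gene,
          "n_ambiguous exceeds the number of probes")
  .assert(n_ambiguous == 0 || n_genes >= 2,
          "ambiguous probes need at least 2 genes")
  .assert(length(mismatch_range) == 2 && mismatch_range[1] >= 0 &&
            mismatch_range[1] <= mismatch_range[2],
          "mismatch_range must be a non-decreasing pair of counts >= 0")
  if (!is.null(ambiguity_degrees)) {
    .assert(all(ambiguity_degrees >= 2 & ambiguity_degrees <= n_genes),
            "ambiguity degrees must lie in [2, n_genes]")
  }
  verify_mm <- max(2, mismatch_range[2])
  # enough room to host home + foreign plantings without overlap
  slots_needed <- probes_per_gene + n_ambiguous
  .assert(gene_length >= slots_needed * probe_length,
          "gene_length too small to host %d non-overlapping plantings",
          slots_needed)

  .with_seed(seed, {
    n_probes <- n_genes * probes_per_gene
    probe_ids <- sprintf("P%03d", seq_len(n_probes))
    gene_ids <- sprintf("G%02d", seq_len(n_genes))
    home <- rep(gene_ids, each = probes_per_gene)
    # ambiguous probes fill trailing genes first
    amb_idx <- if (n_ambiguous > 0) {
      rev(seq_len(n_probes))[seq_len(n_ambiguous)]
    } else integer(0)
    degrees <- if (n_ambiguous == 0) integer(0) else if
      (is.null(ambiguity_degrees)) {
        sample(2:min(n_genes, 6), n_ambiguous, replace = TRUE)
      } else rep_len(ambiguity_degrees, n_ambiguous)

    for (attempt in seq_len(max_tries)) {
      genes <- setNames(vapply(seq_len(n_genes),
                               function(i) .random_dna(gene_length),
                               character(1)), gene_ids)
      occupied <- setNames(rep(list(integer(0)), n_genes), gene_ids)
      probes <- character(n_probes)
      planted <- list()
      ok <- TRUE

      plant <- function(probe_seq, gene_id, mm) {
        # returns updated gene string or NULL when no free slot found
        gseq <- genes[[gene_id]]
        for (try in 1:200) {
          off <- sample.int(gene_length - probe_length + 1L, 1L) - 1L
          span <- (off + 1L):(off + probe_length)
          if (any(span %in% occupied[[gene_id]])) next
          variant <- strsplit(probe_seq, "", fixed = TRUE)[[1]]
          if (mm > 0) {
            pos <- sample.int(probe_length, mm)
            for (p in pos) {
              variant[p] <- sample(setdiff(.ACGT, variant[p]), 1)
            }
          }
          substr(gseq, off + 1L, off + probe_length) <-
            paste(variant, collapse = "")
          occupied[[gene_id]] <<- c(occupied[[gene_id]], span)
          return(gseq)
        }
        NULL
      }

      a <- 0L
      for (i in seq_len(n_probes)) {
        probes[i] <- .random_dna(probe_length)
        targets <- home[i]
        if (i %in% amb_idx) {
          a <- match(i, amb_idx)
          extra <- sample(setdiff(gene_ids, home[i]), degrees[a] - 1L)
          targets <- c(home[i], extra)
        }
        for (g in targets) {
          mm <- if (mismatch_range[1] == mismatch_range[2])
            mismatch_range[1] else
              sample(mismatch_range[1]:mismatch_range[2], 1L)
          gseq <- plant(probes[i], g, mm)
          if (is.null(gseq)) { ok <- FALSE; break }
          genes[[g]] <- gseq
          planted[[length(planted) + 1]] <-
            tibble::tibble(probe_id = probe_ids[i], gene_id = g,
                           mismatches = as.integer(mm))
        }
        if (!ok) break
      }
      if (!ok) next

      planted <- dplyr::bind_rows(planted)
      probe_tab <- tibble::tibble(probe_id = probe_ids, sequence = probes)
      # rejection check: the realized map must equal the planted truth
      map <- build_probe_gene_map(probe_tab, genes, max_mm = verify_mm)
      realized <- paste(map$hits$probe_id, map$hits$gene_id)
      expected <- paste(planted$probe_id, planted$gene_id)
      if (setequal(realized, expected) &&
          nrow(map$hits) == nrow(planted)) {
        # record the realized minimal mismatch counts (equal to the planted
        # ones unless a reverse-complement coincidence beat them, which the
        # set check already rules out for extra pairs)
        planted <- dplyr::arrange(planted, .data$probe_id, .data$gene_id)
        planted$mismatches <- map$hits$mismatches

        degree <- table(planted$probe_id)
        amb <- degree[degree >= 2]
        expected_ambiguous <- setNames(as.integer(amb), names(amb))
        expected_ambiguous <-
          expected_ambiguous[order(names(expected_ambiguous))]
        expected_unique <- sort(setdiff(probe_ids, names(expected_ambiguous)))

        return(structure(
          list(genes = genes, probes = probe_tab, planted = planted,
               expected_unique = expected_unique,
               expected_ambiguous = expected_ambiguous,
               params = list(n_genes = n_genes,
                             probes_per_gene = probes_per_gene,
                             n_ambiguous = n_ambiguous,
                             mismatch_range = mismatch_range,
                             probe_length = probe_length,
                             gene_length = gene_length, seed = seed,
                             attempts = attempt)),
          class = "probe_design_truth"))
      }
    }
    stop("failed to generate a clean design within max_tries attempts",
         call. = FALSE)
  })
}

#' @export
print.probe_design_truth <- function(x, ...) {
  cat(sprintf(
    "probe_design_truth: %d gene(s), %d probe(s) (%d ambiguous), %d planting(s)\n",
    length(x$genes), nrow(x$probes), length(x$expected_ambiguous),
    nrow(x$planted)))
  invisible(x)
}

#' Simulate probe-level expression with an optional planted hotspot
#'
#' Draws a gene-level baseline per gene, then probe values around their
#' gene's baseline, on an RMA-like log2 scale. A hotspot — a sample subset
#' by gene subset block shifted upward by `effect` standard deviations — can
#' be planted and is recorded as ground truth for [detect_hotspots()].
#'
#' @param design A [gen_probe_design()] result.
#' @param samples Character vector of sample labels (non-empty).
#' @param hotspot `NULL`, or a list with `samples`, `genes` (subsets of the
#'   declared labels) and `effect` (shift in units of `baseline_sd`).
#' @param baseline_mean,baseline_sd Log2-scale baseline mean and probe noise
#'   standard deviation (defaults 8 and 1).
#' @param seed Integer seed.
#' @return Object of class `expression_sim`: list with `expr` (probe x
#'   sample matrix), `hotspot` (planted truth, `NULL` when `effect` is 0)
#'   and `params`.
#' @export
gen_expression <- function(design, samples, hotspot = NULL,
                           baseline_mean = 8, baseline_sd = 1, seed = 1) {
  stopifnot(inherits(design, "probe_design_truth"))
  .assert(length(samples) > 0, "sample list is empty")
  .assert(!anyDuplicated(samples), "duplicate sample labels")
  if (!is.null(hotspot)) {
    .assert(all(c("samples", "genes", "effect") %in% names(hotspot)),
            "hotspot needs samples, genes and effect")
    .assert(all(hotspot$samples %in% samples),
            "hotspot samples must be declared samples")
    .assert(all(hotspot$genes %in% names(design$genes)),
            "hotspot genes must be design genes")
    if (hotspot$effect == 0) hotspot <- NULL
  }

  .with_seed(seed, {
    probe_ids <- design$probes$probe_id
    gene_ids <- names(design$genes)
    gene_base <- setNames(rnorm(length(gene_ids), baseline_mean,
                                baseline_sd), gene_ids)
    # each probe follows its home gene (first planted target)
    first_target <- vapply(split(design$planted$gene_id,
                                 design$planted$probe_id), `[`,
                           character(1), 1)
    expr <- matrix(rnorm(length(probe_ids) * length(samples),
                         mean = gene_base[first_target[probe_ids]],
                         sd = baseline_sd),
                   nrow = length(probe_ids),
                   dimnames = list(probe_ids, samples))
    if (!is.null(hotspot)) {
      hp <- probe_ids[first_target[probe_ids] %in% hotspot$genes]
      expr[hp, hotspot$samples] <- expr[hp, hotspot$samples] +
        hotspot$effect * baseline_sd
    }
    structure(list(expr = expr, hotspot = hotspot,
                   params = list(baseline_mean = baseline_mean,
                                 baseline_sd = baseline_sd, seed = seed)),
              class = "expression_sim")
  })
}

# canonical compound set of the default volatile study
.STUDY_COMPOUNDS <- c("β-caryophyllene", "α-humulene", "(E)-β-caryophyllene",
                      "(E)-β-farnesene", "(E,E)-α-farnesene",
                      "(Z,E)-α-farnesene", "(+)-valencene", "α-selinene",
                      "β-selinene", "7-epi-α-selinene", "germacrene D",
                      "(+)-aromadendrene")

#' Canonical flower sesquiterpene compound class
#'
#' The twelve sesquiterpenes of the default volatile study, in canonical
#' spelling. Useful as the `compounds` argument of [composition()] and
#' [compute_flux()] to restrict analyses to sesquiterpenes when a
#' concentration table also carries green-leaf aldehydes or alkanes.
#'
#' @return Character vector of compound names.
#' @export
sesquiterpene_compounds <- function() .STUDY_COMPOUNDS

#' Default volatile study design
#'
#' A 3-cultivar (MA, SB, SH) by 2-stage (EL-18 pre-anthesis, EL-26 full
#' bloom) by 4-replicate design over 12 flower sesquiterpenes, emulating the
#' chemotype structure of grapevine flowers: each cultivar dominated by its
#' own sesquiterpene — (E)-β-farnesene (MA), (E,E)-α-farnesene (SB),
#' (+)-valencene (SH) — MA emitting 74% more (E)-β-farnesene at EL-18 than
#' at EL-26, SH increasing (E,E)-α-farnesene by 85% from EL-18 to EL-26, MA
#' totals well below the other cultivars, and per-group humulyl-cascade
#' shares spanning 14.7-18.6% of total sesquiterpenes. Replicate noise is
#' multiplicative lognormal (concentrations are positive and right-skewed)
#' with a default sigma of 0.15, a realistic ~15% CV for biological
#' replicates of headspace GC-MS.
#'
#' @param cultivars,stages,replicates Design labels and replicate count.
#' @param sigma Lognormal noise sigma (>= 0; 0 gives exact means).
#' @param seed Integer seed stored in the design.
#' @return Object of class `volatile_study_design`: list with the labels,
#'   `replicates`, `means` (tibble `cultivar`, `stage`, `compound`, `mean`
#'   in ug/g FW), `sigma`, `seed`.
#' @export
default_volatile_design <- function(cultivars = c("MA", "SB", "SH"),
                                    stages = c("EL-18", "EL-26"),
                                    replicates = 4, sigma = 0.15, seed = 1) {
  base <- list(
    # cultivar, stage: non-humulyl means (ug/g FW), humulyl target share (%)
    list("MA", "EL-18",
         c("(E)-β-farnesene" = 8.70, "(E,E)-α-farnesene" = 1.20,
           "(Z,E)-α-farnesene" = 0, "(+)-valencene" = 0.80,
           "α-selinene" = 0.30, "7-epi-α-selinene" = 0.30,
           "β-selinene" = 0.05, "germacrene D" = 0.10,
           "(+)-aromadendrene" = 0.05), 18.6),
    list("MA", "EL-26",
         c("(E)-β-farnesene" = 5.00, "(E,E)-α-farnesene" = 1.40,
           "(Z,E)-α-farnesene" = 0, "(+)-valencene" = 0.50,
           "α-selinene" = 0.20, "7-epi-α-selinene" = 0.20,
           "β-selinene" = 0.02, "germacrene D" = 0.08,
           "(+)-aromadendrene" = 0.05), 17.8),
    list("SB", "EL-18",
         c("(E)-β-farnesene" = 2.50, "(E,E)-α-farnesene" = 12.00,
           "(Z,E)-α-farnesene" = 0, "(+)-valencene" = 3.00,
           "α-selinene" = 1.20, "7-epi-α-selinene" = 1.20,
           "β-selinene" = 0.20, "germacrene D" = 0.60,
           "(+)-aromadendrene" = 0.30), 15.8),
    list("SB", "EL-26",
         c("(E)-β-farnesene" = 2.50, "(E,E)-α-farnesene" = 12.00,
           "(Z,E)-α-farnesene" = 0.40, "(+)-valencene" = 1.50,
           "α-selinene" = 0.60, "7-epi-α-selinene" = 0.60,
           "β-selinene" = 0.04, "germacrene D" = 0.30,
           "(+)-aromadendrene" = 0.20), 15.2),
    list("SH", "EL-18",
         c("(E)-β-farnesene" = 2.50, "(E,E)-α-farnesene" = 4.00,
           "(Z,E)-α-farnesene" = 0, "(+)-valencene" = 10.00,
           "α-selinene" = 2.00, "7-epi-α-selinene" = 9.50,
           "β-selinene" = 0.30, "germacrene D" = 0.80,
           "(+)-aromadendrene" = 0.40), 14.7),
    list("SH", "EL-26",
         c("(E)-β-farnesene" = 2.50, "(E,E)-α-farnesene" = 7.40,
           "(Z,E)-α-farnesene" = 0.50, "(+)-valencene" = 8.00,
           "α-selinene" = 1.80, "7-epi-α-selinene" = 7.50,
           "β-selinene" = 0.25, "germacrene D" = 0.80,
           "(+)-aromadendrene" = 0.40), 15.9))
  # humulyl compounds split 70/27/3 and scaled to the target share
  hum_split <- c("β-caryophyllene" = 0.70, "α-humulene" = 0.27,
                 "(E)-β-caryophyllene" = 0.03)
  rows <- lapply(base, function(b) {
    nonhum <- b[[3]]
    target <- b[[4]]
    hum_total <- target / (100 - target) * sum(nonhum)
    means <- c(nonhum, hum_split * hum_total)[.STUDY_COMPOUNDS]
    tibble::tibble(cultivar = b[[1]], stage = b[[2]],
                   compound = .STUDY_COMPOUNDS, mean = unname(means))
  })
  means <- dplyr::bind_rows(rows)
  means <- means[means$cultivar %in% cultivars & means$stage %in% stages, ,
                 drop = FALSE]
  .assert(replicates >= 1, "replicates must be >= 1")
  .assert(sigma >= 0, "noise sigma must be >= 0")
  structure(list(cultivars = cultivars, stages = stages,
                 replicates = replicates, means = means, sigma = sigma,
                 seed = seed),
            class = "volatile_study_design")
}

#' Default calibration curves for the volatile study
#'
#' Exact-line calibration standards for the four compounds with authentic
#' standards — (+)-valencene, (E)-β-farnesene, β-caryophyllene and
#' α-humulene — fitted with [fit_calibration()]. The (+)-valencene curve
#' doubles as the semi-quantitation fallback.
#'
#' @param is_area Internal-standard peak area used for the standards.
#' @return Named list of `calibration_curve` objects.
#' @export
default_calibration_curves <- function(is_area = 5e4) {
  specs <- list("(+)-valencene" = c(a = 1.00, b = 0.002),
                "(E)-β-farnesene" = c(a = 1.25, b = 0.001),
                "β-caryophyllene" = c(a = 0.85, b = 0.003),
                "α-humulene" = c(a = 1.10, b = 0.000))
  conc <- c(0.01, 0.05, 0.1, 0.5, 1)  # ug in the calibration vial
  lapply(setNames(names(specs), names(specs)), function(cmp) {
    s <- specs[[cmp]]
    std <- tibble::tibble(concentration = conc,
                          area = (s[["a"]] * conc + s[["b"]]) * is_area,
                          is_area = is_area)
    fit_calibration(std, compound = cmp)
  })
}

#' Simulate a flower volatile study with matching raw peak tables
#'
#' Draws replicate concentrations as `mean * exp(rnorm(0, sigma))`
#' (multiplicative lognormal noise; `sigma = 0` returns the means exactly)
#' and back-computes GC-MS peak tables through the supplied calibration
#' curves and internal-standard area, so that [quantify()] recovers the
#' generated concentrations — a round-trip oracle for the quantification
#' stage.
#'
#' @param design A [default_volatile_design()]-style design.
#' @param curves Named list of calibration curves (default
#'   [default_calibration_curves()]).
#' @param fallback_compound Curve used for compounds without their own
#'   (default `"(+)-valencene"`).
#' @param is_area Internal-standard peak area written into the peak tables.
#' @param tissue_mass Tissue fresh weight per sample in grams (default
#'   0.010, i.e. 10 mg).
#' @return Object of class `volatile_study`: list with `design`,
#'   `concentrations` (truth tibble: `sample_id`, `cultivar`, `stage`,
#'   `replicate`, `compound`, `concentration` in ug/g FW), `peaks` (peak
#'   table consumed by [quantify()]), `curves`, `fallback_compound`.
#' @export
gen_volatile_study <- function(design = default_volatile_design(),
                               curves = default_calibration_curves(),
                               fallback_compound = "(+)-valencene",
                               is_area = 5e4, tissue_mass = 0.010) {
  stopifnot(inherits(design, "volatile_study_design"))
  .assert(design$sigma >= 0, "noise sigma must be >= 0")
  .assert(design$replicates >= 1, "replicates must be >= 1")
  .assert(all(design$means$mean >= 0), "compound means must be >= 0")
  .assert(fallback_compound %in% names(curves),
          "fallback compound '%s' has no calibration curve",
          fallback_compound)

  .with_seed(design$seed, {
    grid <- tidyr::crossing(design$means,
                            replicate = seq_len(design$replicates))
    grid$sample_id <- sprintf("%s_%s_r%d", grid$cultivar, grid$stage,
                              grid$replicate)
    noise <- if (design$sigma == 0) rep(1, nrow(grid)) else
      exp(rnorm(nrow(grid), 0, design$sigma))
    grid$concentration <- grid$mean * noise

    curve_key <- tolower(names(curves))
    fb <- curves[[fallback_compound]]
    ratio <- vapply(seq_len(nrow(grid)), function(i) {
      j <- match(tolower(grid$compound[i]), curve_key)
      cv <- if (is.na(j)) fb else curves[[j]]
      cv$slope * (grid$concentration[i] * tissue_mass) + cv$intercept
    }, numeric(1))

    conc_cols <- c("sample_id", "cultivar", "stage", "replicate",
                   "compound", "concentration")
    peaks <- tibble::tibble(
      sample_id = grid$sample_id, cultivar = grid$cultivar,
      stage = grid$stage, replicate = grid$replicate,
      compound = grid$compound, peak_area = ratio * is_area,
      is_area = is_area, tissue_mass = tissue_mass)

    structure(list(design = design,
                   concentrations = tibble::as_tibble(grid[, conc_cols]),
                   peaks = peaks, curves = curves,
                   fallback_compound = fallback_compound),
              class = "volatile_study")
  })
}

#' @export
print.volatile_study <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "volatile_study: %d cultivar(s) x %d stage(s) x %d replicate(s) x %d compound(s) (sigma = %g, seed = %d)\n",
    length(d$cultivars), length(d$stages), d$replicates,
    length(unique(d$means$compound)), d$sigma, d$seed))
  invisible(x)
}
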