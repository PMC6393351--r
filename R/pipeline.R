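.PIPELINE_STAGES <- c("simulate", "probemap", "summarize", "quantify",
                      "chemotype", "flux", "network", "seqfeat")

#' Default pipeline configuration
#'
#' @return Named list of configuration defaults; see [run_pipeline()].
#' @export
default_config <- function() {
  list(
    out_dir = "vitiflora_out",
    seed = 1,
    max_mm = 2,
    z_threshold = 1.5, min_genes = 2, min_samples = 2,
    pca_center = TRUE, pca_scale = FALSE,
    major_threshold = 10,
    cascade_map = NULL, cascade_aliases = NULL,
    profiles_csv = NULL,
    # external inputs; when NULL, the matching simulate outputs are used
    genes_fasta = NULL, probes_tsv = NULL, expression_tsv = NULL,
    peaks_csv = NULL, seqfeat_fasta = NULL,
    sim = list(n_genes = 12, probes_per_gene = 2, n_ambiguous = 4,
               gene_length = 400, probe_length = 24, n_samples = 12,
               hotspot_genes = 4, hotspot_samples = 4, hotspot_effect = 3,
               sigma = 0.15)
  )
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order and writes every output
#' under `config$out_dir`, together with a `manifest.yaml` recording inputs,
#' parameters and an MD5 checksum for each output file. Identical
#' configuration and seed give identical checksums, so full runs are
#' reproducible bit for bit.
#'
#' Stages and their dependencies:
#' * `simulate` — generate synthetic gene models, probes, expression, peak
#'   tables and truth sidecars.
#' * `probemap` — needs gene FASTA + probe TSV (from `simulate` or config
#'   paths); writes the probe-gene map and classification.
#' * `summarize` — needs `probemap` outputs and an expression matrix;
#'   writes the gene-level matrix and hotspot report.
#' * `quantify` — needs a peak table; writes the concentration table.
#' * `chemotype` — needs `quantify` output; writes compositions and PCA.
#' * `flux` — needs `quantify` output; writes cascade flux profiles.
#' * `network` — builds the enzyme-product network from the packaged (or
#'   configured) product profiles; writes GraphML/SIF/edge-TSV.
#' * `seqfeat` — ORF and motif screen of a FASTA (config path or the
#'   simulated gene models).
#'
#' @param config List overriding [default_config()] entries (or a YAML file
#'   path).
#' @param stages Character vector of stages to run (any order; executed in
#'   dependency order).
#' @return The manifest (named list), invisibly. The manifest is also
#'   written to `<out_dir>/manifest.yaml`.
#' @export
run_pipeline <- function(config = list(), stages = .PIPELINE_STAGES) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_config(), config)
  bad <- setdiff(stages, .PIPELINE_STAGES)
  .assert(length(bad) == 0, "unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  outputs <- character(0)
  state <- new.env(parent = emptyenv())
  opath <- function(...) file.path(cfg$out_dir, ...)
  declare <- function(path) outputs <<- c(outputs, path)

  need <- function(cfg_path, sim_key, stage, what) {
    if (!is.null(cfg_path)) {
      .assert(file.exists(cfg_path), "%s input does not exist: %s", what,
              cfg_path)
      return(cfg_path)
    }
    p <- opath(sim_key)
    .assert(file.exists(p),
            "missing %s: run stage '%s' first or set the config path",
            what, stage)
    p
  }

  if ("simulate" %in% stages) {
    sim <- cfg$sim
    design <- gen_probe_design(
      n_genes = sim$n_genes, probes_per_gene = sim$probes_per_gene,
      n_ambiguous = sim$n_ambiguous, gene_length = sim$gene_length,
      probe_length = sim$probe_length, seed = cfg$seed)
    samples <- sprintf("S%02d", seq_len(sim$n_samples))
    hotspot <- list(
      genes = names(design$genes)[seq_len(sim$hotspot_genes)],
      samples = samples[seq_len(sim$hotspot_samples)],
      effect = sim$hotspot_effect)
    esim <- gen_expression(design, samples, hotspot = hotspot,
                           seed = cfg$seed + 1)
    vdesign <- default_volatile_design(sigma = sim$sigma,
                                       seed = cfg$seed + 2)
    study <- gen_volatile_study(vdesign)

    declare(write_gene_fasta(design$genes, opath("genes.fasta")))
    declare(write_probe_table(design$probes, opath("probes.tsv")))
    declare(write_expression_matrix(esim$expr, opath("expression.tsv"),
                                    id_col = "probe_id"))
    declare(write_concentration_table(study$peaks, opath("peaks.csv")))
    declare(write_truth_sidecar(design, opath("truth_probe_design.yaml")))
    declare(write_truth_sidecar(esim, opath("truth_expression.yaml")))
    declare(write_truth_sidecar(study, opath("truth_volatiles.yaml")))
    state$study <- study
  }

  if ("probemap" %in% stages) {
    genes <- read_gene_fasta(need(cfg$genes_fasta, "genes.fasta",
                                  "simulate", "gene FASTA"))
    probes <- read_probe_table(need(cfg$probes_tsv, "probes.tsv",
                                    "simulate", "probe TSV"))
    map <- build_probe_gene_map(probes, genes, max_mm = cfg$max_mm)
    cls <- classify_probes(map)
    state$map <- map
    state$cls <- cls
    declare(write_probe_map(map, opath("probe_gene_map.tsv")))
    declare(write_classification(cls, opath("probe_classification.tsv")))
  }

  if ("summarize" %in% stages) {
    .assert(!is.null(state$map),
            "missing probe map: run stage 'probemap' first")
    expr <- read_expression_matrix(need(cfg$expression_tsv,
                                        "expression.tsv", "simulate",
                                        "expression matrix"))
    ge <- summarize_by_gene(expr, state$cls, state$map)
    declare(write_expression_matrix(ge$matrix, opath("gene_expression.tsv"),
                                    id_col = "gene_id"))
    if (nrow(ge$matrix) >= cfg$min_genes &&
        ncol(ge$matrix) >= cfg$min_samples) {
      hs <- detect_hotspots(ge$matrix, z_threshold = cfg$z_threshold,
                            min_genes = cfg$min_genes,
                            min_samples = cfg$min_samples)
      declare(write_hotspot_report(hs, opath("hotspots.yaml")))
    }
  }

  if ("quantify" %in% stages) {
    peaks <- if (!is.null(cfg$peaks_csv) || is.null(state$study)) {
      read_peak_table(need(cfg$peaks_csv, "peaks.csv", "simulate",
                           "peak table"))
    } else state$study$peaks
    curves <- if (!is.null(state$study)) state$study$curves else
      default_calibration_curves()
    conc <- quantify(peaks, curves, fallback = curves[["(+)-valencene"]])
    state$conc <- conc
    declare(write_concentration_table(conc, opath("concentrations.csv")))
  }

  if ("chemotype" %in% stages) {
    .assert(!is.null(state$conc),
            "missing concentrations: run stage 'quantify' first")
    comp <- composition(state$conc)
    declare(write_concentration_table(comp, opath("composition.csv")))
    wide <- tidyr::pivot_wider(
      state$conc[, c("sample_id", "compound", "concentration")],
      names_from = "compound", values_from = "concentration")
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$sample_id
    p <- pca_chemotype(m, center = cfg$pca_center, scale = cfg$pca_scale)
    pv <- tibble::tibble(component = names(p$percent_variance),
                         percent_variance = unname(p$percent_variance))
    readr::write_tsv(pv, opath("pca_variance.tsv"))
    declare(opath("pca_variance.tsv"))
    readr::write_tsv(tibble::as_tibble(p$scores, rownames = "sample_id"),
                     opath("pca_scores.tsv"))
    declare(opath("pca_scores.tsv"))
  }

  if ("flux" %in% stages) {
    .assert(!is.null(state$conc),
            "missing concentrations: run stage 'quantify' first")
    map <- load_cascade_map(cfg$cascade_map, cfg$cascade_aliases)
    flux <- compute_flux(state$conc, map, average = TRUE)
    declare(write_concentration_table(flux, opath("flux_profiles.csv")))
  }

  if ("network" %in% stages) {
    profiles <- read_product_profiles(cfg$profiles_csv)
    validate_profiles(profiles)
    map <- load_cascade_map(cfg$cascade_map, cfg$cascade_aliases)
    net <- build_network(profiles, map,
                         major_threshold = cfg$major_threshold)
    declare(export_network(net, opath("network.graphml"), "graphml"))
    declare(export_network(net, opath("network.sif"), "sif"))
    declare(export_network(net, opath("network_edges.tsv"), "edge-tsv"))
  }

  if ("seqfeat" %in% stages) {
    seqs <- read_gene_fasta(need(cfg$seqfeat_fasta, "genes.fasta",
                                 "simulate", "sequence FASTA"))
    calls <- lapply(names(seqs), function(id) {
      orf <- find_longest_orf(seqs[[id]])
      if (is.null(orf)) {
        return(tibble::tibble(seq_id = id, start = NA_integer_,
                              end = NA_integer_, frame = NA_integer_,
                              protein = NA_character_))
      }
      tibble::tibble(seq_id = id, start = orf$start, end = orf$end,
                     frame = orf$frame, protein = orf$protein)
    })
    calls <- dplyr::bind_rows(calls)
    readr::write_tsv(calls, opath("orf_calls.tsv"))
    declare(opath("orf_calls.tsv"))
    hits <- lapply(seq_len(nrow(calls)), function(i) {
      if (is.na(calls$protein[i])) return(NULL)
      h <- scan_tps_motifs(calls$protein[i])
      if (nrow(h) == 0) return(NULL)
      h$seq_id <- calls$seq_id[i]
      h[, c("seq_id", "motif", "start", "match")]
    })
    hits <- dplyr::bind_rows(hits)
    if (nrow(hits) == 0) {
      hits <- tibble::tibble(seq_id = character(), motif = character(),
                             start = integer(), match = character())
    }
    readr::write_tsv(hits, opath("motif_hits.tsv"))
    declare(opath("motif_hits.tsv"))
  }

  manifest <- list(
    package = "vitiflora",
    stages = stages,
    config = cfg,
    outputs = lapply(setNames(nm = basename(outputs)), function(b) {
      p <- outputs[basename(outputs) == b][1]
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  yaml::write_yaml(manifest, opath("manifest.yaml"))
  invisible(manifest)
}
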