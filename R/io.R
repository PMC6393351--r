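# Readers and writers for the plain-text formats the pipeline exchanges:
# FASTA gene models, 2-column probe TSVs, expression matrices (TSV, header
# row of sample labels, id column first), long concentration CSVs, probe
# map / classification TSVs and YAML truth sidecars.

#' Read gene models from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_gene_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the identifier token of the header
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write gene models to a FASTA file
#'
#' @param genes Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genes, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genes), path)
  invisible(path)
}

#' Read a probe table (probe_id, sequence) from TSV
#'
#' Column names are configurable so platform-table exports with different
#' headers can be consumed directly.
#'
#' @param path TSV path.
#' @param id_col,seq_col Column names holding probe ids and sequences.
#' @return Tibble with `probe_id`, `sequence`.
#' @export
read_probe_table <- function(path, id_col = "probe_id",
                             seq_col = "sequence") {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  .assert(all(c(id_col, seq_col) %in% names(tab)),
          "probe table must have columns '%s' and '%s'", id_col, seq_col)
  tibble::tibble(probe_id = as.character(tab[[id_col]]),
                 sequence = as.character(tab[[seq_col]]))
}

#' Write a probe table to TSV
#' @param probes Tibble with `probe_id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  readr::write_tsv(probes[, c("probe_id", "sequence")], path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample labels and row ids in the first column.
#'
#' @param path TSV path.
#' @return Numeric matrix with rownames from the first column.
#' @export
read_expression_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write an expression matrix to TSV
#' @param mat Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the id column (default `"id"`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, id_col = "id") {
  tab <- tibble::as_tibble(mat, rownames = id_col)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Write a probe-gene map to TSV
#' @param map A `probe_gene_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_map <- function(map, path) {
  stopifnot(inherits(map, "probe_gene_map"))
  readr::write_tsv(map$hits[, c("probe_id", "gene_id", "mismatches",
                                "offset", "orientation")], path)
  invisible(path)
}

#' Write a probe classification to TSV
#'
#' One row per probe: `probe_id`, `status` (unique/ambiguous/unmapped),
#' `gene_count`, `ratio` ("1:n" for mapped probes).
#'
#' @param classification A `probe_classification`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  stopifnot(inherits(classification, "probe_classification"))
  x <- classification
  tab <- dplyr::bind_rows(
    tibble::tibble(probe_id = x$unique, status = "unique", gene_count = 1L),
    tibble::tibble(probe_id = names(x$ambiguous), status = "ambiguous",
                   gene_count = unname(x$ambiguous)),
    tibble::tibble(probe_id = x$unmapped, status = "unmapped",
                   gene_count = 0L))
  tab$ratio <- ifelse(tab$gene_count > 0,
                      sprintf("1:%d", tab$gene_count), NA_character_)
  tab <- dplyr::arrange(tab, .data$probe_id)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Write a concentration table to CSV
#' @param conc Long concentration tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(conc, path) {
  readr::write_csv(conc, path)
  invisible(path)
}

#' Read a long concentration table from CSV
#' @param path CSV path.
#' @return Tibble.
#' @export
read_concentration_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read a GC-MS peak table from CSV
#' @param path CSV path with the [quantify()] peak columns.
#' @return Tibble.
#' @export
read_peak_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("sample_id", "compound", "peak_area", "is_area", "tissue_mass")
  .assert(all(req %in% names(tab)), "peak table needs columns %s",
          paste(req, collapse = ", "))
  tab
}

#' Write the planted truth of a synthetic design as a YAML sidecar
#'
#' @param truth A `probe_design_truth`, `expression_sim` or
#'   `volatile_study`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  payload <- if (inherits(truth, "probe_design_truth")) {
    list(kind = "probe_design",
         expected_unique = as.list(truth$expected_unique),
         expected_ambiguous = as.list(truth$expected_ambiguous),
         planted = lapply(seq_len(nrow(truth$planted)), function(i)
           as.list(truth$planted[i, ])),
         params = truth$params)
  } else if (inherits(truth, "expression_sim")) {
    list(kind = "expression", hotspot = truth$hotspot,
         params = truth$params)
  } else if (inherits(truth, "volatile_study")) {
    list(kind = "volatile_study",
         design = list(cultivars = truth$design$cultivars,
                       stages = truth$design$stages,
                       replicates = truth$design$replicates,
                       sigma = truth$design$sigma,
                       seed = truth$design$seed),
         concentrations = lapply(seq_len(nrow(truth$concentrations)),
                                 function(i)
                                   as.list(truth$concentrations[i, ])))
  } else {
    stop("unsupported truth object", call. = FALSE)
  }
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Write a hotspot report as YAML
#' @param report A `hotspot_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspot_report <- function(report, path) {
  stopifnot(inherits(report, "hotspot_report"))
  yaml::write_yaml(list(params = report$params, blocks = report$blocks),
                   path)
  invisible(path)
}
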