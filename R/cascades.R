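.CASCADE_CLASSES <- c("farnesyl", "humulyl", "germacradienyl",
                      "nerolidyl_bisabolyl")

.CASCADE_PALETTE <- c(farnesyl = "#E69F00", humulyl = "#999999",
                      germacradienyl = "#0072B2",
                      nerolidyl_bisabolyl = "#F0E442",
                      unassigned = "#BBBBBB")

.norm_compound <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(enc2utf8(x))))
}

#' Load a compound-to-carbocation cascade map
#'
#' Sesquiterpenes can be grouped by the carbocation intermediate their
#' biosynthesis proceeds through after ionization of farnesyl diphosphate:
#' direct deprotonation of the farnesyl cation (linear farnesenes), 1,11-ring
#' closure to the humulyl cation (humulenes, caryophyllenes), 1,10-closure to
#' the (E,E)-germacradienyl cation (germacrenes, selinenes, valencene and
#' relatives), or isomerization to nerolidyl diphosphate and the
#' nerolidyl/bisabolyl branch. The packaged default map encodes these
#' assignments; contested compounds are data, not code, so the TSV can be
#' edited or replaced.
#'
#' @param path TSV with columns `compound`, `cascade` (lines starting with
#'   `#` are comments). `NULL` loads the packaged default.
#' @param alias_path TSV with columns `alias`, `compound` mapping naming
#'   variants onto canonical compound names. `NULL` loads the packaged
#'   default; `NA` disables aliases.
#' @return Object of class `cascade_map`: list with `classes` (named by
#'   normalized compound), `aliases`, `source`.
#' @export
load_cascade_map <- function(path = NULL, alias_path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cascade_map.tsv", package = "vitiflora",
                        mustWork = TRUE)
  }
  if (is.null(alias_path)) {
    alias_path <- system.file("extdata", "cascade_aliases.tsv",
                              package = "vitiflora", mustWork = TRUE)
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  .assert(all(c("compound", "cascade") %in% names(tab)),
          "cascade map needs columns compound, cascade")
  bad <- setdiff(unique(tab$cascade), .CASCADE_CLASSES)
  .assert(length(bad) == 0, "unknown cascade class(es): %s",
          paste(bad, collapse = ", "))
  key <- .norm_compound(tab$compound)
  dup <- unique(tab$compound[duplicated(key)])
  .assert(length(dup) == 0, "compound(s) mapped more than once: %s",
          paste(dup, collapse = ", "))
  classes <- setNames(tab$cascade, key)

  aliases <- character(0)
  if (!(length(alias_path) == 1 && is.na(alias_path))) {
    atab <- readr::read_tsv(alias_path, comment = "#", show_col_types = FALSE)
    .assert(all(c("alias", "compound") %in% names(atab)),
            "alias table needs columns alias, compound")
    aliases <- setNames(.norm_compound(atab$compound),
                        .norm_compound(atab$alias))
  }
  structure(list(classes = classes, aliases = aliases, source = path),
            class = "cascade_map")
}

#' @export
print.cascade_map <- function(x, ...) {
  cat(sprintf("cascade_map: %d compound(s), %d alias(es)\n",
              length(x$classes), length(x$aliases)))
  for (cl in .CASCADE_CLASSES) {
    cat(sprintf("  %-20s %d compound(s)\n", cl, sum(x$classes == cl)))
  }
  invisible(x)
}

#' Assign compounds to carbocation cascade classes
#'
#' Alias-resolved, case-insensitive lookup. Unknown compounds return
#' `"unassigned"`, never an error: an unrecognized volatile should reduce
#' every named class share visibly rather than break the analysis.
#'
#' @param compounds Character vector of compound names.
#' @param map A [load_cascade_map()] result.
#' @return Character vector of cascade classes (`"farnesyl"`, `"humulyl"`,
#'   `"germacradienyl"`, `"nerolidyl_bisabolyl"` or `"unassigned"`).
#' @export
assign_cascade <- function(compounds, map = load_cascade_map()) {
  stopifnot(inherits(map, "cascade_map"))
  key <- .norm_compound(compounds)
  ali <- map$aliases[key]
  key <- ifelse(is.na(ali), key, unname(ali))
  cls <- map$classes[key]
  unname(ifelse(is.na(cls), "unassigned", cls))
}

#' Biosynthetic flux percentages through carbocation cascades
#'
#' Sums each sample's concentrations by cascade class and expresses them as
#' percentages of the sample's total over the compound class, the way the
#' per-cultivar flux doughnuts summarize where farnesyl diphosphate is
#' directed. Unassigned compounds stay in the denominator and are reported
#' as their own class, keeping every profile conservative and auditable.
#' With `average = TRUE`, replicate concentrations are averaged per
#' cultivar-by-stage cell *before* percentages are formed.
#'
#' @param conc Concentration table ([quantify()] output or equivalent).
#' @param map A [load_cascade_map()] result.
#' @param compounds Compound class defining the denominator (default: all
#'   compounds present).
#' @param average Average replicates per (cultivar, stage) group first
#'   (default `FALSE`).
#' @return Tibble of class percentages: grouping columns, `cascade`,
#'   `concentration` (summed ug/g FW), `percentage`, `total` (group total
#'   ug/g FW). Every group's percentages sum to 100. All-zero groups are
#'   excluded and recorded in the `excluded` attribute.
#' @export
compute_flux <- function(conc, map = load_cascade_map(),
                         compounds = unique(conc$compound),
                         average = FALSE) {
  .assert(length(compounds) > 0, "compound class is empty")
  d <- conc[conc$compound %in% compounds, , drop = FALSE]
  .assert(nrow(d) > 0, "no rows left after restricting to the compound class")

  if (average) {
    .assert(all(c("cultivar", "stage") %in% names(d)),
            "average = TRUE needs cultivar and stage columns")
    d <- dplyr::summarise(
      dplyr::group_by(d, .data$cultivar, .data$stage, .data$compound),
      concentration = mean(.data$concentration), .groups = "drop")
    d$group <- paste(d$cultivar, d$stage, sep = ".")
    keys <- c("group", "cultivar", "stage")
  } else {
    .assert("sample_id" %in% names(d), "conc needs a sample_id column")
    d$group <- d$sample_id
    keys <- intersect(c("group", "sample_id", "cultivar", "stage",
                        "replicate"), names(d))
  }
  d$cascade <- assign_cascade(d$compound, map)

  agg <- dplyr::summarise(
    dplyr::group_by(d, dplyr::across(dplyr::all_of(keys)), .data$cascade),
    concentration = sum(.data$concentration), .groups = "drop")
  # every class present for every group, zero-filled
  agg <- tidyr::complete(
    dplyr::group_by(agg, dplyr::across(dplyr::all_of(keys))),
    cascade = c(.CASCADE_CLASSES, "unassigned"),
    fill = list(concentration = 0))
  agg <- dplyr::ungroup(agg)
  totals <- tapply(agg$concentration, agg$group, sum)
  excluded <- names(totals)[totals == 0]
  agg <- agg[!(agg$group %in% excluded), , drop = FALSE]
  agg$total <- as.numeric(totals[as.character(agg$group)])
  agg$percentage <- 100 * agg$concentration / agg$total
  agg <- dplyr::arrange(agg, .data$group, .data$cascade)
  out <- tibble::as_tibble(agg)
  attr(out, "excluded") <- excluded
  out
}

#' Range of a cascade class percentage across flux profiles
#'
#' @param profiles A [compute_flux()] result (or any tibble with `cascade`
#'   and `percentage`).
#' @param cascade Cascade class name.
#' @return `c(min, max)` of the class percentage across profiles.
#' @export
flux_range <- function(profiles, cascade) {
  .assert(all(c("cascade", "percentage") %in% names(profiles)),
          "profiles needs cascade and percentage columns")
  p <- profiles$percentage[profiles$cascade == cascade]
  .assert(length(p) >= 1, "no profile carries cascade class '%s'", cascade)
  c(min = min(p), max = max(p))
}
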