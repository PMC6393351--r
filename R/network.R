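#' Read an enzyme product-percentage table
#'
#' Reads a wide CSV laid out compounds-by-enzymes (first column `compound`,
#' one column per enzyme, cells the percentage contribution of that compound
#' to the enzyme's product blend; blanks mean "not produced") into long
#' form. The packaged default table records the product percentages of
#' heterologously expressed grapevine sesquiterpene synthase cultivar
#' variants (VvivSBTPS01 through VvivMATPS28). That table contains two
#' distinct rows both originally labelled "β-Selinene" — almost certainly a
#' printing slip in the original report — kept apart here as
#' "β-Selinene (a)" and "β-Selinene (b)" to preserve the published values
#' rather than silently merging them.
#'
#' @param path CSV path; `NULL` loads the packaged default.
#' @param source Source label attached to every row (default
#'   `"this-study"`).
#' @return Tibble with `enzyme`, `compound`, `percentage`, `source`; one row
#'   per nonzero cell.
#' @export
read_product_profiles <- function(path = NULL, source = "this-study") {
  if (is.null(path)) {
    path <- system.file("extdata", "heterologous_tps_products.csv",
                        package = "vitiflora", mustWork = TRUE)
  }
  wide <- readr::read_csv(path, show_col_types = FALSE)
  .assert(names(wide)[1] == "compound", "first column must be 'compound'")
  long <- tidyr::pivot_longer(wide, -"compound", names_to = "enzyme",
                              values_to = "percentage")
  long <- long[!is.na(long$percentage) & long$percentage != 0, , drop = FALSE]
  long$source <- source
  tibble::as_tibble(long[, c("enzyme", "compound", "percentage", "source")])
}

#' Validate product-percentage profiles
#'
#' Percentage contributions of one enzyme's products should sum to roughly
#' 100; published tables round each cell, so a tolerance window (default
#' 90-101) is applied rather than an exact check. Never mutates the data.
#'
#' @param profiles Long tibble with `enzyme` and `percentage` columns.
#' @param tolerance Length-2 numeric window for acceptable per-enzyme sums.
#' @return Tibble report: `enzyme`, `total`, `within`. Enzymes outside the
#'   window are additionally raised as a warning.
#' @export
validate_profiles <- function(profiles, tolerance = c(90, 101)) {
  .assert(all(c("enzyme", "percentage") %in% names(profiles)),
          "profiles needs enzyme and percentage columns")
  .assert(length(tolerance) == 2 && tolerance[1] <= tolerance[2],
          "tolerance must be an increasing length-2 window")
  neg <- unique(profiles$enzyme[profiles$percentage < 0])
  .assert(length(neg) == 0, "negative percentage(s) for enzyme(s): %s",
          paste(neg, collapse = ", "))
  totals <- tapply(profiles$percentage, profiles$enzyme, sum)
  report <- tibble::tibble(
    enzyme = names(totals),
    total = unname(as.numeric(totals)),
    within = as.vector(totals >= tolerance[1] & totals <= tolerance[2]))
  if (any(!report$within)) {
    warning(sprintf(
      "product percentages outside [%g, %g] for: %s", tolerance[1],
      tolerance[2],
      paste(sprintf("%s (%.1f)", report$enzyme[!report$within],
                    report$total[!report$within]), collapse = ", ")))
  }
  report
}

#' Build the enzyme-to-product bipartite network
#'
#' Enzymes are source nodes, their volatiles target nodes, and each nonzero
#' percentage becomes a directed edge. Edges are classed `major` when their
#' weight strictly exceeds `major_threshold` (default 10 percent), `minor`
#' otherwise. Each enzyme node is colored by its dominant cascade: the
#' carbocation class with the largest summed percentage over the enzyme's
#' products, ties broken lexicographically and flagged. Weights are used as
#' printed — they are not renormalized to 100.
#'
#' @param profiles Long product profiles ([read_product_profiles()] form).
#' @param map A [load_cascade_map()] result used to color nodes.
#' @param major_threshold Strict threshold separating major from minor edges.
#' @return Object of class `terpene_network`: list with `nodes` (tibble:
#'   `id`, `type`, `cascade`, `color`, `tie`), `edges` (tibble: `enzyme`,
#'   `compound`, `weight`, `class`, sorted by enzyme then weight
#'   descending), `major_threshold`.
#' @export
build_network <- function(profiles, map = load_cascade_map(),
                          major_threshold = 10) {
  .assert(all(c("enzyme", "compound", "percentage") %in% names(profiles)),
          "profiles needs enzyme, compound, percentage columns")
  prof <- profiles[!is.na(profiles$percentage) & profiles$percentage != 0, ,
                   drop = FALSE]
  edges <- tibble::tibble(
    enzyme = prof$enzyme, compound = prof$compound,
    weight = prof$percentage,
    class = ifelse(prof$percentage > major_threshold, "major", "minor"))
  edges <- dplyr::arrange(edges, .data$enzyme, dplyr::desc(.data$weight),
                          .data$compound)

  compounds <- sort(unique(edges$compound))
  comp_cascade <- assign_cascade(compounds, map)
  comp_nodes <- tibble::tibble(
    id = compounds, type = "compound", cascade = comp_cascade,
    color = unname(.CASCADE_PALETTE[comp_cascade]), tie = FALSE)

  enzymes <- sort(unique(edges$enzyme))
  enz_nodes <- lapply(enzymes, function(e) {
    sub <- edges[edges$enzyme == e, , drop = FALSE]
    by_class <- tapply(sub$weight, assign_cascade(sub$compound, map), sum)
    top <- max(by_class)
    winners <- sort(names(by_class)[by_class == top])
    tibble::tibble(id = e, type = "enzyme", cascade = winners[1],
                   color = unname(.CASCADE_PALETTE[winners[1]]),
                   tie = length(winners) > 1)
  })
  nodes <- dplyr::bind_rows(c(enz_nodes, list(comp_nodes)))
  nodes <- dplyr::arrange(nodes, .data$type, .data$id)

  structure(list(nodes = nodes, edges = edges,
                 major_threshold = major_threshold),
            class = "terpene_network")
}

#' @export
print.terpene_network <- function(x, ...) {
  cat(sprintf(
    "terpene_network: %d enzyme(s), %d compound(s), %d edge(s) (%d major > %g%%)\n",
    sum(x$nodes$type == "enzyme"), sum(x$nodes$type == "compound"),
    nrow(x$edges), sum(x$edges$class == "major"), x$major_threshold))
  invisible(x)
}

#' Export a terpene network to GraphML, SIF or edge TSV
#'
#' GraphML and edge-TSV exports are lossless (weights, edge classes, node
#' cascades/colors and the major threshold survive a round trip through
#' [import_network()]); SIF carries topology and edge class only, for quick
#' loading into Cytoscape-style editors.
#'
#' @param net A `terpene_network`.
#' @param path Output file path.
#' @param format `"graphml"`, `"sif"` or `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path,
                           format = c("graphml", "sif", "edge-tsv")) {
  stopifnot(inherits(net, "terpene_network"))
  if (length(format) != 1 || !format %in% c("graphml", "sif", "edge-tsv")) {
    .validation_error("unknown network format: %s",
                      paste(format, collapse = ", "))
  }
  if (format == "graphml") {
    verts <- as.data.frame(net$nodes)
    verts$tie <- as.integer(verts$tie)
    edf <- as.data.frame(net$edges[, c("enzyme", "compound", "weight",
                                       "class")])
    g <- igraph::graph_from_data_frame(edf, directed = TRUE,
                                       vertices = verts)
    g <- igraph::set_graph_attr(g, "major_threshold", net$major_threshold)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", net$edges$enzyme, net$edges$class,
                       net$edges$compound), path)
  } else {
    readr::write_tsv(net$edges, path)
  }
  invisible(path)
}

#' Import a GraphML network written by [export_network()]
#'
#' @param path GraphML file path.
#' @return A `terpene_network`.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  verts <- igraph::as_data_frame(g, what = "vertices")
  edf <- igraph::as_data_frame(g, what = "edges")
  nodes <- tibble::tibble(id = verts$name, type = verts$type,
                          cascade = verts$cascade, color = verts$color,
                          tie = as.logical(verts$tie))
  nodes <- dplyr::arrange(nodes, .data$type, .data$id)
  edges <- tibble::tibble(enzyme = edf$from, compound = edf$to,
                          weight = as.numeric(edf$weight), class = edf$class)
  edges <- dplyr::arrange(edges, .data$enzyme, dplyr::desc(.data$weight),
                          .data$compound)
  structure(list(nodes = nodes, edges = edges,
                 major_threshold =
                   as.numeric(igraph::graph_attr(g, "major_threshold"))),
            class = "terpene_network")
}
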