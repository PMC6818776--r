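#' Network specification of a dyadic behaviour analysis
#'
#' A `network_spec` is the renderer-independent description of one of
#' the analysis networks: behaviour categories as nodes (with a size
#' value and a border shade) and directed sequencing relations as edges
#' (weight, sign, solid/dashed style, significance flag). Auto-loops
#' (first = second) are kept but carry a downscale factor so cross-node
#' structure stays readable.
#'
#' @param nodes data frame with columns `category`, `size`, `shade`.
#' @param edges data frame with columns `first`, `second`, `weight`,
#'   `sign`, `style`, `significant`.
#' @param auto_loop_scale factor in `(0, 1]` applied to auto-loop widths
#'   at render time.
#' @param min_node_size node size floor used when building `nodes`.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(nodes, edges, auto_loop_scale = 0.5,
                         min_node_size = 0.05) {
  stopifnot(all(c("category", "size", "shade") %in% names(nodes)),
            all(c("first", "second", "weight", "sign", "style",
                  "significant") %in% names(edges)) || nrow(edges) == 0)
  if (any(nodes$size < min_node_size - 1e-12))
    stop("node sizes must respect the minimum node size")
  if (nrow(edges) && any((edges$sign < 0) != (edges$style == "dashed")))
    stop("dashed style must coincide with negative sign")
  if (auto_loop_scale <= 0 || auto_loop_scale > 1)
    stop("auto_loop_scale must be in (0, 1]")
  structure(list(nodes = nodes, edges = edges,
                 auto_loop_scale = auto_loop_scale,
                 min_node_size = min_node_size),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Network spec:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      sum(x$edges$first == x$edges$second), "auto-loops )\n")
  invisible(x)
}

empty_edges <- function() {
  data.frame(first = character(), second = character(), weight = numeric(),
             sign = numeric(), style = character(), significant = logical(),
             stringsAsFactors = FALSE)
}

#' Build the sample-average network
#'
#' Nodes are the behaviour categories, sized by the sample-mean relative
#' frequency (floored at `min_node_size` so labels stay readable); a
#' directed edge is drawn for every ordered pair whose mean sequencing
#' likelihood differs significantly from chance at level `alpha`, with
#' weight `|mean jac_norm|`, solid when the sequence occurs more often
#' than chance and dashed when less often. The per-pair summaries carry
#' an upper-tailed p-value (is the sequence *more* likely than chance);
#' for edge selection this is folded into a two-sided test by default so
#' below-chance sequencing also shows up, as dashed edges
#' (`tail = "upper"` restricts edges to above-chance sequencing).
#'
#' @param summaries a `sample_summary` from [summarize_sample()].
#' @param alpha significance level for drawing an edge (default 0.05).
#' @param tail `"two"` (default) or `"upper"`.
#' @param min_node_size node size floor.
#' @param node_scale linear factor from mean frequency to node size.
#' @param auto_loop_scale downscale factor for auto-loop widths.
#' @return A [network_spec()].
#' @export
build_sample_network <- function(summaries, alpha = 0.05,
                                 tail = c("two", "upper"),
                                 min_node_size = 0.05, node_scale = 1,
                                 auto_loop_scale = 0.5) {
  tail <- match.arg(tail)
  if (!inherits(summaries, "sample_summary"))
    stop("'summaries' must be a sample_summary")
  fr <- summaries$frequencies
  sq <- summaries$sequences
  if (!nrow(fr) || nrow(sq) != nrow(fr)^2)
    stop("summaries must cover all categories and all ordered pairs")
  nodes <- data.frame(category = fr$category,
                      size = pmax(min_node_size, node_scale * fr$mean),
                      shade = "black", stringsAsFactors = FALSE)
  p <- sq$p_value
  p_sel <- if (tail == "two") 2 * pmin(p, 1 - p) else p
  keep <- !is.na(p_sel) & p_sel < alpha & !is.na(sq$mean)
  edges <- if (any(keep)) {
    data.frame(first = sq$first[keep], second = sq$second[keep],
               weight = abs(sq$mean[keep]), sign = sign(sq$mean[keep]),
               style = ifelse(sq$mean[keep] < 0, "dashed", "solid"),
               significant = TRUE, stringsAsFactors = FALSE)
  } else empty_edges()
  network_spec(nodes, edges, auto_loop_scale, min_node_size)
}

#' Build a covariate correlation network
#'
#' Depicts how one covariate (e.g. trust) relates to the behaviour
#' profile: node size is the absolute Spearman correlation between the
#' category's relative frequency and the covariate, node border shade
#' encodes the correlation sign (grey positive, black negative), and a
#' directed edge appears for each sequencing likelihood whose
#' correlation with the covariate is significant at `alpha`, sized by
#' `|rho|`, dashed when negative.
#'
#' @param correlations output of [correlate_attachment()] filtered to a
#'   single covariate (rows of both measure types).
#' @param alpha significance level for drawing an edge.
#' @param partial use the partial (`partial_rho`/`partial_p`) instead of
#'   the bivariate columns.
#' @param min_node_size node size floor.
#' @param auto_loop_scale downscale factor for auto-loop widths.
#' @return A [network_spec()].
#' @export
build_correlation_network <- function(correlations, alpha = 0.05,
                                      partial = FALSE,
                                      min_node_size = 0.05,
                                      auto_loop_scale = 0.5) {
  if (length(unique(correlations$covariate)) != 1)
    stop("correlations must concern exactly one covariate")
  rho_col <- if (partial) "partial_rho" else "rho"
  p_col <- if (partial) "partial_p" else "p_value"
  fr <- correlations[correlations$measure_type == "frequency", ]
  sq <- correlations[correlations$measure_type == "sequence", ]
  if (!nrow(fr) || !nrow(sq))
    stop("need both frequency and sequence correlations")
  rho_f <- fr[[rho_col]]
  nodes <- data.frame(
    category = fr$first,
    size = pmax(min_node_size, abs(ifelse(is.na(rho_f), 0, rho_f))),
    shade = ifelse(!is.na(rho_f) & rho_f < 0, "black", "grey"),
    stringsAsFactors = FALSE)
  keep <- !is.na(sq[[p_col]]) & sq[[p_col]] < alpha & !is.na(sq[[rho_col]])
  edges <- if (any(keep)) {
    r <- sq[[rho_col]][keep]
    data.frame(first = sq$first[keep], second = sq$second[keep],
               weight = abs(r), sign = sign(r),
               style = ifelse(r < 0, "dashed", "solid"),
               significant = TRUE, stringsAsFactors = FALSE)
  } else empty_edges()
  network_spec(nodes, edges, auto_loop_scale, min_node_size)
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a network specification to DOT or GraphML
#'
#' Serialization is deterministic: the same spec always yields the same
#' bytes. Node attributes carry size and shade, edge attributes weight,
#' sign, style and significance; auto-loop widths are pre-multiplied by
#' the spec's downscale factor. A fixed circular ordering of the nodes
#' (as listed in the spec) is emitted as a layout hint. GraphML output
#' can be re-imported with [read_network_graphml()].
#'
#' @param spec a [network_spec()].
#' @param format `"dot"` or `"graphml"`.
#' @param path optional file to write to.
#' @return Character vector of output lines, invisibly when `path` is
#'   given.
#' @export
export_network <- function(spec, format = c("dot", "graphml"), path = NULL) {
  format <- match.arg(format)
  if (format == "dot") {
    n <- nrow(spec$nodes)
    ang <- 2 * pi * (seq_len(n) - 1) / n
    node_lines <- sprintf(
      '  %s [width=%.4f, color=%s, pos="%.3f,%.3f!"];',
      dot_quote(spec$nodes$category), spec$nodes$size, spec$nodes$shade,
      2 * cos(ang), 2 * sin(ang))
    edge_lines <- if (nrow(spec$edges)) {
      w <- spec$edges$weight *
        ifelse(spec$edges$first == spec$edges$second, spec$auto_loop_scale, 1)
      sprintf('  %s -> %s [penwidth=%.4f, weight=%.4f, sign=%d, style=%s];',
              dot_quote(spec$edges$first), dot_quote(spec$edges$second),
              pmax(w * 10, 0.1), spec$edges$weight,
              as.integer(spec$edges$sign), spec$edges$style)
    } else character()
    lines <- c("digraph behavior_network {", "  layout=neato;",
               node_lines, edge_lines, "}")
  } else {
    g <- igraph::graph_from_data_frame(
      d = if (nrow(spec$edges)) spec$edges else empty_edges(),
      directed = TRUE,
      vertices = spec$nodes)
    igraph::graph_attr(g, "auto_loop_scale") <- spec$auto_loop_scale
    igraph::graph_attr(g, "min_node_size") <- spec$min_node_size
    tmp <- tempfile(fileext = ".graphml")
    on.exit(unlink(tmp))
    igraph::write_graph(g, tmp, format = "graphml")
    lines <- readLines(tmp, warn = FALSE)
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Re-import a GraphML network export
#'
#' Inverse of [export_network()] with `format = "graphml"`: recovers an
#' attribute-equal [network_spec()].
#'
#' @param path GraphML file written by [export_network()].
#' @return A [network_spec()].
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(category = igraph::V(g)$name,
                      size = igraph::V(g)$size,
                      shade = igraph::V(g)$shade,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- if (nrow(el)) {
    data.frame(first = el[, 1], second = el[, 2],
               weight = igraph::E(g)$weight, sign = igraph::E(g)$sign,
               style = igraph::E(g)$style,
               significant = as.logical(igraph::E(g)$significant),
               stringsAsFactors = FALSE)
  } else empty_edges()
  network_spec(nodes, edges,
               auto_loop_scale = igraph::graph_attr(g, "auto_loop_scale"),
               min_node_size = igraph::graph_attr(g, "min_node_size"))
}

#' Plot a network specification
#'
#' Draws the spec with the same visual encoding as the exports: node
#' area by size value, edge width by weight (auto-loops downscaled),
#' dashed edges for negative relations, on a fixed circular layout.
#'
#' @param x a [network_spec()].
#' @param ... further arguments passed to [igraph::plot.igraph()].
#' @return `x`, invisibly.
#' @export
plot.network_spec <- function(x, ...) {
  g <- igraph::graph_from_data_frame(
    d = if (nrow(x$edges)) x$edges else empty_edges(),
    directed = TRUE, vertices = x$nodes)
  w <- if (nrow(x$edges))
    x$edges$weight * ifelse(x$edges$first == x$edges$second,
                            x$auto_loop_scale, 1) else numeric()
  igraph::plot.igraph(
    g, layout = igraph::layout_in_circle(g),
    vertex.size = 15 + 40 * x$nodes$size,
    vertex.color = "white",
    vertex.frame.color = x$nodes$shade,
    edge.width = 1 + 8 * w,
    edge.lty = if (nrow(x$edges))
      ifelse(x$edges$style == "dashed", 2, 1) else 1,
    edge.curved = 0.15, ...)
  invisible(x)
}
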