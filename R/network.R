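#' Build a glycan biosynthesis network over a panel
#'
#' Nodes are the detected panel compositions; a directed edge a -> b is
#' drawn when b extends a by exactly one residue of one kind (one Hex,
#' HexNAc, Fuc or NeuAc), i.e. a single glycosyltransferase step. Only
#' detected compositions appear; no intermediate nodes are inferred.
#' Residue counts strictly increase along edges, so the graph is acyclic.
#'
#' @param panel Panel tibble (see [reference_panel()]); codes must be
#'   unique.
#' @param model A [mass_model()] for node m/z attributes.
#' @return An [igraph::igraph] directed graph; node attributes `name`
#'   (code), `label_mz` (integer peak label), `mz`, `type`; edge
#'   attributes `residue` and `delta_mz`.
#' @examples
#' g <- build_network(reference_panel())
#' igraph::gorder(g)
#' @export
build_network <- function(panel, model = mass_model()) {
  panel <- check_composition(panel, require_valid = TRUE)
  if (!"code" %in% names(panel)) panel$code <- format_glycan_code(panel)
  if (anyDuplicated(panel$code)) {
    abort("Panel codes must be unique to build a biosynthesis network.")
  }
  cls <- classify_glycans(panel)
  mz <- glycan_mz(panel, model)
  counts <- as.matrix(panel[, c("hex", "hexnac", "fuc", "neuac")])
  n <- nrow(panel)
  from <- integer(0); to <- integer(0); residue <- character(0)
  residues <- c("hex", "hexnac", "fuc", "neuac")
  for (i in seq_len(n)) {
    d <- sweep(counts, 2, counts[i, ], "-")
    # b - a == +1 in exactly one residue kind
    hits <- which(rowSums(d == 1) == 1 & rowSums(d == 0) == 3)
    for (j in hits) {
      from <- c(from, i); to <- c(to, j)
      residue <- c(residue, residues[which(d[j, ] == 1)])
    }
  }
  delta <- model$residues[residue]
  delta[residue == "neuac"] <- delta[residue == "neuac"] + model$methyl_ester
  g <- igraph::graph_from_data_frame(
    data.frame(from = panel$code[from], to = panel$code[to],
               residue = residue, delta_mz = unname(delta),
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = panel$code,
                          label_mz = as.integer(floor(mz)),
                          mz = mz, type = cls$type,
                          stringsAsFactors = FALSE)
  )
  g
}

#' Annotate a biosynthesis network with group fold changes
#'
#' Adds a `log2fc` node attribute: log2 of the ratio of arithmetic group
#' means, log2(mean over case samples / mean over control samples), per
#' glycan.
#'
#' @param graph Network from [build_network()].
#' @param abundance Wide abundance tibble (`sample_id` + glycan columns).
#' @param groups Character/factor vector of group labels aligned with the
#'   rows of `abundance`.
#' @param case,control Group labels for numerator and denominator means.
#' @param panel Panel used to resolve column names.
#' @return The graph with a `log2fc` node attribute.
#' @export
annotate_fold_change <- function(graph, abundance, groups,
                                 case = "UC", control = "HLT",
                                 panel = reference_panel()) {
  groups <- as.character(groups)
  if (length(groups) != nrow(abundance)) {
    abort("`groups` must align with the rows of `abundance`.")
  }
  if (sum(groups == case) < 1 || sum(groups == control) < 1) {
    abort("Both groups need at least one sample.")
  }
  cols <- resolve_glycan_columns(abundance, panel)
  vals <- as.matrix(abundance[, cols$column, drop = FALSE])
  if (any(vals <= 0)) abort("All abundances must be positive.")
  mean_case <- colMeans(vals[groups == case, , drop = FALSE])
  mean_control <- colMeans(vals[groups == control, , drop = FALSE])
  if (any(mean_control == 0)) abort("Zero control mean: ratio undefined.")
  log2fc <- setNames(log2(mean_case / mean_control), cols$code)
  nodes <- igraph::V(graph)$name
  missing_nodes <- setdiff(nodes, names(log2fc))
  if (length(missing_nodes) > 0) {
    abort(paste0("No abundance column for network node(s): ",
                 paste(missing_nodes, collapse = ", "), "."))
  }
  igraph::set_vertex_attr(graph, "log2fc", value = unname(log2fc[nodes]))
}

#' Export a biosynthesis network for graph tools
#'
#' GraphML carries node and edge attributes in one file. The SIF format
#' writes one `source addition target` line per edge (isolated nodes as
#' bare names) plus a tab-delimited node attribute table
#' (`<path>` with extension replaced by `_attributes.tsv`).
#'
#' @param graph Network from [build_network()], optionally annotated.
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return Invisibly, the path(s) written.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  edges <- igraph::as_data_frame(graph, what = "edges")
  nodes <- igraph::as_data_frame(graph, what = "vertices")
  lines <- character(0)
  if (nrow(edges) > 0) {
    lines <- paste(edges$from, "addition", edges$to)
  }
  isolated <- setdiff(nodes$name, unique(c(edges$from, edges$to)))
  lines <- c(lines, isolated)
  writeLines(lines, path)
  attr_path <- sub("\\.[^.]*$", "", path)
  attr_path <- paste0(attr_path, "_attributes.tsv")
  attrs <- tibble(
    code = nodes$name,
    label = nodes$label_mz %||% NA_integer_,
    type = nodes$type %||% NA_character_,
    log2fc = if ("log2fc" %in% names(nodes)) nodes$log2fc else NA_real_
  )
  readr::write_tsv(attrs, attr_path)
  invisible(c(path, attr_path))
}

#' Re-import an exported network
#'
#' @param path File written by [export_graph()].
#' @param format `"graphml"` or `"sif"`.
#' @return An igraph graph. For SIF, node attributes are restored from the
#'   companion `_attributes.tsv` table when present.
#' @export
import_graph <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "[\t ]+")
  len <- vapply(fields, length, integer(1))
  if (any(!len %in% c(1, 3))) {
    abort("Malformed SIF line: expected `source relation target` or a bare node.")
  }
  edges <- do.call(rbind, lapply(fields[len == 3], function(f) f[c(1, 3)]))
  isolated <- unlist(fields[len == 1])
  node_names <- unique(c(as.vector(t(edges)), isolated))
  attr_path <- paste0(sub("\\.[^.]*$", "", path), "_attributes.tsv")
  vertices <- data.frame(name = node_names, stringsAsFactors = FALSE)
  if (file.exists(attr_path)) {
    attrs <- readr::read_tsv(attr_path, show_col_types = FALSE)
    vertices <- as.data.frame(
      attrs[match(node_names, attrs$code), , drop = FALSE]
    )
    names(vertices)[names(vertices) == "code"] <- "name"
    names(vertices)[names(vertices) == "label"] <- "label_mz"
  }
  edge_df <- if (is.null(edges)) {
    data.frame(from = character(0), to = character(0))
  } else {
    data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(edge_df, directed = TRUE, vertices = vertices)
}

#' Mean fold change per structural class
#'
#' Summarises an annotated network: per structural type and per aggregate
#' class, the member count and the mean and median node log2 fold change.
#'
#' @param graph Annotated network (see [annotate_fold_change()]).
#' @return A tibble with columns `class`, `n`, `mean_log2fc`,
#'   `median_log2fc`.
#' @export
class_summary <- function(graph) {
  nodes <- igraph::as_data_frame(graph, what = "vertices")
  if (!"log2fc" %in% names(nodes)) {
    abort("Network is not annotated with fold changes; run annotate_fold_change() first.")
  }
  cls <- classify_glycans(parse_glycan_code(nodes$name))
  preds <- class_predicates()
  purrr::map_dfr(names(preds), function(p) {
    sel <- preds[[p]](cls)
    tibble(
      class = p, n = sum(sel),
      mean_log2fc = if (any(sel)) mean(nodes$log2fc[sel]) else NA_real_,
      median_log2fc = if (any(sel)) median(nodes$log2fc[sel]) else NA_real_
    )
  })
}
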