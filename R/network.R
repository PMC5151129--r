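#' Build class-specific correlation networks
#'
#' For each class, emits an edge for every molecule pair whose Spearman
#' correlation exceeds the threshold in absolute value (strictly). Optionally
#' restricted to a marker pair set, reproducing the "differentially
#' correlated pairs only" view.
#'
#' @param object an [expression_set()] or numeric matrix (then `class`
#'   required).
#' @param class two-level factor (ignored for an [expression_set()]).
#' @param r_threshold absolute-correlation edge threshold (default 0.40,
#'   strict `>`).
#' @param restrict_to optional data.frame with columns `molecule_a`,
#'   `molecule_b` (e.g. [markers()] output): only these pairs are considered.
#' @return data.frame of class `"network_edges"`: `class`, `molecule_a`,
#'   `molecule_b`, `r`, `sign` ("positive"/"negative"), `differential`
#'   (pair is in `restrict_to`, or NA when unrestricted and no marker set
#'   given).
#' @export
build_network <- function(object, class = NULL, r_threshold = 0.40,
                          restrict_to = NULL) {
  if (inherits(object, "expression_set")) {
    vals <- object$values
    class <- object$class
  } else {
    vals <- as.matrix(object)
    if (is.null(class)) stop("'class' is required when 'object' is a matrix")
    class <- droplevels(as.factor(class))
  }
  stopifnot(nlevels(class) == 2)
  mols <- colnames(vals)
  key <- NULL
  if (!is.null(restrict_to)) {
    restrict_to <- as.data.frame(restrict_to)
    stopifnot(all(c("molecule_a", "molecule_b") %in% names(restrict_to)))
    key <- c(paste(restrict_to$molecule_a, restrict_to$molecule_b),
             paste(restrict_to$molecule_b, restrict_to$molecule_a))
  }
  out <- list()
  for (lv in levels(class)) {
    g <- vals[class == lv, , drop = FALSE]
    R <- suppressWarnings(
      stats::cor(g, method = "spearman", use = "pairwise.complete.obs"))
    ij <- which(upper.tri(R), arr.ind = TRUE)
    r <- R[ij]
    pk <- paste(mols[ij[, 1]], mols[ij[, 2]])
    sel <- !is.na(r) & abs(r) > r_threshold
    if (!is.null(key)) sel <- sel & (pk %in% key)
    out[[lv]] <- data.frame(
      class = rep(lv, sum(sel)),
      molecule_a = mols[ij[sel, 1]], molecule_b = mols[ij[sel, 2]],
      r = r[sel],
      sign = ifelse(r[sel] >= 0, "positive", "negative"),
      differential = if (is.null(key)) rep(NA, sum(sel)) else pk[sel] %in% key,
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  rownames(edges) <- NULL
  attr(edges, "r_threshold") <- r_threshold
  class(edges) <- c("network_edges", "data.frame")
  edges
}

#' Node degrees of a correlation network, per class
#'
#' Counts supra-threshold edges per molecule within each class; molecules
#' with many edges are the network's hubs.
#'
#' @param edges a [build_network()] result.
#' @return data.frame with `class`, `molecule`, `degree`, sorted by degree
#'   within class (descending).
#' @export
network_hubs <- function(edges) {
  stopifnot(inherits(edges, "network_edges") || is.data.frame(edges))
  out <- lapply(split(edges, edges$class), function(e) {
    tab <- sort(table(c(e$molecule_a, e$molecule_b)), decreasing = TRUE)
    data.frame(class = if (nrow(e)) e$class[1] else character(),
               molecule = names(tab), degree = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export correlation networks to GraphML and SIF
#'
#' Writes one GraphML and one SIF file per class, with the correlation,
#' sign and differential flag as edge attributes (SIF uses the sign as the
#' relation type). Exports are round-trippable: [read_network_sif()] returns
#' the same edge set.
#'
#' @param edges a [build_network()] result.
#' @param path_prefix output prefix; files are
#'   `<prefix>_<class>.graphml` and `<prefix>_<class>.sif`.
#' @param classes classes to write files for; defaults to those present in
#'   `edges`. Passing them explicitly yields valid empty-graph files for
#'   classes without supra-threshold edges.
#' @return character vector of the written paths, invisibly.
#' @export
export_network <- function(edges, path_prefix, classes = unique(edges$class)) {
  stopifnot(is.data.frame(edges))
  paths <- character()
  for (lv in classes) {
    e <- edges[edges$class == lv, , drop = FALSE]
    gml <- paste0(path_prefix, "_", lv, ".graphml")
    sif <- paste0(path_prefix, "_", lv, ".sif")
    g <- igraph::graph_from_data_frame(
      e[, c("molecule_a", "molecule_b", "r", "sign", "differential")],
      directed = FALSE)
    ok <- tryCatch({
      igraph::write_graph(g, gml, format = "graphml")
      TRUE
    }, error = function(err) err)
    if (!isTRUE(ok)) stop("failed to write ", gml, ": ", conditionMessage(ok))
    lines <- if (nrow(e)) {
      paste(e$molecule_a, e$sign, e$molecule_b, sep = "\t")
    } else character()
    writeLines(lines, sif)
    paths <- c(paths, gml, sif)
  }
  invisible(paths)
}

#' @rdname export_network
#' @param path a SIF file written by [export_network()].
#' @export
read_network_sif <- function(path) {
  if (!file.exists(path)) stop("no such SIF file: ", path)
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(molecule_a = character(), sign = character(),
                      molecule_b = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) stop("malformed SIF line(s) in ", path, ": ",
                     paste(which(bad), collapse = ", "))
  m <- do.call(rbind, parts)
  data.frame(molecule_a = m[, 1], sign = m[, 2], molecule_b = m[, 3],
             stringsAsFactors = FALSE)
}
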