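#' Build an expressed-protein interaction network
#'
#' Keeps edges only when both endpoints are in the expressed set, drops
#' self-loops and merges duplicate edges with the union of their source
#' tags.
#'
#' @param edge_list data frame whose first two columns are interactors;
#'   an optional `source` column carries provenance tags.
#' @param expressed_set character vector of expressed proteins.
#' @return list of class `ppi_graph`: `graph` (igraph, undirected simple),
#'   `edges` data frame (a, b, sources), `universe`.
#' @export
build_ppi <- function(edge_list, expressed_set) {
  if (length(expressed_set) == 0) stop("expressed set is empty")
  el <- as.data.frame(edge_list)
  if (ncol(el) < 2) stop("edge list needs two endpoint columns")
  a <- as.character(el[[1]]); b <- as.character(el[[2]])
  src <- if ("source" %in% names(el)) as.character(el$source)
         else rep("unspecified", nrow(el))
  bad <- which(is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b))
  if (length(bad) > 0)
    stop("malformed edge row(s): ", paste(bad, collapse = ", "))
  keep <- a %in% expressed_set & b %in% expressed_set & a != b
  a <- a[keep]; b <- b[keep]; src <- src[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  sources <- vapply(split(src, key), function(s)
    paste(sort(unique(s)), collapse = ";"), character(1))
  uk <- names(sources)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  edges <- data.frame(a = vapply(parts, `[`, "", 1),
                      b = vapply(parts, `[`, "", 2),
                      sources = unname(sources), row.names = NULL)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = sort(unique(expressed_set)))
  structure(list(graph = g, edges = edges,
                 universe = sort(unique(expressed_set))),
            class = "ppi_graph")
}

#' First-degree neighborhood of a seed set
#'
#' Seeds plus all of their direct interaction partners.  Seeds absent from
#' the network are skipped with a warning.
#'
#' @param ppi a `ppi_graph`.
#' @param seeds character vector of seed proteins.
#' @return sorted character vector of the neighborhood (empty, with a
#'   warning, when no seed is present).
#' @export
first_degree_neighborhood <- function(ppi, seeds) {
  stopifnot(inherits(ppi, "ppi_graph"))
  present <- intersect(seeds, ppi$universe)
  missing <- setdiff(seeds, present)
  if (length(missing) > 0)
    warning("seed(s) not in network skipped: ",
            paste(missing, collapse = ", "))
  if (length(present) == 0) {
    warning("no seed present in the network; empty neighborhood")
    return(character(0))
  }
  nb <- unique(unlist(lapply(
    igraph::ego(ppi$graph, order = 1, nodes = present, mode = "all"),
    function(v) v$name)))
  sort(unique(c(present, nb)))
}

#' Annotation enrichment of a protein neighborhood
#'
#' Fisher enrichment of the neighborhood against each annotation set over
#' the universe, flagged significant when p < 0.01 and the lower bound of
#' the odds-ratio 95% CI exceeds 2.
#'
#' @param pin_nodes character vector (e.g. a first-degree neighborhood).
#' @param annotation_sets named list of protein sets.
#' @param universe protein universe.
#' @return data frame: set, a..d, odds_ratio, ci_lower, p, significant.
#' @export
pin_enrichment <- function(pin_nodes, annotation_sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  rows <- lapply(names(annotation_sets), function(nm) {
    er <- fisher_enrichment(pin_nodes, annotation_sets[[nm]], universe)
    data.frame(set = nm, a = er$a, b = er$b, c = er$c, d = er$d,
               odds_ratio = er$odds_ratio, ci_lower = er$ci_lower,
               p = er$p,
               significant = er$p < 0.01 & er$ci_lower > 2)
  })
  do.call(rbind, rows)
}
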