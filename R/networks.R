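## Genotype networks and intranetwork statistics.
##
## A genotype set (all sites bound by a phenotype) induces a subgraph of
## the genotype space; its connected components are genotype networks and
## the largest is the dominant network, which carries all statistics.

.as_graph <- function(x) {
  if (inherits(x, "genotype_space")) return(x$graph)
  if (inherits(x, "igraph")) return(x)
  stop("expected an igraph or genotype_space", call. = FALSE)
}

#' Induced subgraph of a genotype set
#'
#' @param sites character vector of canonical sites.
#' @param omega a `genotype_space`.
#' @return an igraph graph on `sites` with the edges of the genotype
#'   space that have both endpoints in `sites`.
#' @export
induced_graph <- function(sites, omega) {
  igraph::induced_subgraph(omega$graph, site_index(sites, omega))
}

#' Split a genotype set into its genotype networks
#'
#' Connected components of the induced subgraph, sorted by size
#' descending with ties broken by the lexicographically smallest member
#' site. The first component is the dominant genotype network.
#'
#' @param sites character vector of canonical sites (the genotype set).
#' @param omega a `genotype_space`.
#' @param phenotype_id optional label carried through to the result.
#' @return object of class `genotype_networks`: list with `phenotype_id`,
#'   `components` (list of sorted site vectors), `dominant` (the first
#'   component) and `set_size`.
#' @export
genotype_networks <- function(sites, omega, phenotype_id = NULL) {
  if (!length(sites)) stop("empty genotype set", call. = FALSE)
  g <- induced_graph(sites, omega)
  cm <- igraph::components(g)
  comp <- split(igraph::V(g)$name, cm$membership)
  comp <- lapply(comp, sort)
  ord <- order(-lengths(comp), vapply(comp, `[`, "", 1))
  comp <- unname(comp[ord])
  structure(list(phenotype_id = phenotype_id, components = comp,
                 dominant = comp[[1]], set_size = length(unique(sites))),
            class = "genotype_networks")
}

#' @export
print.genotype_networks <- function(x, ...) {
  cat(sprintf("genotype set%s: %d sites, %d network(s), dominant %d sites\n",
              if (is.null(x$phenotype_id)) "" else paste0(" [", x$phenotype_id, "]"),
              x$set_size, length(x$components), length(x$dominant)))
  invisible(x)
}

#' Clustering coefficient
#'
#' Mean over nodes of the fraction of a node's neighbor pairs that are
#' themselves adjacent; nodes of degree < 2 contribute 0.
#'
#' @param g an igraph graph or a `genotype_space`.
#' @return clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  g <- .as_graph(g)
  deg <- igraph::degree(g)
  tri <- igraph::count_triangles(g)
  ci <- ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
  mean(ci)
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees at the two ends of each edge. For a
#' regular graph the variance term is zero and the result is `NaN`.
#'
#' @inheritParams clustering_coefficient
#' @return assortativity in `[-1, 1]`, or `NaN` for a regular graph.
#' @export
degree_assortativity <- function(g) {
  g <- .as_graph(g)
  if (igraph::ecount(g) < 1) stop("graph has no edges", call. = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  j <- deg[el[, 1]]
  k <- deg[el[, 2]]
  num <- mean(j * k) - mean((j + k) / 2)^2
  den <- mean((j^2 + k^2) / 2) - mean((j + k) / 2)^2
  num / den
}

#' Diameter and characteristic path length
#'
#' All-pairs unweighted shortest paths: the diameter is the longest and
#' the characteristic path length L the mean over unordered distinct
#' pairs (identical to the ordered-pair mean for an undirected graph).
#'
#' @inheritParams clustering_coefficient
#' @return list with `diameter` and `L` (both 0 for a single-node graph).
#' @export
path_metrics <- function(g) {
  g <- .as_graph(g)
  if (igraph::vcount(g) == 1) return(list(diameter = 0, L = 0))
  dt <- igraph::distance_table(g)
  if (dt$unconnected > 0) stop("graph is not connected", call. = FALSE)
  d <- seq_along(dt$res)
  list(diameter = max(d[dt$res > 0]),
       L = sum(d * dt$res) / sum(dt$res))
}

#' Route factor of a genotype network
#'
#' Mean, over all non-target sites i of the network, of the ratio of the
#' within-network shortest path to the target over the genotype-space
#' shortest path to the target. q = 1 means the network is optimally
#' distributed (no within-network detours); q > 1 indicates detours.
#'
#' @param g igraph graph of the (connected) genotype network, vertices
#'   named by site.
#' @param omega a `genotype_space`.
#' @param target target site (must be a vertex of `g`); conventionally
#'   the highest-affinity site.
#' @return route factor q >= 1, or `NaN` for a single-node network.
#' @export
route_factor <- function(g, omega, target) {
  g <- .as_graph(g)
  vn <- igraph::V(g)$name
  if (!target %in% vn) stop("target not in network", call. = FALSE)
  if (length(vn) < 2) return(NaN)
  l <- igraph::distances(g, v = target)[1, ]
  d <- igraph::distances(omega$graph, v = site_index(target, omega),
                         to = site_index(vn, omega))[1, ]
  keep <- vn != target
  mean(l[keep] / d[keep])
}

## highest-affinity site within a network; ties -> lexicographically smallest
.target_site <- function(table, tf_id, sites) {
  sc <- table$scores[sites, tf_id]
  cand <- sort(sites[sc == max(sc)])
  cand[1]
}

#' Per-TF intranetwork metrics table
#'
#' For each TF: genotype-set size, number of genotype networks, dominant
#' network size and fraction, and on the dominant network the edge count,
#' diameter, characteristic path length, clustering coefficient, degree
#' assortativity and route factor (target = highest-affinity site, ties
#' broken lexicographically). TFs with a single-site dominant network are
#' flagged degenerate (diameter and L reported 0, q and r `NaN`).
#'
#' @param table an `escore_table`.
#' @param omega a `genotype_space`.
#' @param meta optional TF metadata data.frame (`tf_id`, `species`,
#'   `domain`).
#' @param tau affinity threshold.
#' @param tfs subset of TFs (default all).
#' @return data.frame, one row per TF.
#' @export
intranetwork_report <- function(table, omega, meta = NULL, tau = 0.35,
                                tfs = table$tfs) {
  rows <- lapply(tfs, function(tf) {
    sites <- bound_sites(table, tf, tau)
    base <- data.frame(tf_id = tf, set_size = length(sites),
                       n_components = NA_integer_, dominant_size = NA_integer_,
                       dominant_fraction = NA_real_, M = NA_integer_,
                       diameter = NA_real_, L = NA_real_, c = NA_real_,
                       r = NA_real_, q = NA_real_, target = NA_character_,
                       degenerate = TRUE, stringsAsFactors = FALSE)
    if (!length(sites)) return(base)
    gn <- genotype_networks(sites, omega, tf)
    dom <- gn$dominant
    g <- induced_graph(dom, omega)
    pm <- path_metrics(g)
    tgt <- .target_site(table, tf, dom)
    base$n_components <- length(gn$components)
    base$dominant_size <- length(dom)
    base$dominant_fraction <- length(dom) / gn$set_size
    base$M <- igraph::ecount(g)
    base$diameter <- pm$diameter
    base$L <- pm$L
    base$c <- clustering_coefficient(g)
    base$r <- if (igraph::ecount(g) >= 1) degree_assortativity(g) else NaN
    base$q <- route_factor(g, omega, tgt)
    base$target <- tgt
    base$degenerate <- length(dom) < 2
    base
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) {
    out <- merge(meta, out, by = "tf_id", sort = FALSE)
    out <- out[match(tfs, out$tf_id), ]
    rownames(out) <- NULL
  }
  out
}
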