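#' Cluster long reads into repeat families
#'
#' Builds the read-similarity graph from overlap edges and partitions it
#' into clusters of mutually similar reads, each cluster representing one
#' repeat family. Connected components are computed first; a component is
#' split further by greedy modularity-maximising community detection only
#' when the split's modularity exceeds a small gain threshold, so loosely
#' bridged families separate while homogeneous components stay whole. Reads
#' participating in no edge remain unclustered singletons.
#'
#' Clusters are labelled `CL1`, `CL2`, ... by decreasing size, with ties
#' broken by the lexicographically smallest member read id, which makes the
#' labelling invariant to input order.
#'
#' @param reads Read `data.frame` (columns `id`, `seq`).
#' @param edges Edge `data.frame` from [find_overlaps()].
#' @param min_modularity Minimum modularity of the community split required
#'   to subdivide a connected component.
#' @param split_density_max Only components with edge density below this
#'   value are considered for splitting. A family of mutually similar reads
#'   forms a dense (often near-clique or thick ring) component, whereas a
#'   component bridging several families through shared flanking reads is
#'   sparse; the density gate keeps single-family components whole while
#'   separating such composites.
#' @return An object of class `read_clusters`: a list with `membership`
#'   (data.frame `read_id`, `cluster`), `sizes` (named integer vector),
#'   `edges`, `reads`, and `unclustered` (ids of singleton reads).
#' @export
build_clusters <- function(reads, edges, min_modularity = 0.05,
                           split_density_max = 0.3) {
  if (nrow(edges) == 0) {
    out <- list(membership = data.frame(read_id = character(0),
                                        cluster = character(0),
                                        stringsAsFactors = FALSE),
                sizes = integer(0), edges = edges, reads = reads,
                unclustered = sort(reads$id))
    class(out) <- "read_clusters"
    return(out)
  }
  g <- igraph::graph_from_data_frame(edges[, c("read_a", "read_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = reads$id))
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  groups <- list()
  for (ci in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == ci]
    if (length(vs) < 2L) next
    sub <- igraph::induced_subgraph(g, vs)
    parts <- list(vs)
    if (length(vs) >= 4L &&
        igraph::edge_density(sub) < split_density_max) {
      cm <- igraph::cluster_fast_greedy(sub)
      if (length(cm) > 1L && igraph::modularity(cm) > min_modularity) {
        parts <- split(names(igraph::membership(cm)),
                       as.integer(igraph::membership(cm)))
      }
    }
    for (p in parts) {
      if (length(p) >= 2L) groups[[length(groups) + 1L]] <- sort(p)
    }
  }
  # rank by decreasing size, ties by smallest member id
  sizes <- vapply(groups, length, integer(1))
  first <- vapply(groups, `[`, character(1), 1L)
  ord <- order(-sizes, first)
  groups <- groups[ord]
  labels <- paste0("CL", seq_along(groups))
  membership <- data.frame(
    read_id = unlist(groups, use.names = FALSE),
    cluster = rep(labels, lengths(groups)),
    stringsAsFactors = FALSE)
  out <- list(membership = membership,
              sizes = stats::setNames(lengths(groups), labels),
              edges = edges, reads = reads,
              unclustered = sort(setdiff(reads$id, membership$read_id)))
  class(out) <- "read_clusters"
  out
}

#' @export
print.read_clusters <- function(x, ...) {
  cat(length(x$sizes), "clusters covering", nrow(x$membership), "of",
      nrow(x$reads), "reads (",
      round(100 * nrow(x$membership) / max(1, nrow(x$reads)), 1),
      "% clustered )\n")
  if (length(x$sizes)) {
    show <- utils::head(x$sizes, 10L)
    cat("largest:", paste(names(show), show, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Size-ranked cluster summary
#'
#' Tabulates cluster sizes as proportions of all analysed reads together
#' with the cumulative proportion, and reports the smallest number of top
#' clusters that contain at least half of all reads.
#'
#' @param clusters A `read_clusters` object.
#' @param total_reads Total number of analysed reads (defaults to the reads
#'   the clustering saw).
#' @return A `data.frame` (`cluster`, `size`, `proportion`, `cumulative`)
#'   with attributes `clustered_fraction` and `k_half` (`NA` if the clusters
#'   never reach half of the reads).
#' @export
cluster_summary <- function(clusters, total_reads = nrow(clusters$reads)) {
  if (total_reads == 0) stop("total_reads must be positive")
  sizes <- clusters$sizes
  out <- data.frame(cluster = names(sizes), size = as.integer(sizes),
                    proportion = as.numeric(sizes) / total_reads,
                    stringsAsFactors = FALSE)
  out$cumulative <- cumsum(out$proportion)
  attr(out, "clustered_fraction") <- sum(out$size) / total_reads
  k <- which(out$cumulative >= 0.5)
  attr(out, "k_half") <- if (length(k)) k[1L] else NA_integer_
  out
}

#' Classify the layout shape of a cluster graph
#'
#' The layout of a cluster's similarity graph reflects the genomic
#' organisation of the underlying repeat: tandem arrays whose unit is much
#' longer than a read yield a dominant long cycle (`"circular"`), dispersed
#' elements yield elongated low-cycle graphs (`"linear"`), and short-monomer
#' satellites yield dense, near-clique graphs (`"globular"`). The rules are:
#' circular when the graph has a dominant long cycle — the diameter path has
#' at least `min_diameter` hops and its two ends remain connected after
#' removing the path's interior; otherwise globular when edge density is at
#' least `density_min`; otherwise linear. The hop diameter of a ring-shaped
#' graph is set by the repeat unit length relative to the read overlap
#' reach, not by the read count, hence an absolute hop threshold. Rings are
#' resolvable when the unit is at least roughly four read-overlap reaches
#' (about 2 kb units for 250-nt reads); shorter tandem units collapse into
#' dense globular graphs. Clusters with fewer than 10 members are labelled
#' `"other"`.
#'
#' @param clusters A `read_clusters` object.
#' @param cluster Cluster label (e.g. `"CL1"`).
#' @param density_min Edge-density threshold for `"globular"`.
#' @param min_diameter Minimum hop length of the diameter path for the
#'   circularity test.
#' @return One of `"circular"`, `"linear"`, `"globular"`, `"other"`.
#' @export
classify_graph_shape <- function(clusters, cluster, density_min = 0.2,
                                 min_diameter = 6L) {
  members <- clusters$membership$read_id[clusters$membership$cluster == cluster]
  n <- length(members)
  if (n < 10L) return("other")
  e <- clusters$edges
  keep <- e$read_a %in% members & e$read_b %in% members
  g <- igraph::simplify(igraph::graph_from_data_frame(
    e[keep, c("read_a", "read_b")], directed = FALSE,
    vertices = data.frame(name = members)))
  dens <- igraph::edge_density(g)
  diam_path <- igraph::get_diameter(g)
  D <- length(diam_path) - 1L
  if (D >= min_diameter) {
    ends <- diam_path[c(1L, length(diam_path))]
    interior <- diam_path[-c(1L, length(diam_path))]
    if (length(interior) == 0) return("linear")
    g2 <- igraph::delete_vertices(g, interior)
    d2 <- igraph::distances(g2, v = names(ends)[1L], to = names(ends)[2L])
    if (is.finite(d2[1L, 1L])) return("circular")
    return("linear")
  }
  if (dens >= density_min) return("globular")
  "linear"
}

#' Detect the tandem period of a repeat sequence
#'
#' Scans all lags `p` up to a third of the sequence length and reports the
#' smallest lag at which the sequence matches itself shifted by `p` with at
#' least `min_identity` identity — the monomer length of a tandem array.
#' Identity at a lag is the best ungapped identity over windows of
#' `max(30, 2p)` positions rather than over the full overlap, so that a
#' single indel (which shifts the phase of everything downstream) does not
#' mask the periodicity; a 30-position window keeps the chance of a random
#' window reaching 80% identity negligible. Returns `NA` when no lag
#' qualifies (e.g. for single-copy or dispersed-repeat sequence).
#'
#' @param seq A character scalar (e.g. a representative cluster read).
#' @param min_identity Minimum windowed self-match identity at the reported
#'   lag.
#' @return Integer period in bp, or `NA_integer_`.
#' @export
detect_tandem_period <- function(seq, min_identity = 0.8) {
  n <- nchar(seq)
  max_p <- floor(n / 3)
  if (max_p < 1L) return(NA_integer_)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in seq_len(max_p)) {
    m <- n - p
    match_vec <- bases[seq_len(m)] == bases[p + seq_len(m)]
    w <- min(m, max(30L, 2L * p))
    cs <- c(0, cumsum(match_vec))
    best <- max(cs[(w + 1L):(m + 1L)] - cs[1L:(m + 1L - w)]) / w
    if (best >= min_identity) return(as.integer(p))
  }
  NA_integer_
}

#' Extract the member reads of one cluster
#'
#' @param clusters A `read_clusters` object.
#' @param cluster Cluster label.
#' @return Read `data.frame` of the members.
#' @export
cluster_reads <- function(clusters, cluster) {
  ids <- clusters$membership$read_id[clusters$membership$cluster == cluster]
  clusters$reads[clusters$reads$id %in% ids, , drop = FALSE]
}
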