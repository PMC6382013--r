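# Seed-rooted hierarchical tier classification of an interaction network:
# primary interactors bind the seed directly, secondary bind primary but not
# the seed, tertiary bind secondary, and everything farther that still has a
# path to the seed is quaternary.  This is exactly breadth-first distance
# from the seed with distances >= 4 collapsed; members with no path are
# "unconnected".

.TIER_LEVELS <- c("seed", "primary", "secondary", "tertiary",
                  "quaternary", "unconnected")

#' Assign interaction-network tiers around a seed
#'
#' Computes breadth-first distances from the seed over the undirected graph
#' (restricted to \code{members} plus the seed when \code{members} is given;
#' with \code{keep_bridges = TRUE} non-member nodes are retained for distance
#' computation but labeled \code{NA} in the output) and maps distance 1, 2, 3
#' and >= 4 to \code{primary}, \code{secondary}, \code{tertiary} and
#' \code{quaternary}.  Members unreachable from the seed — including members
#' absent from the graph — are \code{unconnected}.  Deterministic and
#' independent of node enumeration order.
#'
#' @param graph an \code{igraph} object (undirected; direction is ignored).
#' @param seed seed/bait node name (must be in the graph).
#' @param members optional character vector restricting the layered node set
#'   (the seed is always included).
#' @param keep_bridges retain non-member nodes as distance-carrying bridges
#'   (default \code{FALSE}: edges through non-members are discarded).
#' @return \code{DataFrame} with columns \code{node} and \code{tier} (factor
#'   with levels seed, primary, secondary, tertiary, quaternary,
#'   unconnected), one row per member plus the seed, sorted by tier then
#'   node name.
#' @export
assignTiers <- function(graph, seed, members = NULL, keep_bridges = FALSE) {
  vn <- igraph::V(graph)$name
  if (is.null(vn)) stop("graph vertices must be named")
  if (!seed %in% vn) stop("seed '", seed, "' absent from graph")
  if (!is.null(members)) {
    members <- unique(as.character(members))
    node_set <- union(members, seed)
    if (!keep_bridges)
      graph <- igraph::induced_subgraph(graph, intersect(vn, node_set))
  } else {
    node_set <- vn
  }
  # hand-rolled BFS frontier expansion (adjacency lists, no distance oracle)
  vn2 <- igraph::V(graph)$name
  adj <- igraph::as_adj_list(graph, mode = "all")
  adj <- lapply(adj, function(v) vn2[as.integer(v)])
  names(adj) <- vn2
  dist <- setNames(rep(NA_integer_, length(vn2)), vn2)
  dist[seed] <- 0L
  frontier <- seed
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  out_nodes <- sort(setdiff(node_set, seed))
  dd <- dist[out_nodes]
  tier <- ifelse(is.na(dd), "unconnected",
                 ifelse(dd == 1L, "primary",
                        ifelse(dd == 2L, "secondary",
                               ifelse(dd == 3L, "tertiary", "quaternary"))))
  res <- DataFrame(node = c(seed, out_nodes),
                   tier = factor(c("seed", tier), levels = .TIER_LEVELS))
  res[order(res$tier, res$node), ]
}

#' Per-tier group composition
#'
#' Cross-tabulates tier assignments against a node grouping (e.g. the Venn
#' region each hit falls in) and returns the fractions both ways: the group
#' make-up of each tier and the tier make-up of each group.  Nodes without a
#' group label form an explicit \code{"unlabeled"} group; empty tiers are
#' reported with zero counts, not an error.
#'
#' @param assignment output of \code{\link{assignTiers}}.
#' @param groups named character vector, node to group label.
#' @param include_seed include the seed row (default \code{FALSE}).
#' @return list with \code{counts} (tiers x groups), \code{by_tier}
#'   (fractions, rows sum to 1 for non-empty tiers) and \code{by_group}
#'   (fractions, columns sum to 1 for non-empty groups).
#' @export
tierComposition <- function(assignment, groups, include_seed = FALSE) {
  a <- assignment
  if (!include_seed) a <- a[a$tier != "seed", ]
  g <- setNames(as.character(groups), normalizeIds(names(groups)))
  lab <- g[normalizeIds(a$node)]
  lab[is.na(lab)] <- "unlabeled"
  tiers <- setdiff(.TIER_LEVELS, if (include_seed) character(0) else "seed")
  counts <- table(factor(as.character(a$tier), levels = tiers),
                  factor(lab, levels = sort(unique(lab))))
  counts <- unclass(counts)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  by_tier <- sweep(counts, 1L, ifelse(rs == 0, 1, rs), "/")
  by_group <- sweep(counts, 2L, ifelse(cs == 0, 1, cs), "/")
  list(counts = counts, by_tier = by_tier, by_group = by_group)
}
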