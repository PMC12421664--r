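# Fragmentation engine: bond-graph construction from covalent radii and
# connected-component fragment assignment.

#' Fragmentation parameters
#'
#' Controls how the bond graph underlying fragment detection is built.
#'
#' @param cutoff_scale dimensionless multiplier on the sum of the two atoms'
#'   covalent radii; a pair closer than `cutoff_scale * (r_i + r_j)` is bonded.
#'   Default 1.15, a common covalent-bond heuristic.
#' @param absolute_cutoff optional maximum bonding distance in Angstrom; when
#'   set it replaces the radius-based criterion entirely.
#' @param coordination_overrides named integer vector mapping element symbol to
#'   its maximum coordination number; excess bonds are pruned farthest-first.
#'   Useful for coordination bonds around metal centres.
#' @param custom_bonds data frame with integer columns `i`, `j` (1-based atom
#'   indices) and character column `action` (`"bond"` adds the edge, `"break"`
#'   removes it). Applied last, as the final word over the automatic criteria:
#'   the mechanism for assigning specific bonds to separate fragments.
#' @return An object of class `led_frag_params`.
#' @export
fragmentation_params <- function(cutoff_scale = 1.15, absolute_cutoff = NULL,
                                 coordination_overrides = integer(),
                                 custom_bonds = NULL) {
  stopifnot(cutoff_scale > 0)
  if (!is.null(absolute_cutoff)) stopifnot(absolute_cutoff > 0)
  if (length(coordination_overrides) > 0) {
    stopifnot(!is.null(names(coordination_overrides)),
              all(coordination_overrides >= 0))
  }
  if (is.null(custom_bonds)) {
    custom_bonds <- data.frame(i = integer(), j = integer(),
                               action = character())
  }
  stopifnot(all(c("i", "j", "action") %in% names(custom_bonds)),
            all(custom_bonds$action %in% c("bond", "break")))
  structure(list(cutoff_scale = cutoff_scale,
                 absolute_cutoff = absolute_cutoff,
                 coordination_overrides = coordination_overrides,
                 custom_bonds = custom_bonds),
            class = "led_frag_params")
}

#' Build the bond graph of a geometry
#'
#' An undirected edge (i, j) exists when the interatomic distance is at most
#' `absolute_cutoff` (if set) or `cutoff_scale * (r_cov(i) + r_cov(j))`.
#' Edges in excess of an atom's coordination override are then pruned
#' farthest-first (ties broken towards the partner with the lower atom index),
#' and finally custom bonds are applied.
#'
#' @param geom an `led_geometry`.
#' @param params an `led_frag_params`; defaults to [fragmentation_params()].
#' @return Data frame with columns `i`, `j` (i < j) and `dist` (Angstrom).
#'   An atom with no edges is a legal singleton fragment.
#' @export
build_bond_graph <- function(geom, params = fragmentation_params()) {
  n <- n_atoms(geom)
  if (n == 0) stop("empty geometry", call. = FALSE)
  bad <- params$custom_bonds$i < 1 | params$custom_bonds$i > n |
    params$custom_bonds$j < 1 | params$custom_bonds$j > n
  if (any(bad)) stop("custom bond references an invalid atom index",
                     call. = FALSE)
  edges <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (n > 1) {
    d <- as.matrix(stats::dist(geom$coords))
    radii <- covalent_radii()[geom$element]
    if (is.null(params$absolute_cutoff)) {
      thr <- params$cutoff_scale * outer(radii, radii, `+`)
    } else {
      thr <- matrix(params$absolute_cutoff, n, n)
    }
    hit <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit) > 0) {
      edges <- data.frame(i = hit[, 1], j = hit[, 2],
                          dist = d[hit])
      edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    }
  }
  edges <- prune_coordination(edges, geom, params$coordination_overrides)
  edges <- apply_custom_bonds(edges, geom, params$custom_bonds)
  rownames(edges) <- NULL
  edges
}

prune_coordination <- function(edges, geom, overrides) {
  if (length(overrides) == 0 || nrow(edges) == 0) return(edges)
  # process atoms in index order; for each over-coordinated atom drop its
  # farthest edges, ties resolved by removing the lower-indexed partner first
  for (a in seq_len(n_atoms(geom))) {
    cap <- overrides[geom$element[a]]
    if (is.na(cap)) next
    repeat {
      mine <- which(edges$i == a | edges$j == a)
      if (length(mine) <= cap) break
      partner <- ifelse(edges$i[mine] == a, edges$j[mine], edges$i[mine])
      drop <- mine[order(-edges$dist[mine], partner)][1]
      edges <- edges[-drop, , drop = FALSE]
    }
  }
  edges
}

apply_custom_bonds <- function(edges, geom, custom) {
  if (nrow(custom) == 0) return(edges)
  d <- NULL
  for (k in seq_len(nrow(custom))) {
    i <- min(custom$i[k], custom$j[k])
    j <- max(custom$i[k], custom$j[k])
    have <- which(edges$i == i & edges$j == j)
    if (custom$action[k] == "break") {
      if (length(have) > 0) edges <- edges[-have, , drop = FALSE]
    } else if (length(have) == 0) {
      if (is.null(d)) d <- as.matrix(stats::dist(geom$coords))
      edges <- rbind(edges, data.frame(i = i, j = j, dist = d[i, j]))
    }
  }
  edges[order(edges$i, edges$j), , drop = FALSE]
}

#' Detect molecular fragments
#'
#' Fragments are the connected components of the bond graph produced by
#' [build_bond_graph()]. Component ids are assigned 1..F in order of each
#' component's lowest atom index, so numbering is reproducible and independent
#' of traversal order.
#'
#' @param geom an `led_geometry`.
#' @param params an `led_frag_params`.
#' @return The input geometry with its `fragment` assignment replaced.
#' @export
detect_fragments <- function(geom, params = fragmentation_params()) {
  edges <- build_bond_graph(geom, params)
  n <- n_atoms(geom)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  }
  memb <- igraph::components(g)$membership
  # renumber components by their lowest atom index
  first <- tapply(seq_len(n), memb, min)
  rank <- match(memb, as.integer(names(sort(first))))
  geom$fragment <- as.integer(rank)
  validate_geometry(geom)
  geom
}
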