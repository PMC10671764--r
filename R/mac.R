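#' Parameters of the multi-stage graph clustering algorithm
#'
#' @param sigma_filter number of standard deviations above the mean triangle
#'   area beyond which a triangle is an outlier (one-sided; default 2).
#' @param knn neighbourhood size for mutual-nearest-neighbour pruning
#'   (default 1).
#' @param tie_tol absolute tolerance under which candidate representatives
#'   are considered tied and pooled into a multiset (default 1e-9).
#' @param multiset_max maximal representative-multiset size before a cluster
#'   is deemed to have grown out of control and is dissolved by
#'   [auto_correct()] (default 3).
#' @param max_cycles maximal number of auto-correction cycles (default 5).
#' @return A list of class `mac_params`.
#' @export
mac_params <- function(sigma_filter = 2, knn = 1L, tie_tol = 1e-9,
                       multiset_max = 3L, max_cycles = 5L) {
  stopifnot(sigma_filter > 0, knn >= 1L, tie_tol >= 0,
            multiset_max >= 1L, max_cycles >= 1L)
  structure(
    list(sigma_filter = sigma_filter, knn = as.integer(knn),
         tie_tol = tie_tol, multiset_max = as.integer(multiset_max),
         max_cycles = as.integer(max_cycles)),
    class = "mac_params"
  )
}

#' Triangle area by Heron's formula
#'
#' `sqrt(p (p-a) (p-b) (p-c))` with `p = (a+b+c)/2`. Distance triples that
#' violate the triangle inequality make the radicand negative; such
#' non-metric triples are clamped to area 0 and flagged in the `nonmetric`
#' attribute of the result. Vectorized over the three sides.
#'
#' @param a,b,c non-negative side lengths.
#' @return Numeric vector of areas, with a logical attribute `nonmetric`
#'   marking clamped triples.
#' @examples
#' heron_area(3, 4, 5)  # 6
#' heron_area(1, 1, 1)  # sqrt(3)/4
#' @export
heron_area <- function(a, b, c) {
  if (any(a < 0 | b < 0 | c < 0)) stop("side lengths must be non-negative")
  p <- (a + b + c) / 2
  rad <- p * (p - a) * (p - b) * (p - c)
  nonmetric <- rad < 0
  area <- sqrt(pmax(rad, 0))
  attr(area, "nonmetric") <- nonmetric
  area
}

# Canonical label order: C-locale radix sort, so results are deterministic
# and permutation-equivariant.
sort_labels <- function(x) {
  if (!length(x)) return(character(0))
  x[order(x, method = "radix")]
}

# Coerce to a canonical distance matrix: symmetric values, labels sorted.
canonical_dist <- function(D) {
  m <- as_dist_matrix(D)
  labs <- sort_labels(rownames(m))
  m[labs, labs, drop = FALSE]
}

#' Filter edges through triangle-area outliers
#'
#' Computes the Heron area of every unordered triple of labels and declares
#' a triangle an outlier when its area exceeds
#' `mean + sigma_filter * sd` of the area distribution (one-sided: only
#' large, deformed triangles are rejected). An edge survives when it belongs
#' to at least one non-outlier triangle. With fewer than three labels no
#' triangle exists and the complete graph is returned with a warning.
#'
#' @param D an [ncd_matrix()] or labelled square numeric matrix.
#' @param sigma_filter positive number of standard deviations.
#' @return A logical adjacency matrix (labels sorted) with attribute
#'   `triangle_stats` (list: `areas`, `mean_area`, `sd_area`,
#'   `n_outliers`, `n_nonmetric`).
#' @export
triangle_filter <- function(D, sigma_filter = 2) {
  m <- canonical_dist(D)
  n <- nrow(m)
  labs <- rownames(m)
  adj <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  if (n < 3) {
    warning("fewer than 3 labels: no triangles, returning complete graph")
    adj[] <- TRUE
    diag(adj) <- FALSE
    attr(adj, "triangle_stats") <- list(
      areas = numeric(), mean_area = NA_real_, sd_area = NA_real_,
      n_outliers = 0L, n_nonmetric = 0L)
    return(adj)
  }
  tri <- utils::combn(n, 3)
  a <- m[cbind(tri[1, ], tri[2, ])]
  b <- m[cbind(tri[2, ], tri[3, ])]
  cc <- m[cbind(tri[3, ], tri[1, ])]
  areas <- heron_area(a, b, cc)
  mu <- mean(areas)
  sd_a <- stats::sd(areas)
  keep <- if (is.na(sd_a) || sd_a == 0) {
    rep(TRUE, length(areas))
  } else {
    areas <= mu + sigma_filter * sd_a
  }
  for (e in 1:3) {
    i <- tri[e, keep]
    j <- tri[e %% 3 + 1, keep]
    adj[cbind(i, j)] <- TRUE
    adj[cbind(j, i)] <- TRUE
  }
  attr(adj, "triangle_stats") <- list(
    areas = as.numeric(areas), mean_area = mu, sd_area = sd_a,
    n_outliers = sum(!keep), n_nonmetric = sum(attr(areas, "nonmetric")))
  adj
}

#' Mutual nearest-neighbour ("first-of-first") pruning
#'
#' Keeps an edge `(u, v)` of the retained graph when `v` is among the `knn`
#' nearest retained neighbours of `u` *and* `u` is among the `knn` nearest
#' of `v` (mutual kNN). In addition every node's single nearest retained
#' neighbour edge is always kept, whether mutual or not — the
#' "first-of-first" guarantee that prevents a node from being isolated
#' merely because its nearest neighbour is popular. All orderings break
#' ties lexicographically by label.
#'
#' @param G logical adjacency matrix from [triangle_filter()].
#' @param D distance matrix (same labels).
#' @param knn neighbourhood size.
#' @return A pruned logical adjacency matrix.
#' @export
first_of_first_prune <- function(G, D, knn = 1L) {
  m <- canonical_dist(D)
  labs <- rownames(m)
  G <- G[labs, labs, drop = FALSE]
  n <- length(labs)
  topk <- vector("list", n)
  nearest <- rep(NA_integer_, n)
  for (u in seq_len(n)) {
    nb <- which(G[u, ])
    if (!length(nb)) next
    nb <- nb[order(m[u, nb], labs[nb], method = "radix")]
    topk[[u]] <- nb[seq_len(min(knn, length(nb)))]
    nearest[u] <- nb[1]
  }
  out <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (u in seq_len(n)) {
    for (v in topk[[u]]) {
      if (u %in% topk[[v]]) {
        out[u, v] <- TRUE
        out[v, u] <- TRUE
      }
    }
    if (!is.na(nearest[u])) {
      out[u, nearest[u]] <- TRUE
      out[nearest[u], u] <- TRUE
    }
  }
  out
}

# igraph over an adjacency matrix with D-weighted edges.
graph_from_adj <- function(G, D) {
  g <- igraph::graph_from_adjacency_matrix(G * 1, mode = "undirected",
                                           diag = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el)) {
    igraph::E(g)$weight <- D[cbind(el[, 1], el[, 2])]
  }
  g
}

#' Split graph components at internal density boundaries
#'
#' Within each connected component, each node's closeness to the
#' component is its mean distance (in `D`) to the other members; a node
#' is a *local minimum* when no graph neighbour has a strictly smaller
#' closeness, with exact plateau ties resolved lexicographically so a
#' fully degenerate plateau yields one minimum rather than shattering. A
#' component with two or more local minima contains an internal
#' boundary — e.g. a dumbbell of two centred blobs joined by a bridge
#' keeps one minimum per blob: each node is then assigned to its nearest
#' local minimum by shortest weighted path length (a Voronoi partition
#' over the graph, ties to the lexicographically smallest minimum
#' label), and the resulting parts are re-examined — with closeness
#' recomputed on each part — until every part has exactly one local
#' minimum.
#'
#' @param G logical adjacency matrix (typically from
#'   [first_of_first_prune()]).
#' @param D distance matrix (same labels).
#' @return A list of character vectors of labels, sorted, ordered by first
#'   label.
#' @export
local_minima_partition <- function(G, D) {
  m <- canonical_dist(D)
  labs <- rownames(m)
  G <- G[labs, labs, drop = FALSE]
  g_all <- graph_from_adj(G, m)
  comp <- igraph::components(g_all)
  queue <- split(labs, comp$membership)
  done <- list()
  while (length(queue)) {
    part <- queue[[1]]
    queue <- queue[-1]
    if (length(part) == 1L) {
      done <- c(done, list(part))
      next
    }
    sub <- G[part, part, drop = FALSE]
    gsub <- graph_from_adj(sub, m[part, part, drop = FALSE])
    cs <- igraph::components(gsub)
    if (cs$no > 1L) {
      queue <- c(queue, unname(split(part, cs$membership)))
      next
    }
    mean_d <- vapply(part, function(u) {
      mean(m[u, setdiff(part, u)])
    }, numeric(1))
    is_min <- vapply(seq_along(part), function(ui) {
      u <- part[ui]
      nb <- part[sub[u, ]]
      if (!length(nb)) return(TRUE)
      !any(mean_d[nb] < mean_d[u] |
             (mean_d[nb] == mean_d[u] & nb < u))
    }, logical(1))
    minima <- sort_labels(part[is_min])
    if (length(minima) <= 1L) {
      done <- c(done, list(sort_labels(part)))
      next
    }
    pd <- igraph::distances(gsub, v = minima, to = part,
                            weights = igraph::E(gsub)$weight)
    assign_to <- vapply(part, function(u) {
      col <- pd[, u]
      minima[which(col == min(col))[1]]  # minima already label-sorted
    }, character(1))
    queue <- c(queue, unname(split(part, assign_to)))
  }
  done <- lapply(done, sort_labels)
  done[order(vapply(done, `[`, character(1), 1), method = "radix")]
}

#' Best representative multiset of a cluster
#'
#' The representatives are the members minimizing the total distance to all
#' other members (the medoids); every member whose total comes within
#' `tie_tol` of the minimum enters the multiset. The distance from any
#' element to the multiset is the minimum distance to its members.
#'
#' @param members character vector of labels.
#' @param D distance matrix containing them.
#' @param tie_tol absolute tie tolerance on the distance sums.
#' @return Sorted character vector of representative labels.
#' @export
best_representative <- function(members, D, tie_tol = 1e-9) {
  if (!length(members)) stop("members must be non-empty")
  m <- as_dist_matrix(D)
  if (length(members) == 1L) return(members)
  sums <- rowSums(m[members, members, drop = FALSE])
  sort_labels(members[sums <= min(sums) + tie_tol])
}

dist_to_multiset <- function(label, reps, m) min(m[label, reps])

make_cluster <- function(members, m, tie_tol) {
  reps <- best_representative(members, m, tie_tol)
  radius <- mean(vapply(members, dist_to_multiset, numeric(1),
                        reps = reps, m = m))
  list(members = sort_labels(members), representatives = reps,
       mean_radius = radius)
}

# One run of filter -> prune -> partition over a label subset.
pipeline_once <- function(m, params) {
  G <- triangle_filter(m, params$sigma_filter)
  G <- first_of_first_prune(G, m, params$knn)
  local_minima_partition(G, m)
}

#' Forward clustering pass
#'
#' The core pipeline over a distance matrix: [triangle_filter()] rejects
#' edges that only ever occur in outlier triangles, [first_of_first_prune()]
#' thins the graph to mutual nearest neighbours, and
#' [local_minima_partition()] splits the remaining components at internal
#' boundaries. Parts of size two or more become clusters with medoid
#' multiset representatives; isolated labels become singletons. A *final
#' recall* then re-runs the same pipeline once on the singleton subset of
#' the matrix, promoting any newly found groups of size two or more to
#' clusters.
#'
#' @param D an [ncd_matrix()] or labelled square numeric matrix, `n >= 2`.
#' @param params a [mac_params()] object.
#' @return An object of class `mac_clustering`: list with `clusters` (each
#'   a list of `members`, `representatives`, `mean_radius`), `singletons`,
#'   and a `cycles` log.
#' @export
forward_pass <- function(D, params = mac_params()) {
  m <- canonical_dist(D)
  if (nrow(m) < 2L) stop("need at least 2 labels to cluster")
  parts <- pipeline_once(m, params)
  sizes <- lengths(parts)
  clusters <- parts[sizes >= 2L]
  singles <- sort_labels(unlist(parts[sizes == 1L], use.names = FALSE))
  recalled <- 0L
  if (length(singles) >= 2L) {
    parts2 <- pipeline_once(m[singles, singles, drop = FALSE], params)
    new_clusters <- parts2[lengths(parts2) >= 2L]
    recalled <- length(new_clusters)
    clusters <- c(clusters, new_clusters)
    singles <- sort_labels(unlist(parts2[lengths(parts2) == 1L],
                                  use.names = FALSE))
  }
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1),
                             method = "radix")]
  structure(
    list(
      clusters = lapply(clusters, make_cluster, m = m,
                        tie_tol = params$tie_tol),
      singletons = singles,
      cycles = list(list(pass = "forward", n_clusters = length(clusters),
                         n_singletons = length(singles),
                         recall_clusters = recalled))
    ),
    class = "mac_clustering"
  )
}

#' Auto-correction of overgrown clusters
#'
#' A cluster whose representative multiset exceeds `multiset_max` is taken
#' as having grown beyond one coherent group: it is deleted and each of its
#' members is redistributed to the surviving cluster whose representative
#' multiset is nearest (or to the singleton pool when no cluster survives).
#' Representatives of the receiving clusters are recomputed, and the check
#' repeats — up to `max_cycles` times or until a fixpoint. Each cycle is
#' appended to the clustering's `cycles` log.
#'
#' @param C a `mac_clustering` from [forward_pass()].
#' @param D the distance matrix it was built from.
#' @param params a [mac_params()] object.
#' @return The corrected `mac_clustering`.
#' @export
auto_correct <- function(C, D, params = mac_params()) {
  m <- canonical_dist(D)
  for (cycle in seq_len(params$max_cycles)) {
    over <- vapply(C$clusters, function(cl) {
      length(cl$representatives) > params$multiset_max
    }, logical(1))
    if (!any(over)) break
    displaced <- sort_labels(unlist(lapply(C$clusters[over], `[[`,
                                           "members")))
    survivors <- C$clusters[!over]
    if (!length(survivors)) {
      C$singletons <- sort_labels(c(C$singletons, displaced))
      C$clusters <- list()
      C$cycles <- c(C$cycles, list(list(
        pass = "auto_correct", cycle = cycle,
        deleted = sum(over), displaced = length(displaced),
        to_singletons = length(displaced))))
      next
    }
    target <- vapply(displaced, function(x) {
      dd <- vapply(survivors, function(cl) {
        dist_to_multiset(x, cl$representatives, m)
      }, numeric(1))
      first_rep <- vapply(survivors, function(cl) cl$representatives[1],
                          character(1))
      cand <- which(dd == min(dd))
      cand[order(first_rep[cand], method = "radix")][1]
    }, integer(1))
    for (k in seq_along(survivors)) {
      add <- displaced[target == k]
      if (length(add)) {
        survivors[[k]] <- make_cluster(c(survivors[[k]]$members, add), m,
                                       params$tie_tol)
      }
    }
    survivors <- survivors[order(vapply(survivors, function(cl)
      cl$members[1], character(1)), method = "radix")]
    C$clusters <- survivors
    C$cycles <- c(C$cycles, list(list(
      pass = "auto_correct", cycle = cycle, deleted = sum(over),
      displaced = length(displaced), to_singletons = 0L)))
  }
  C
}

#' Cluster a distance matrix
#'
#' Runs [forward_pass()] followed by [auto_correct()]. This is the
#' whole-pipeline entry point used on NCD matrices of genome sets.
#'
#' @inheritParams forward_pass
#' @return A `mac_clustering`.
#' @export
mac_cluster <- function(D, params = mac_params()) {
  auto_correct(forward_pass(D, params), D, params)
}

#' @export
print.mac_clustering <- function(x, ...) {
  cat("Clustering:", length(x$clusters), "cluster(s),",
      length(x$singletons), "singleton(s)\n")
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  [%d] %d members (rep: %s; mean radius %.4f): %s\n", i,
                length(cl$members),
                paste(cl$representatives, collapse = ","),
                cl$mean_radius, paste(cl$members, collapse = " ")))
  }
  if (length(x$singletons)) {
    cat("  singletons:", paste(x$singletons, collapse = " "), "\n")
  }
  invisible(x)
}

#' Cluster membership as a named vector
#'
#' @param C a `mac_clustering`.
#' @return Named character vector mapping each label to `"C1"`, `"C2"`, ...
#'   or `"S"` for singletons.
#' @export
cluster_assignments <- function(C) {
  out <- character(0)
  for (i in seq_along(C$clusters)) {
    mem <- C$clusters[[i]]$members
    out[mem] <- paste0("C", i)
  }
  out[C$singletons] <- "S"
  out[sort_labels(names(out))]
}

quote_newick <- function(x) {
  bad <- grepl("[^A-Za-z0-9_.|-]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

# Newick fragment (no trailing ";") for an hclust over `labels`;
# returns list(text, height).
hclust_newick <- function(hc, labels) {
  build <- function(node) {
    if (node < 0) {
      return(list(text = quote_newick(labels[-node]), height = 0))
    }
    h <- hc$height[node]
    kids <- lapply(hc$merge[node, ], build)
    parts <- vapply(kids, function(k) {
      sprintf("%s:%g", k$text, max(h - k$height, 0))
    }, character(1))
    list(text = paste0("(", paste(parts, collapse = ","), ")"), height = h)
  }
  build(nrow(hc$merge))
}

#' Export a clustering as a Newick tree
#'
#' Each cluster is resolved internally by average-linkage agglomeration of
#' its members; clusters are then joined by average linkage on the mean
#' distances between their representative multisets, and singletons are
#' attached at the root. Branch lengths are merge heights; labels are
#' quoted when they contain characters outside the safe Newick set.
#'
#' @param C a `mac_clustering`.
#' @param D the distance matrix it was built from.
#' @return A Newick string (terminated by `;`).
#' @export
clusters_to_newick <- function(C, D) {
  m <- canonical_dist(D)
  subtree <- function(members) {
    if (length(members) == 1L) {
      return(list(text = quote_newick(members), height = 0))
    }
    hc <- stats::hclust(stats::as.dist(m[members, members]),
                        method = "average")
    hclust_newick(hc, hc$labels)
  }
  frags <- lapply(C$clusters, function(cl) subtree(cl$members))
  if (length(C$clusters) >= 2L) {
    k <- length(C$clusters)
    cd <- matrix(0, k, k)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        ri <- C$clusters[[i]]$representatives
        rj <- C$clusters[[j]]$representatives
        cd[i, j] <- cd[j, i] <- mean(m[ri, rj, drop = FALSE])
      }
    }
    hc <- stats::hclust(stats::as.dist(cd), method = "average")
    build <- function(node) {
      if (node < 0) return(frags[[-node]])
      h <- hc$height[node]
      kids <- lapply(hc$merge[node, ], build)
      parts <- vapply(kids, function(kk) {
        sprintf("%s:%g", kk$text, max(h - kk$height, 0))
      }, character(1))
      list(text = paste0("(", paste(parts, collapse = ",")
                         , ")"), height = h)
    }
    core <- build(nrow(hc$merge))
  } else if (length(C$clusters) == 1L) {
    core <- frags[[1]]
  } else {
    core <- NULL
  }
  leaves <- c(if (!is.null(core)) list(core),
              lapply(C$singletons, function(s)
                list(text = quote_newick(s), height = 0)))
  if (!length(leaves)) stop("empty clustering")
  if (length(leaves) == 1L && is.null(core) || length(leaves) == 1L) {
    return(paste0(leaves[[1]]$text, ";"))
  }
  root_h <- max(c(vapply(leaves, `[[`, numeric(1), "height"), max(m)))
  parts <- vapply(leaves, function(k) {
    sprintf("%s:%g", k$text, max(root_h - k$height, 0))
  }, character(1))
  paste0("(", paste(parts, collapse = ","), ");")
}
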