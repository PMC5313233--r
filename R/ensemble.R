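#' Pool of conformations
#'
#' @param coords Array `n_frames x n_particles x ndim` (or a list of
#'   conformation matrices with identical shapes).
#' @param frame_id Optional frame identifiers; default `1:n_frames`.
#' @param source Optional per-frame provenance (walker/run id, basin label).
#' @param cv Optional matrix of per-frame CV values.
#' @return Object of class `conformation_pool`.
#' @export
conformation_pool <- function(coords, frame_id = NULL, source = NULL,
                              cv = NULL) {
  if (is.list(coords)) {
    n <- length(coords)
    m1 <- as.matrix(coords[[1]])
    arr <- array(0, c(n, nrow(m1), ncol(m1)))
    for (f in seq_len(n)) {
      mf <- as.matrix(coords[[f]])
      if (!all(dim(mf) == dim(m1)))
        stop("all frames must share the same particle count")
      arr[f, , ] <- mf
    }
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3)
  nf <- dim(coords)[1]
  structure(list(coords = coords,
                 frame_id = frame_id %||% seq_len(nf),
                 source = source, cv = cv,
                 n_frames = nf, n_particles = dim(coords)[2],
                 ndim = dim(coords)[3]),
            class = "conformation_pool")
}

#' @export
print.conformation_pool <- function(x, ...) {
  cat(sprintf("conformation_pool: %d frames x %d particles (%dD)\n",
              x$n_frames, x$n_particles, x$ndim))
  invisible(x)
}

# Kabsch: optimal rotation of y onto x (both centered), returns rotated y
.kabsch_align <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  s <- svd(t(yc) %*% xc)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(rep(1, ncol(x) - 1), d))
  R <- s$v %*% D %*% t(s$u)
  yc %*% t(R)
}

.frame_rmsd <- function(a, b, superpose = TRUE) {
  if (superpose) {
    ac <- sweep(a, 2, colMeans(a))
    b <- .kabsch_align(a, b)
    a <- ac
  }
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Pairwise RMSD matrix of a conformation pool
#'
#' @param pool A [conformation_pool()] (>= 2 frames).
#' @param selection Optional integer vector of particle indices entering
#'   the RMSD; default all.
#' @param superpose Apply optimal least-squares rigid-body superposition
#'   (Kabsch) per pair before the RMSD. Default `TRUE`.
#' @return Symmetric matrix (A) with zero diagonal.
#' @export
pairwise_rmsd <- function(pool, selection = NULL, superpose = TRUE) {
  stopifnot(inherits(pool, "conformation_pool"))
  if (pool$n_frames < 2) stop("pairwise RMSD needs at least 2 frames")
  sel <- selection %||% seq_len(pool$n_particles)
  if (length(sel) == 0) stop("empty selection")
  nf <- pool$n_frames
  frames <- lapply(seq_len(nf), function(f)
    pool$coords[f, sel, , drop = FALSE][1, , ])
  frames <- lapply(frames, function(m)
    matrix(m, nrow = length(sel), ncol = pool$ndim))
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1))
    for (j in seq(i + 1, nf)) {
      D[i, j] <- D[j, i] <- .frame_rmsd(frames[[i]], frames[[j]], superpose)
    }
  D
}

#' Diameter-bounded agglomerative clustering of conformations
#'
#' Complete-linkage hierarchical agglomeration cut so that no two members
#' of any cluster are farther apart than `diameter` (for complete linkage
#' the merge height of a cluster equals its diameter, so cutting the tree
#' at the threshold yields exactly the diameter-bounded partition).  The
#' diameter invariant is certified post hoc by a direct check over all
#' intra-cluster pairs on every call.
#'
#' @param pool A [conformation_pool()].
#' @param diameter Maximum intra-cluster pairwise RMSD, A. Default 3.0.
#' @param selection,superpose Passed to [pairwise_rmsd()].
#' @param rmsd Optional precomputed pairwise RMSD matrix.
#' @return Object of class `cluster_set`: list with `membership` (integer
#'   per frame; clusters numbered by their smallest frame id),
#'   `representative` (medoid frame per cluster), `diameter`, `rmsd`,
#'   `n_clusters`.
#' @export
cluster_conformations <- function(pool, diameter = 3.0, selection = NULL,
                                  superpose = TRUE, rmsd = NULL) {
  stopifnot(inherits(pool, "conformation_pool"))
  if (pool$n_frames < 1) stop("empty pool")
  D <- rmsd %||% pairwise_rmsd(pool, selection, superpose)
  if (pool$n_frames == 1) {
    memb <- 1L
  } else if (diameter <= 0) {
    memb <- seq_len(pool$n_frames)
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    memb <- stats::cutree(hc, h = diameter)
  }
  # renumber clusters by smallest member frame id
  first <- tapply(seq_along(memb), memb, min)
  relabel <- rank(first, ties.method = "first")
  memb <- as.integer(relabel[as.character(memb)])
  # certify the diameter invariant
  for (cl in unique(memb)) {
    idx <- which(memb == cl)
    if (length(idx) > 1 && max(D[idx, idx]) > diameter + 1e-9)
      stop("internal error: cluster diameter invariant violated")
  }
  reps <- vapply(sort(unique(memb)), function(cl) {
    idx <- which(memb == cl)
    if (length(idx) == 1) return(idx)
    sums <- rowSums(D[idx, idx, drop = FALSE])
    idx[which.min(sums)]  # ties: smallest frame id via which.min
  }, 0L)
  structure(list(membership = memb, representative = reps,
                 diameter = diameter, rmsd = D,
                 n_clusters = length(reps)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters over %d frames (diameter %.2f A)\n",
              x$n_clusters, length(x$membership), x$diameter))
  invisible(x)
}

# inter-cluster distance per linkage mode
.cluster_distance <- function(clusters, a, b,
                              mode = c("single", "representative")) {
  mode <- match.arg(mode)
  D <- clusters$rmsd
  ia <- which(clusters$membership == a)
  ib <- which(clusters$membership == b)
  if (mode == "single") min(D[ia, ib])
  else D[clusters$representative[a], clusters$representative[b]]
}

#' Connect clusters into a network at a link threshold
#'
#' Two clusters are linked when their inter-cluster distance (single
#' linkage over member pairs by default, or representative-to-
#' representative RMSD) is at or below the threshold.
#'
#' @param clusters A [cluster_set()].
#' @param link Link threshold, A. Default 3.8.
#' @param mode `"single"` (any member pair) or `"representative"`.
#' @return Object of class `cluster_network`: list with `adjacency`
#'   (symmetric logical matrix, no self-edges), `edges` (data.frame
#'   `from`, `to`, `distance`), `labels` (cluster labels, initially `NA`),
#'   `clusters`, `mode`, `link`.
#' @export
build_network <- function(clusters, link = 3.8,
                          mode = c("single", "representative")) {
  stopifnot(inherits(clusters, "cluster_set"))
  mode <- match.arg(mode)
  k <- clusters$n_clusters
  adj <- matrix(FALSE, k, k)
  edges <- list()
  if (k > 1)
    for (a in seq_len(k - 1))
      for (b in seq(a + 1, k)) {
        d <- .cluster_distance(clusters, a, b, mode)
        if (d <= link) {
          adj[a, b] <- adj[b, a] <- TRUE
          edges[[length(edges) + 1]] <- data.frame(from = a, to = b,
                                                   distance = d)
        }
      }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = integer(), to = integer(),
                           distance = numeric())
  structure(list(adjacency = adj, edges = edges,
                 labels = rep(NA_character_, k), clusters = clusters,
                 mode = mode, link = link),
            class = "cluster_network")
}

#' Define a geometric classification criterion
#'
#' A criterion measures a distance in every frame of a cluster — either
#' between two particles or between the center of mass of a particle group
#' and a particle — and aggregates it either as the fraction of frames
#' strictly beyond/below a threshold (`aggregate = "fraction"`, satisfied
#' when that fraction is strictly greater than `p`) or as the mean distance
#' compared against the threshold (`aggregate = "mean"`).  All inequalities
#' are strict.
#'
#' @param kind `"atom-atom"` or `"com-atom"`.
#' @param i First particle index (`atom-atom`) — or, for `com-atom`, use
#'   `group`.
#' @param j Second particle index.
#' @param group Particle group whose center of mass is used (`com-atom`).
#' @param threshold Distance threshold, A (> 0).
#' @param direction `"less"` (distance < threshold counts) or `"greater"`.
#' @param aggregate `"fraction"` or `"mean"`.
#' @param p Fraction cutoff in (0, 1) for `aggregate = "fraction"`.
#'   Default 0.5.
#' @return Object of class `geom_criterion`.
#' @export
geom_criterion <- function(kind = c("atom-atom", "com-atom"), i = NULL,
                           j, group = NULL, threshold,
                           direction = c("less", "greater"),
                           aggregate = c("fraction", "mean"), p = 0.5) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  aggregate <- match.arg(aggregate)
  if (threshold <= 0) stop("threshold must be > 0")
  if (aggregate == "fraction" && (p <= 0 || p >= 1))
    stop("fraction cutoff must be in (0, 1)")
  if (kind == "atom-atom" && is.null(i)) stop("atom-atom needs indices i, j")
  if (kind == "com-atom" && is.null(group)) stop("com-atom needs a group")
  structure(list(kind = kind, i = i, j = j, group = group,
                 threshold = threshold, direction = direction,
                 aggregate = aggregate, p = p), class = "geom_criterion")
}

.criterion_distances <- function(crit, coords) {
  nf <- dim(coords)[1]
  vapply(seq_len(nf), function(f) {
    fr <- coords[f, , , drop = FALSE][1, , ]
    fr <- matrix(fr, ncol = dim(coords)[3])
    if (crit$kind == "atom-atom") {
      if (max(crit$i, crit$j) > nrow(fr))
        stop(sprintf("criterion names particle %d, beyond the frame",
                     max(crit$i, crit$j)))
      sqrt(sum((fr[crit$i, ] - fr[crit$j, ])^2))
    } else {
      if (max(c(crit$group, crit$j)) > nrow(fr))
        stop(sprintf("criterion names particle %d, beyond the frame",
                     max(c(crit$group, crit$j))))
      com <- colMeans(fr[crit$group, , drop = FALSE])
      sqrt(sum((com - fr[crit$j, ])^2))
    }
  }, 0)
}

#' Test one geometric criterion over a set of frames
#'
#' @param crit A [geom_criterion()].
#' @param coords Frame array `n_frames x n_particles x ndim`.
#' @return Logical: does the frame set satisfy the criterion?
#' @export
criterion_satisfied <- function(crit, coords) {
  d <- .criterion_distances(crit, coords)
  hit <- if (crit$direction == "less") d < crit$threshold
         else d > crit$threshold
  if (crit$aggregate == "fraction") mean(hit) > crit$p
  else if (crit$direction == "less") mean(d) < crit$threshold
  else mean(d) > crit$threshold
}

#' Classify clusters by ordered, labeled criterion sets
#'
#' Each element of `spec` is a list with a `label` and a list of `criteria`
#' ([geom_criterion()]); a cluster receives the label of the first set
#' whose criteria are all satisfied by its frames, or `default` otherwise.
#'
#' @param pool The [conformation_pool()] the clusters partition.
#' @param clusters A [cluster_set()] (or a `cluster_network`, whose labels
#'   are then filled in).
#' @param spec List of labeled criterion sets.
#' @param default Label for unmatched clusters. Default `"other"`.
#' @return Character vector of labels per cluster (and, for a network
#'   input, the network with `labels` set).
#' @export
classify_clusters <- function(pool, clusters, spec, default = "other") {
  net <- NULL
  if (inherits(clusters, "cluster_network")) {
    net <- clusters
    clusters <- clusters$clusters
  }
  labels <- vapply(seq_len(clusters$n_clusters), function(cl) {
    idx <- which(clusters$membership == cl)
    fr <- pool$coords[idx, , , drop = FALSE]
    for (set in spec) {
      ok <- all(vapply(set$criteria, criterion_satisfied, TRUE, coords = fr))
      if (ok) return(set$label)
    }
    default
  }, "")
  if (!is.null(net)) {
    net$labels <- labels
    return(net)
  }
  labels
}

#' Mean distance from query clusters to their nearest reference cluster
#'
#' For every query cluster, the minimum cluster-to-cluster distance to any
#' reference cluster — representative-to-representative RMSD by default, or
#' single linkage over member pairs — is found, and the minima are averaged
#' over the queries.  A query that also appears in the reference set is
#' excluded from its own reference comparisons.
#'
#' @param clusters A [cluster_set()] (or `cluster_network`).
#' @param query,reference Integer vectors of cluster ids (non-empty).
#' @param mode `"representative"` or `"single"`.
#' @return Scalar mean nearest-reference distance, A.
#' @export
mean_nearest_neighbor_distance <- function(clusters, query, reference,
                                           mode = c("representative",
                                                    "single")) {
  if (inherits(clusters, "cluster_network")) clusters <- clusters$clusters
  stopifnot(inherits(clusters, "cluster_set"))
  mode <- match.arg(mode)
  if (length(query) == 0 || length(reference) == 0)
    stop("query and reference sets must be non-empty")
  nn <- vapply(query, function(q) {
    refs <- setdiff(reference, q)
    if (length(refs) == 0)
      stop("empty reference set after self-exclusion for cluster ", q)
    min(vapply(refs, function(r)
      .cluster_distance(clusters, q, r, mode), 0))
  }, 0)
  mean(nn)
}

#' Normalized 2D density with fixed contour interval
#'
#' A two-dimensional histogram over the two CV columns, normalized to total
#' mass one, with contour levels at multiples of `interval`.
#'
#' @param cv_xy Matrix or data.frame with two columns of per-frame CV
#'   values (>= 1 row).
#' @param xlim,ylim Axis ranges; default data range padded by one bin.
#' @param nbins Number of bins per axis. Default 50.
#' @param interval Contour interval in density units. Default 0.005.
#' @return Object of class `density_map`: list with `x`, `y` (bin centers),
#'   `density` (matrix summing to 1), `levels` (contour levels),
#'   `interval`.
#' @export
density_contours <- function(cv_xy, xlim = NULL, ylim = NULL, nbins = 50,
                             interval = 0.005) {
  cv_xy <- as.matrix(cv_xy)
  if (nrow(cv_xy) < 1) stop("at least one frame is required")
  if (ncol(cv_xy) != 2) stop("density_contours expects two CV columns")
  if (nbins < 2) stop("degenerate grid")
  pad <- function(r) {
    if (diff(r) == 0) r + c(-0.5, 0.5) else r + diff(r) / nbins * c(-1, 1)
  }
  xlim <- xlim %||% pad(range(cv_xy[, 1]))
  ylim <- ylim %||% pad(range(cv_xy[, 2]))
  xb <- seq(xlim[1], xlim[2], length.out = nbins + 1)
  yb <- seq(ylim[1], ylim[2], length.out = nbins + 1)
  ix <- pmin(pmax(findInterval(cv_xy[, 1], xb, all.inside = TRUE), 1), nbins)
  iy <- pmin(pmax(findInterval(cv_xy[, 2], yb, all.inside = TRUE), 1), nbins)
  dens <- matrix(0, nbins, nbins)
  for (f in seq_len(nrow(cv_xy)))
    dens[ix[f], iy[f]] <- dens[ix[f], iy[f]] + 1
  dens <- dens / sum(dens)
  levels <- seq(interval, max(dens), by = interval)
  structure(list(x = (xb[-1] + xb[-length(xb)]) / 2,
                 y = (yb[-1] + yb[-length(yb)]) / 2,
                 density = dens, levels = levels, interval = interval),
            class = "density_map")
}

#' Root-mean-square fluctuations per particle
#'
#' RMSF about the mean structure, `sqrt(<|x - <x>|^2>)` per particle, after
#' optional rigid-body superposition of every frame onto the first frame
#' (Kabsch, over `superpose_selection`).
#'
#' @param pool A [conformation_pool()] or [run_langevin()] trajectory
#'   (>= 2 frames).
#' @param selection Particles to report; default all.
#' @param superpose Superpose frames before averaging. Default `FALSE`
#'   (appropriate when the system is anchored in space).
#' @param superpose_selection Particles used for the superposition;
#'   default all.
#' @return Object of class `rmsf_profile`: data.frame with columns
#'   `particle` and `rmsf` (A).
#' @export
compute_rmsf <- function(pool, selection = NULL, superpose = FALSE,
                         superpose_selection = NULL) {
  if (inherits(pool, "md_trajectory"))
    pool <- conformation_pool(pool$coords)
  stopifnot(inherits(pool, "conformation_pool"))
  if (pool$n_frames < 2) stop("RMSF needs at least 2 frames")
  sel <- selection %||% seq_len(pool$n_particles)
  coords <- pool$coords
  if (superpose) {
    ssel <- superpose_selection %||% seq_len(pool$n_particles)
    ref <- matrix(coords[1, ssel, ], ncol = pool$ndim)
    refc <- sweep(ref, 2, colMeans(ref))
    for (f in seq_len(pool$n_frames)) {
      fr <- matrix(coords[f, , ], ncol = pool$ndim)
      sub <- fr[ssel, , drop = FALSE]
      subc <- sweep(sub, 2, colMeans(sub))
      s <- svd(t(subc) %*% refc)
      d <- sign(det(s$v %*% t(s$u)))
      D <- diag(c(rep(1, pool$ndim - 1), d))
      R <- s$v %*% D %*% t(s$u)
      coords[f, , ] <- sweep(fr, 2, colMeans(sub)) %*% t(R)
    }
  }
  rmsf <- vapply(sel, function(p) {
    xp <- matrix(coords[, p, ], ncol = pool$ndim)
    mu <- colMeans(xp)
    sqrt(mean(rowSums(sweep(xp, 2, mu)^2)))
  }, 0)
  structure(data.frame(particle = sel, rmsf = rmsf),
            class = c("rmsf_profile", "data.frame"))
}
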