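#' Build a 2D binary search tree (k-d tree) over bin feature points
#'
#' Alternating-axis median splits, starting on the MQ axis, then RD, and
#' so on; each internal node stores the lower-median point of its split
#' axis, points with axis value up to the median go left (BST ordering),
#' the rest right. Subsets of at most \code{leafSize} points are stored
#' in leaf buckets. The tree supports exact epsilon-range queries
#' without all-pairs distance computation.
#'
#' @param points numeric matrix with n rows and 2 columns
#'   \code{(rd, mq)}.
#' @param leafSize maximum bucket size of a leaf (default 16).
#' @return an object of class \code{KdTree2D}.
#' @export
buildKdTree <- function(points, leafSize = 16L) {
    points <- as.matrix(points)
    stopifnot(ncol(points) == 2L, nrow(points) >= 1L,
              all(is.finite(points)), leafSize >= 1L)
    build <- function(idx, depth) {
        if (length(idx) <= leafSize)
            return(list(leaf = TRUE, idx = idx))
        axis <- if (depth %% 2L == 1L) 2L else 1L     # MQ axis first
        ord <- idx[order(points[idx, axis])]
        m <- (length(ord) + 1L) %/% 2L                # lower median
        list(leaf = FALSE, axis = axis,
             split = unname(points[ord[m], axis]), point = ord[m],
             left = build(ord[seq_len(m - 1L)], depth + 1L),
             right = build(ord[seq.int(m + 1L, length(ord))], depth + 1L))
    }
    structure(list(root = build(seq_len(nrow(points)), 1L),
                   points = points, leafSize = as.integer(leafSize)),
              class = "KdTree2D")
}

#' @export
print.KdTree2D <- function(x, ...) {
    cat("KdTree2D |", nrow(x$points), "points | leaf size",
        x$leafSize, "\n")
    invisible(x)
}

#' Exact epsilon-range query on a 2D k-d tree
#'
#' Returns the indices of all points within Euclidean distance
#' \code{eps} of \code{q} (a closed ball, so a point at distance exactly
#' \code{eps} is included). Descends to the bucket containing \code{q},
#' then backtracks, visiting a sibling subtree only when the splitting
#' hyperplane lies within \code{eps} of \code{q} — which is exactly the
#' condition under which the sibling can hold a qualifying point.
#'
#' @param tree a \code{KdTree2D} from [buildKdTree()].
#' @param q numeric length-2 query point \code{(rd, mq)}.
#' @param eps search radius, > 0.
#' @return sorted integer indices into the tree's point matrix.
#' @export
kdRangeQuery <- function(tree, q, eps) {
    stopifnot(inherits(tree, "KdTree2D"), length(q) == 2L, eps > 0)
    pts <- tree$points
    eps2 <- eps^2
    hits <- integer(0)
    recurse <- function(node) {
        if (node$leaf) {
            if (length(node$idx)) {
                d2 <- (pts[node$idx, 1L] - q[1L])^2 +
                      (pts[node$idx, 2L] - q[2L])^2
                hits <<- c(hits, node$idx[d2 <= eps2])
            }
            return(invisible(NULL))
        }
        d2 <- (pts[node$point, 1L] - q[1L])^2 +
              (pts[node$point, 2L] - q[2L])^2
        if (d2 <= eps2)
            hits <<- c(hits, node$point)
        delta <- q[node$axis] - node$split
        if (delta <= 0) {
            recurse(node$left)
            if (-delta <= eps) recurse(node$right)
        } else {
            recurse(node$right)
            if (delta <= eps) recurse(node$left)
        }
        invisible(NULL)
    }
    recurse(tree$root)
    sort(hits)
}

#' DBSCAN over 2D bin feature points
#'
#' Density-based clustering of the (RD, MQ) bin points. A point whose
#' closed epsilon-neighborhood (which counts the point itself) holds at
#' least \code{minPts} points is a core point; clusters are the
#' density-connected components of core points; non-core points within
#' \code{eps} of a cluster's core point become border members of the
#' first cluster that reaches them (core points are seeded in ascending
#' index order, so the labelling is deterministic). Everything else is
#' noise — and in this caller, noise bins are the TD candidates.
#'
#' @param points numeric n x 2 matrix \code{(rd, mq)}.
#' @param eps neighborhood radius (default 0.7).
#' @param minPts minimum neighborhood size for a core point (default 4,
#'   twice the number of features).
#' @param leafSize k-d tree leaf bucket size.
#' @return a list with \code{labels} (integer vector, 0 = noise,
#'   clusters numbered from 1), \code{isCore} (logical) and
#'   \code{nClusters}.
#' @export
dbscanCluster <- function(points, eps = 0.7, minPts = 4L,
                          leafSize = 16L) {
    points <- as.matrix(points)
    stopifnot(eps > 0, minPts >= 1L)
    n <- nrow(points)
    tree <- buildKdTree(points, leafSize)
    nbr <- vector("list", n)
    for (i in seq_len(n))
        nbr[[i]] <- kdRangeQuery(tree, points[i, ], eps)
    .dbscanFromNeighborhoods(nbr, minPts)
}

## Clustering given precomputed neighborhoods (shared by the k-d tree
## implementation and by brute-force cross-checks in the test suite).
.dbscanFromNeighborhoods <- function(nbr, minPts) {
    n <- length(nbr)
    isCore <- lengths(nbr) >= minPts
    labels <- integer(n)
    cl <- 0L
    for (i in seq_len(n)) {
        if (!isCore[i] || labels[i] != 0L)
            next
        cl <- cl + 1L
        labels[i] <- cl
        queue <- i
        head <- 1L
        while (head <= length(queue)) {
            p <- queue[head]
            head <- head + 1L
            if (!isCore[p])
                next                       # border: claimed, not expanded
            nb <- nbr[[p]]
            fresh <- nb[labels[nb] == 0L]
            if (length(fresh)) {
                labels[fresh] <- cl
                queue <- c(queue, fresh)
            }
        }
    }
    list(labels = labels, isCore = isCore, nClusters = cl)
}

#' Indices of noise bins from a clustering
#'
#' @param labels result of [dbscanCluster()] (or its \code{labels}
#'   vector); label 0 marks noise.
#' @return ascending integer indices of noise points.
#' @export
noiseBins <- function(labels) {
    if (is.list(labels))
        labels <- labels$labels
    sort(which(labels == 0L))
}
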