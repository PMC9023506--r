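#' Default behavior feature weights
#'
#' The clustering down-weights the five optomotor features: weight 1 for
#' the activity family, 0.5 ("Eweight") for the OMR family.
#'
#' @return Named numeric vector of 10 weights.
#' @export
behavior_weights <- function() {
  w <- stats::setNames(rep(1, 10), behavior_measure_names())
  w[omr_measures()] <- 0.5
  w
}

#' Feature matrix of behavioral profiles
#'
#' Rows are profile labels (drugs, reference compounds, additive
#' inverses), columns the 10 behaviors, values percentage-point deltas
#' (missing allowed). No centering, scaling, or transformation is applied
#' before clustering.
#'
#' @param x Numeric matrix (labels as rownames) or a
#'   `behavioral_profiles` data.frame (spread via [profiles_matrix()]).
#' @param weights Per-column weights; defaults to [behavior_weights()]
#'   matched by column name (columns without a default get weight 1).
#' @return A `feature_matrix`: the matrix with a `weights` attribute.
#' @export
feature_matrix <- function(x, weights = NULL) {
  if (inherits(x, "behavioral_profiles")) x <- profiles_matrix(x)
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("feature matrix needs row labels", call. = FALSE)
  if (nrow(x) < 2L) stop("feature matrix needs at least 2 rows", call. = FALSE)
  if (is.null(weights)) {
    weights <- rep(1, ncol(x))
    known <- intersect(colnames(x), behavior_measure_names())
    weights[match(known, colnames(x))] <- behavior_weights()[known]
  }
  stopifnot(length(weights) == ncol(x), all(weights > 0))
  if (any(rowSums(!is.na(x)) == 0L)) {
    stop("every row needs at least one defined value", call. = FALSE)
  }
  structure(x, weights = as.numeric(weights), class = c("feature_matrix", "matrix"))
}

#' @export
as.matrix.feature_matrix <- function(x, ...) {
  attr(x, "weights") <- NULL
  attr(x, "family") <- NULL
  class(x) <- NULL
  x
}

#' Weighted Euclidean distance (Cluster 3.0 convention)
#'
#' The mean weighted squared difference over mutually defined features:
#' `d = sum(w * (x - y)^2) / sum(w)`, without a square root, with the
#' weight normalization restricted to features defined in both rows.
#' `sqrt = TRUE` gives the textbook-metric variant. The merge order of
#' complete linkage is identical either way; the no-sqrt form matches the
#' clustering tool the assay's profiles were designed for.
#'
#' @param x,y Numeric vectors (NAs allowed).
#' @param w Positive weights (recycled-length-checked).
#' @param sqrt Take the square root of the mean squared difference.
#' @return Nonnegative distance; `d(x, x) = 0`.
#' @examples
#' weighted_euclidean(c(10, rep(0, 9)), rep(0, 10), rep(1, 10)) # 10
#' @export
weighted_euclidean <- function(x, y, w = NULL, sqrt = FALSE) {
  stopifnot(length(x) == length(y))
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x), all(w > 0))
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no mutually defined features", call. = FALSE)
  d <- sum(w[ok] * (x[ok] - y[ok])^2) / sum(w[ok])
  if (sqrt) base::sqrt(d) else d
}

#' Pairwise weighted distance matrix
#' @param fm A [feature_matrix()].
#' @param sqrt See [weighted_euclidean()].
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
profile_distances <- function(fm, sqrt = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  w <- attr(fm, "weights")
  n <- nrow(fm)
  d <- matrix(0, n, n, dimnames = list(rownames(fm), rownames(fm)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- weighted_euclidean(fm[i, ], fm[j, ], w, sqrt = sqrt)
    }
  }
  d
}

#' Additive-inverse (hypothetical) profiles
#'
#' Negates every defined delta of the selected rows, appending them as
#' hypothetical compounds with a `-inv` label suffix. Searching for real
#' compounds that cluster with the inverse of a reference profile
#' identifies drugs with opposite effects on the brain.
#'
#' @param x A `feature_matrix`, matrix, or numeric profile vector.
#' @param rows Labels (or indices) of rows to invert; default all.
#' @param append If `TRUE` (default for matrices) return the input with
#'   the inverted rows appended; otherwise return just the inverted rows.
#' @return Same shape as the input.
#' @export
additive_inverse <- function(x, rows = NULL, append = inherits(x, "matrix") ||
                               is.matrix(x)) {
  if (is.null(dim(x))) {
    return(-x)
  }
  w <- attr(x, "weights")
  m <- as.matrix(x)
  if (is.null(rows)) rows <- rownames(m)
  if (is.numeric(rows)) rows <- rownames(m)[rows]
  inv <- -m[rows, , drop = FALSE]
  rownames(inv) <- paste0(rows, "-inv")
  out <- if (append) rbind(m, inv) else inv
  if (!is.null(w) && nrow(out) >= 2L) out <- feature_matrix(out, weights = w)
  out
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering on [weighted_euclidean()] distances with
#' complete (maximum) linkage. Ties in the minimum inter-cluster distance
#' are broken deterministically in favor of the pair of clusters with the
#' smallest original row indices, so the merge sequence is reproducible
#' and independent of row order up to relabeling.
#'
#' @param fm A [feature_matrix()] (or matrix coercible to one).
#' @param sqrt Use the square-root distance variant.
#' @return A `linkage_tree`: list with `merge`, `height`, `order`,
#'   `labels` in [stats::hclust()] conventions (use [as.hclust()] for
#'   plotting and [stats::cutree()]).
#' @export
complete_linkage <- function(fm, sqrt = FALSE) {
  if (!inherits(fm, "feature_matrix")) fm <- feature_matrix(fm)
  d <- profile_distances(fm, sqrt = sqrt)
  n <- nrow(d)
  # active cluster bookkeeping: id = negative leaf / positive merge node,
  # min_leaf = smallest original row index (tie-break key)
  active <- data.frame(id = -seq_len(n), min_leaf = seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  dd <- d
  for (step in seq_len(n - 1L)) {
    k <- nrow(active)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        dij <- dd[i, j]
        if (dij < best_d) {
          best_d <- dij
          best <- c(i, j)
        } else if (dij == best_d) {
          # smallest-pair tie-break on (min leaf of i, min leaf of j)
          cur <- sort(c(active$min_leaf[i], active$min_leaf[j]))
          old <- sort(c(active$min_leaf[best[1]], active$min_leaf[best[2]]))
          if (cur[1] < old[1] || (cur[1] == old[1] && cur[2] < old[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]
    j <- best[2]
    ids <- sort(c(active$id[i], active$id[j]))
    merge[step, ] <- ids
    height[step] <- best_d
    # complete linkage: new distances are the pairwise maxima
    new_row <- pmax(dd[i, ], dd[j, ])[-c(i, j)]
    keep <- setdiff(seq_len(k), c(i, j))
    dd <- dd[keep, keep, drop = FALSE]
    dd <- rbind(cbind(dd, new_row), c(new_row, 0))
    active <- rbind(
      active[keep, , drop = FALSE],
      data.frame(id = step, min_leaf = min(active$min_leaf[c(i, j)]))
    )
  }
  tree <- structure(
    list(
      merge = merge, height = height,
      order = tree_leaf_order(merge),
      labels = rownames(d),
      method = "complete",
      dist.method = if (sqrt) "weighted_euclidean_sqrt" else "weighted_euclidean",
      call = match.call()
    ),
    class = "linkage_tree"
  )
  tree
}

# Leaf order by left-to-right traversal of the merge tree.
tree_leaf_order <- function(merge) {
  rec <- function(node) {
    if (node < 0L) {
      return(-node)
    }
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' @export
as.hclust.linkage_tree <- function(x, ...) {
  structure(
    list(
      merge = x$merge, height = x$height, order = x$order,
      labels = x$labels, method = x$method, call = x$call,
      dist.method = x$dist.method
    ),
    class = "hclust"
  )
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(
    "Complete-linkage tree over", length(x$labels), "profiles",
    sprintf("(distance: %s)\n", x$dist.method)
  )
  cat("Merge heights:", paste(signif(x$height, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Cut a linkage tree into flat clusters
#'
#' Cuts at `k` clusters or height `h` and reports each cluster's members
#' and cohesion. Cohesion is reconstructed as the mean pairwise Pearson
#' correlation of the member profiles over mutually defined features
#' (`cohesion = "min"` reports the minimum pairwise correlation instead);
#' singletons get `NA`.
#'
#' @param tree A `linkage_tree`.
#' @param fm The [feature_matrix()] the tree was built from (for
#'   cohesion).
#' @param k,h Number of clusters or cut height (exactly one).
#' @param cohesion `"mean"` or `"min"` pairwise correlation.
#' @return List of cluster reports: `members`, `size`, `cohesion`.
#' @export
extract_clusters <- function(tree, fm, k = NULL, h = NULL,
                             cohesion = c("mean", "min")) {
  cohesion <- match.arg(cohesion)
  stopifnot(inherits(tree, "linkage_tree"), xor(is.null(k), is.null(h)))
  if (!is.null(k) && (k < 1L || k > length(tree$labels))) {
    stop("k must lie in 1..number of leaves", call. = FALSE)
  }
  assign <- stats::cutree(as.hclust(tree), k = k, h = h)
  m <- as.matrix(fm)
  lapply(split(names(assign), assign), function(members) {
    coh <- NA_real_
    if (length(members) >= 2L) {
      cors <- c()
      for (i in seq_len(length(members) - 1L)) {
        for (j in (i + 1L):length(members)) {
          cors <- c(cors, profile_correlation(m[members[i], ], m[members[j], ]))
        }
      }
      coh <- if (cohesion == "mean") mean(cors, na.rm = TRUE) else min(cors, na.rm = TRUE)
    }
    list(members = members, size = length(members), cohesion = coh)
  })
}

# Pearson correlation over mutually defined features; NA when fewer than
# 3 shared features or a profile is constant.
profile_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) {
    return(NA_real_)
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}

#' Export a clustered profile table in Cluster 3.0 format
#'
#' Writes the clustered data table (CDT) with GID/UNIQID/NAME/GWEIGHT
#' columns, the EWEIGHT row carrying the feature weights (0.5 for OMR
#' columns under the defaults), rows in dendrogram leaf order, and the
#' gene-tree (GTR) file with one `NODEkX` line per merge. GTR scores are
#' the negated merge heights, so larger scores mean tighter nodes, as
#' tree-viewer programs expect.
#'
#' @param fm The [feature_matrix()].
#' @param tree The `linkage_tree` over its rows.
#' @param cdt_path,gtr_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_cdt_gtr <- function(fm, tree, cdt_path, gtr_path) {
  stopifnot(inherits(tree, "linkage_tree"))
  m <- as.matrix(fm)
  stopifnot(identical(rownames(m), tree$labels))
  w <- attr(fm, "weights")
  n <- nrow(m)
  gid <- sprintf("GENE%dX", seq_len(n))
  fmtnum <- function(x) ifelse(is.na(x), "", formatC(x, format = "g", digits = 10))
  header <- c("GID", "UNIQID", "NAME", "GWEIGHT", colnames(m))
  eweight <- c("EWEIGHT", "", "", "", fmtnum(w))
  lines <- c(
    paste(header, collapse = "\t"),
    paste(eweight, collapse = "\t")
  )
  for (i in tree$order) {
    row <- c(gid[i], tree$labels[i], tree$labels[i], "1", fmtnum(m[i, ]))
    lines <- c(lines, paste(row, collapse = "\t"))
  }
  writeLines(lines, cdt_path)

  node_name <- function(id) {
    if (id < 0L) gid[-id] else sprintf("NODE%dX", id)
  }
  gtr <- vapply(seq_len(nrow(tree$merge)), function(s) {
    paste(
      c(
        sprintf("NODE%dX", s),
        node_name(tree$merge[s, 1]), node_name(tree$merge[s, 2]),
        formatC(-tree$height[s], format = "g", digits = 10)
      ),
      collapse = "\t"
    )
  }, character(1))
  writeLines(gtr, gtr_path)
  invisible(list(cdt = cdt_path, gtr = gtr_path))
}

#' Read a CDT file back into a feature matrix
#'
#' Inverse of the CDT half of [write_cdt_gtr()]; rows come back in the
#' file's (leaf) order.
#'
#' @param path CDT path.
#' @return A [feature_matrix()] with the EWEIGHT row as weights.
#' @export
read_cdt <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  cols <- header[-(1:4)]
  ew <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  weights <- as.numeric(ew[-(1:4)])
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  m <- t(vapply(body, function(x) {
    vals <- x[-(1:4)]
    vals[vals == ""] <- NA
    as.numeric(vals)
  }, numeric(length(cols))))
  rownames(m) <- vapply(body, `[[`, character(1), 2L)
  colnames(m) <- cols
  feature_matrix(m, weights = weights)
}
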