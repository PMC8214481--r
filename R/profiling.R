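#' Build a herb-by-feature profile matrix
#'
#' Binary mode (the default input): each herb maps to a feature set and the
#' matrix holds 0/1 incidence.  Count mode: each herb maps to a named numeric
#' vector (e.g. enriched-gene counts per pathway).  Columns are the union of
#' features, sorted lexicographically; herbs with an all-zero row are dropped
#' with a warning.
#'
#' @param features Named list: herb -> character vector (binary) or named
#'   numeric vector (counts).
#' @param level Feature level label: `"symptom"`, `"target"`, `"go"` or
#'   `"kegg"`.
#' @return A numeric matrix (herbs x features) with attribute `level`.
#' @export
build_profile <- function(features, level = c("symptom", "target", "go", "kegg")) {
  level <- match.arg(level)
  stopifnot(is.list(features), !is.null(names(features)))
  if (length(features) < 2L) stop("need at least 2 herbs", call. = FALSE)
  counts_mode <- any(vapply(features, is.numeric, NA))
  cols <- sort(unique(unlist(lapply(features, function(f) {
    if (is.numeric(f)) names(f) else as.character(f)
  }), use.names = FALSE)))
  if (length(cols) == 0L) stop("no features in any herb", call. = FALSE)
  mat <- matrix(0, nrow = length(features), ncol = length(cols),
                dimnames = list(names(features), cols))
  for (h in names(features)) {
    f <- features[[h]]
    if (is.numeric(f)) {
      mat[h, names(f)] <- as.numeric(f)
    } else if (length(f) > 0L) {
      mat[h, as.character(f)] <- 1
    }
  }
  zero <- rowSums(mat != 0) == 0L
  if (any(zero)) {
    warning("dropping herb(s) with empty profile: ",
            paste(rownames(mat)[zero], collapse = ", "), call. = FALSE)
    mat <- mat[!zero, , drop = FALSE]
  }
  if (nrow(mat) < 2L) stop("fewer than 2 herbs with non-empty profiles", call. = FALSE)
  attr(mat, "level") <- level
  attr(mat, "mode") <- if (counts_mode) "count" else "binary"
  mat
}

#' Pairwise Euclidean distances between profile rows
#'
#' \eqn{D_{ij} = \sqrt{\sum_f (x_{if} - x_{jf})^2}}; for binary profiles
#' \eqn{D_{ij}^2} equals the Hamming distance between the rows.
#'
#' @param profile Matrix from [build_profile()] (or any numeric matrix).
#' @return A `dist` object.
#' @export
profile_dist <- function(profile) {
  stats::dist(profile, method = "euclidean")
}

#' Error sum of squares of a cluster
#'
#' \eqn{ESS = \sum_i x_i^2 - \frac{1}{n}\left(\sum_i x_i\right)^2} applied per
#' coordinate and summed, i.e. the total within-cluster sum of squared
#' deviations from the centroid.
#'
#' @param x Numeric matrix (rows = cluster members) or vector (one coordinate).
#' @return Scalar ESS.
#' @export
ess <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n == 0L) return(0)
  sum(x^2) - sum(colSums(x)^2) / n
}

#' Agglomerative Ward clustering on the error sum of squares
#'
#' Starts from singletons and at each step merges the pair of clusters whose
#' union minimises the increase in total ESS, computed directly from the
#' cluster sizes and centroids as
#' \eqn{\Delta ESS = \frac{n_A n_B}{n_A + n_B} \lVert c_A - c_B \rVert^2}
#' (for singletons this is half the squared Euclidean distance).  Ties are
#' broken by the smallest pair of cluster labels, a cluster's label being the
#' smallest original row index among its members; this makes the output
#' deterministic.  Merge costs are non-decreasing (Ward has no inversions).
#'
#' The `"ward.D2"` method delegates to [stats::hclust()] on the Euclidean
#' distances as an alternative linkage; its heights are on the
#' \eqn{\sqrt{2\,\Delta ESS}} scale.
#'
#' @param profile Numeric matrix (herbs x features), e.g. from
#'   [build_profile()].
#' @param method `"ess"` (direct ESS-increase merging, the default) or
#'   `"ward.D2"`.
#' @return A `ward_clustering`: list with `merge` (n-1 x 2 matrix in
#'   [stats::hclust()] convention), `delta_ess` (merge costs), `height`
#'   (cumulative ESS after each merge), `labels`, and `method`.
#' @export
ward_cluster <- function(profile, method = c("ess", "ward.D2")) {
  method <- match.arg(method)
  stopifnot(is.matrix(profile), nrow(profile) >= 2L)
  labels <- rownames(profile)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(profile)))
  n <- nrow(profile)
  if (method == "ward.D2") {
    hc <- stats::hclust(stats::dist(profile), method = "ward.D2")
    delta <- hc$height^2 / 2
    return(structure(list(merge = hc$merge, delta_ess = delta,
                          height = cumsum(delta), labels = labels,
                          method = method),
                     class = "ward_clustering"))
  }
  active <- seq_len(n)                  # cluster label = smallest member row index
  members <- as.list(seq_len(n))
  centroid <- profile
  size <- rep(1L, n)
  merge_id <- rep(0L, n)                # 0 = singleton, else merge step index
  merge <- matrix(0L, n - 1L, 2L)
  delta_ess <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]; b <- active[jj]
        d2 <- sum((centroid[a, ] - centroid[b, ])^2)
        cost <- size[a] * size[b] / (size[a] + size[b]) * d2
        lo <- min(a, b); hi <- max(a, b)
        if (is.null(best) || cost < best$cost - 1e-12 ||
            (abs(cost - best$cost) <= 1e-12 &&
             (lo < best$lo || (lo == best$lo && hi < best$hi)))) {
          best <- list(cost = cost, lo = lo, hi = hi)
        }
      }
    }
    a <- best$lo; b <- best$hi
    code <- function(cl) if (merge_id[cl] == 0L) -cl else merge_id[cl]
    merge[step, ] <- sort(c(code(a), code(b)))
    delta_ess[step] <- best$cost
    centroid[a, ] <- (size[a] * centroid[a, ] + size[b] * centroid[b, ]) /
      (size[a] + size[b])
    members[[a]] <- c(members[[a]], members[[b]])
    size[a] <- size[a] + size[b]
    merge_id[a] <- step
    active <- setdiff(active, b)
  }
  structure(list(merge = merge, delta_ess = delta_ess,
                 height = cumsum(delta_ess), labels = labels, method = "ess"),
            class = "ward_clustering")
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat("ward_clustering (", x$method, "): ", length(x$labels), " items, ",
      nrow(x$merge), " merges, total ESS ",
      format(x$height[length(x$height)]), "\n", sep = "")
  invisible(x)
}

#' Cut a Ward clustering into k groups
#'
#' Undoes the last k-1 merges.  Groups are numbered by first appearance in
#' the original row order, so the labelling is deterministic.
#'
#' @param clustering A `ward_clustering`.
#' @param k Number of clusters, between 1 and the number of items.
#' @return Named integer vector (item -> cluster in 1..k).
#' @export
cut_ward <- function(clustering, k) {
  stopifnot(inherits(clustering, "ward_clustering"))
  n <- length(clustering$labels)
  if (k < 1L || k > n) stop("k must be between 1 and ", n, call. = FALSE)
  assignment <- seq_len(n)
  steps <- n - k
  if (steps > 0L) {
    cluster_members <- vector("list", n - 1L)
    for (step in seq_len(steps)) {
      get_members <- function(code) {
        if (code < 0L) -code else cluster_members[[code]]
      }
      m <- c(get_members(clustering$merge[step, 1L]),
             get_members(clustering$merge[step, 2L]))
      cluster_members[[step]] <- m
      assignment[m] <- min(assignment[m])
    }
  }
  relabel <- match(assignment, unique(assignment))
  stats::setNames(as.integer(relabel), clustering$labels)
}

#' Cross-level cluster membership table
#'
#' Lays out one clustering per feature level side by side: one row per
#' cluster index, one column per level, each cell listing the member herbs.
#'
#' @param assignments Named list: level -> named integer vector as returned
#'   by [cut_ward()].
#' @return Data frame with a `cluster` column and one character column per
#'   level (comma-joined member herbs, `""` when a level has fewer clusters).
#' @export
multilevel_summary <- function(assignments) {
  stopifnot(is.list(assignments), length(assignments) >= 1L,
            !is.null(names(assignments)))
  kmax <- max(vapply(assignments, max, 1L))
  out <- data.frame(cluster = seq_len(kmax))
  for (level in names(assignments)) {
    a <- assignments[[level]]
    out[[level]] <- vapply(seq_len(kmax), function(cl) {
      paste(sort(names(a)[a == cl]), collapse = ", ")
    }, "")
  }
  out
}
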