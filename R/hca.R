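#' Ward hierarchical clustering via the Lance-Williams update
#'
#' Agglomerative clustering with Ward's minimum-variance linkage on one of
#' three dissimilarities. For \code{"euclidean"} the algorithm operates on
#' squared Euclidean distances (Ward's original objective) and reports square
#' roots of the criterion as merge heights (the \code{ward.D2} convention);
#' for \code{"squared_euclidean"} and \code{"manhattan"} the Lance-Williams
#' Ward update is applied to the chosen dissimilarity as-is (the
#' \code{ward.D} convention). Ward on Manhattan distances is a heuristic --
#' the variance interpretation is lost -- but is provided because both
#' metrics are commonly compared on high-dimensional omics tables. Ties are
#' broken deterministically by the lowest pair index.
#'
#' @param x numeric matrix, rows are the objects to cluster; no missing values
#' @param distance "euclidean", "squared_euclidean" or "manhattan"
#' @return object of class \code{ward_hca}: \code{merge} and \code{height} in
#'   \code{\link[stats]{hclust}} encoding, \code{labels}, \code{linkage},
#'   \code{distance}, and the cophenetic distance matrix \code{cophenetic}
#' @export
ward_hca <- function(x, distance = c("euclidean", "squared_euclidean",
                                     "manhattan")) {
  distance <- match.arg(distance)
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) stop("input matrix contains NA/Inf")
  n <- nrow(x)
  if (n < 2) stop("need at least two rows")
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  D <- switch(distance,
    euclidean = as.matrix(stats::dist(x, "euclidean"))^2,
    squared_euclidean = as.matrix(stats::dist(x, "euclidean"))^2,
    manhattan = as.matrix(stats::dist(x, "manhattan")))
  diag(D) <- Inf

  size <- rep(1L, n)
  active <- rep(TRUE, n)
  id <- -seq_len(n)            # hclust encoding: negatives are leaves
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- lapply(seq_len(n), function(i) i)
  coph <- matrix(0, n, n)

  for (step in seq_len(n - 1)) {
    # lowest-index tie-break: row-major scan keeps the first strict minimum
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(n - 1)) {
      if (!active[i]) next
      for (j in seq((i + 1), n)) {
        if (!active[j]) next
        if (D[i, j] < best) { best <- D[i, j]; bi <- i; bj <- j }
      }
    }
    h <- if (distance == "euclidean") sqrt(best) else best
    height[step] <- h
    pr <- c(id[bi], id[bj])
    # hclust row convention: singletons (negative) first, then ascending
    pr <- pr[order(pr >= 0, abs(pr))]
    merge[step, ] <- pr
    coph[members[[bi]], members[[bj]]] <- h
    coph[members[[bj]], members[[bi]]] <- h

    ni <- size[bi]; nj <- size[bj]
    for (k in seq_len(n)) {
      if (!active[k] || k == bi || k == bj) next
      nk <- size[k]
      D[bi, k] <- D[k, bi] <-
        ((ni + nk) * D[bi, k] + (nj + nk) * D[bj, k] - nk * best) /
        (ni + nj + nk)
    }
    size[bi] <- ni + nj
    active[bj] <- FALSE
    members[[bi]] <- c(members[[bi]], members[[bj]])
    id[bi] <- step
  }
  dimnames(coph) <- list(labels, labels)
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = "ward", distance = distance, cophenetic = coph),
            class = "ward_hca")
}

#' @export
print.ward_hca <- function(x, ...) {
  cat("Ward hierarchical clustering (", x$distance, "), ",
      length(x$labels), " leaves\n", sep = "")
  invisible(x)
}

#' Convert a ward_hca tree to an hclust object
#' @param x a [ward_hca()] result
#' @param ... unused
#' @return an object of class \code{hclust}
#' @export
as.hclust.ward_hca <- function(x, ...) {
  # leaf order: left-to-right traversal of the merge tree
  ord <- function(k) {
    if (k < 0) return(-k)
    c(ord(x$merge[k, 1]), ord(x$merge[k, 2]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = ord(nrow(x$merge)), labels = x$labels,
                 method = paste0("ward/", x$distance),
                 call = match.call(), dist.method = x$distance),
            class = "hclust")
}

#' Write a ward_hca tree as Newick text
#' @param x a [ward_hca()] result
#' @param path optional file path; when NULL the Newick string is returned
#' @return the Newick string, invisibly when written to file
#' @export
hca_newick <- function(x, path = NULL) {
  phy <- ape::as.phylo(as.hclust(x))
  s <- ape::write.tree(phy)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
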