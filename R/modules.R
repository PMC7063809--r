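#' Topological-overlap dissimilarity
#'
#' \eqn{d_{ij} = 1 - TOM_{ij}}, with zero diagonal; the standard clustering
#' input for co-expression module detection.
#'
#' @param tom TOM matrix.
#' @return dissimilarity matrix.
#' @export
tom_dissimilarity <- function(tom) {
  d <- 1 - tom
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering of a dissimilarity matrix
#'
#' @param diss square symmetric dissimilarity matrix.
#' @param linkage agglomeration method (default \code{"average"}).
#' @return an \code{\link[stats]{hclust}} tree.
#' @export
hierarchical_cluster <- function(diss, linkage = "average") {
  if (!is.matrix(diss) || nrow(diss) != ncol(diss))
    stop("input error: dissimilarity must be a square matrix")
  stats::hclust(stats::as.dist(diss), method = linkage)
}

## Leaf sets for every internal node of an hclust merge matrix.
node_leaves <- function(merge) {
  n_nodes <- nrow(merge)
  leaves <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    pick <- function(x) if (x < 0) -x else leaves[[x]]
    leaves[[i]] <- c(pick(merge[i, 1]), pick(merge[i, 2]))
  }
  leaves
}

#' Adaptive (dynamic) cut of a co-expression dendrogram
#'
#' A dynamic hybrid-style tree cut in four stages:
#' \enumerate{
#'   \item \emph{Adaptive ceiling}: branches are only considered below
#'     \code{cut_height_frac} times the tree's maximum joining height.
#'     On a topological-overlap dendrogram the merges among
#'     unconnected background genes crowd directly under the maximum, so
#'     this data-driven ceiling strips them into the unassigned pool while
#'     leaving genuinely cohesive branches intact.
#'   \item \emph{Branch decomposition}: each branch under the ceiling is
#'     split top-down; a node is split whenever both sub-branches carry at
#'     least \code{min_module_size} leaves, and sub-branches below that size
#'     are peeled into the pool, so candidates are maximal tight branches.
#'     (The decomposition deliberately over-splits; fragments of one true
#'     module are reunited downstream by \code{\link{merge_close_modules}},
#'     whose eigengenes correlate almost perfectly.)
#'   \item \emph{Cohesion backstop}: a candidate survives only if its mean
#'     within-branch topological overlap is at least \code{tightness} times
#'     the overlap implied by the ceiling itself (\eqn{1 -} ceiling height);
#'     this dissolves the rare chance agglomerate that slipped under the
#'     ceiling.
#'   \item \emph{PAM-like assignment}: membership is then iterated to
#'     convergence in the manner of partitioning around medoids: every gene
#'     (pooled or already clustered) is assigned to the cluster whose mean
#'     overlap with it, relative to that cluster's own mean internal overlap,
#'     is largest — provided the relative overlap reaches
#'     \code{pam_cohesion}; otherwise the gene is unassigned (label 0).
#'     Cluster cohesions are refreshed between iterations.
#' }
#' Clusters that end up below \code{min_module_size} dissolve to label 0.
#'
#' @param dend an \code{hclust} tree from \code{\link{hierarchical_cluster}}.
#' @param diss the TOM dissimilarity the tree was built from.
#' @param min_module_size smallest allowed module (default 10).
#' @param cut_height_frac ceiling as a fraction of the maximum joining
#'   height (default 0.995; smaller is more aggressive at discarding loose
#'   genes).
#' @param tightness within-overlap multiple of the ceiling overlap required
#'   to keep a candidate branch (default 2).
#' @param pam_cohesion fraction of a cluster's internal overlap a gene must
#'   reach to be (re)assigned to it (default 0.35).
#' @param pam_iterations assignment/cohesion refresh rounds (default 3).
#' @return integer label vector (0 = unassigned), named by gene ID.
#' @export
cut_tree_dynamic <- function(dend, diss, min_module_size = 10L,
                             cut_height_frac = 0.995, tightness = 2,
                             pam_cohesion = 0.35, pam_iterations = 3L) {
  if (min_module_size < 2) stop("input error: min_module_size must be >= 2")
  n <- nrow(diss)
  ids <- rownames(diss)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1) return(stats::setNames(0L, ids))
  if (min_module_size > n) {
    warning("min_module_size exceeds the number of genes; all unassigned")
    return(stats::setNames(rep(0L, n), ids))
  }
  tom <- 1 - diss
  diag(tom) <- 0

  ceiling_h <- cut_height_frac * max(dend$height)
  base <- stats::cutree(dend, h = ceiling_h)
  leaves <- node_leaves(dend$merge)
  clusters <- list()
  pool <- integer(0)

  for (cl_id in unique(base)) {
    memb <- which(base == cl_id)
    if (length(memb) < min_module_size) { pool <- c(pool, memb); next }
    ## top-down decomposition of this branch: split while both sides are
    ## large enough, peeling small side-branches into the pool
    root <- which(vapply(leaves, function(lv)
      length(lv) == length(memb) && all(sort(lv) == sort(memb)), NA))[1]
    stack <- root
    while (length(stack) > 0) {
      node <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (node < 0) { pool <- c(pool, -node); next }
      kids <- dend$merge[node, ]
      sz <- vapply(kids, function(x) if (x < 0) 1L else length(leaves[[x]]),
                   integer(1))
      if (all(sz >= min_module_size)) {
        stack <- c(stack, kids)
      } else if (any(sz >= min_module_size)) {
        big <- kids[which.max(sz)]
        small <- kids[which.min(sz)]
        pool <- c(pool, if (small < 0) -small else leaves[[small]])
        stack <- c(stack, big)
      } else {
        lv <- leaves[[node]]
        if (length(lv) >= min_module_size)
          clusters[[length(clusters) + 1]] <- lv
        else pool <- c(pool, lv)
      }
    }
  }

  ## cohesion backstop: candidates must be tighter than the ceiling implies
  min_overlap <- tightness * (1 - ceiling_h)
  keep <- vapply(clusters, function(cl) {
    mean(tom[cl, cl][upper.tri(diag(length(cl)))]) >= min_overlap
  }, NA)
  pool <- c(pool, unlist(clusters[!keep]))
  clusters <- clusters[keep]

  labels <- stats::setNames(rep(0L, n), ids)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i

  ## iterated PAM-like assignment of every gene, gated by cluster cohesion
  if (length(clusters) > 0) {
    for (iter in seq_len(pam_iterations)) {
      mods <- sort(unique(labels[labels > 0]))
      if (length(mods) == 0) break
      member <- lapply(mods, function(m) which(labels == m))
      cohesion <- vapply(member, function(cl)
        mean(tom[cl, cl][upper.tri(diag(length(cl)))]), 0)
      ## mean overlap of every gene with every cluster (self excluded)
      mean_to <- sapply(seq_along(mods), function(j) {
        cl <- member[[j]]
        s <- rowSums(tom[, cl, drop = FALSE])
        sz <- rep(length(cl), n)
        s[cl] <- s[cl]            # tom diagonal is zero, self adds nothing
        sz[cl] <- sz[cl] - 1
        s / sz
      })
      ratio <- sweep(mean_to, 2, pmax(cohesion, .Machine$double.eps), "/")
      best <- max.col(ratio, ties.method = "first")
      bv <- ratio[cbind(seq_len(n), best)]
      new_labels <- ifelse(bv >= pam_cohesion, mods[best], 0L)
      names(new_labels) <- ids
      ## drop clusters that fell below the size floor before the next round
      tab <- table(new_labels[new_labels > 0])
      for (lab in names(tab)[tab < min_module_size])
        new_labels[new_labels == as.integer(lab)] <- 0L
      if (all(new_labels == labels)) { labels <- new_labels; break }
      labels <- new_labels
    }
  }
  relabel_by_size(labels)
}

#' Static single-height cut (fallback)
#'
#' Cuts the tree at a fixed height and dissolves clusters below the size
#' floor; a simple alternative when the adaptive cut is not wanted.
#'
#' @param dend an \code{hclust} tree.
#' @param cut_height dissimilarity height at which to cut.
#' @param min_module_size smallest allowed module.
#' @return integer label vector (0 = unassigned), named by gene ID.
#' @export
cut_tree_static <- function(dend, cut_height, min_module_size = 10L) {
  cl <- stats::cutree(dend, h = cut_height)
  tab <- table(cl)
  labels <- ifelse(tab[as.character(cl)] >= min_module_size, cl, 0L)
  labels <- stats::setNames(as.integer(labels), dend$labels)
  relabel_by_size(labels)
}

## renumber modules 1..K by decreasing size (ties: previous label order)
relabel_by_size <- function(labels) {
  tab <- table(labels[labels > 0])
  if (length(tab) == 0) return(labels)
  ord <- names(tab)[order(-as.numeric(tab), as.numeric(names(tab)))]
  out <- labels
  for (i in seq_along(ord)) out[labels == as.integer(ord[i])] <- i
  out
}

#' Merge modules with closely correlated eigengenes
#'
#' Computes one eigengene per module, clusters the eigengenes by
#' \eqn{1 - cor} (average linkage), merges every group of modules joined
#' below \code{merge_cut_height}, and iterates until no pair of eigengenes
#' has dissimilarity below the threshold. Labels are then renumbered by
#' decreasing size and given standard module colors.
#'
#' @param expr gene x sample matrix covering the labeled genes.
#' @param labels integer labels (0 = unassigned), named by gene ID.
#' @param merge_cut_height eigengene dissimilarity threshold (default 0.25,
#'   i.e. modules correlated above 0.75 are fused).
#' @param max_iter safety bound on merge iterations.
#' @return a \code{module_partition}.
#' @export
merge_close_modules <- function(expr, labels, merge_cut_height = 0.25,
                                max_iter = 20L) {
  if (merge_cut_height <= 0 || merge_cut_height >= 1)
    stop("input error: merge_cut_height must be in (0,1)")
  labels <- labels[rownames(expr)]
  for (iter in seq_len(max_iter)) {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    eig <- sapply(mods, function(m)
      module_eigengene(expr, names(labels)[labels == m])$eigengene)
    ec <- stats::cor(eig)
    d <- 1 - ec
    if (all(d[upper.tri(d)] >= merge_cut_height)) break
    tree <- stats::hclust(stats::as.dist(d), method = "average")
    groups <- stats::cutree(tree, h = merge_cut_height)
    new <- labels
    for (g in unique(groups)) {
      members <- mods[groups == g]
      new[labels %in% members] <- min(members)
    }
    labels <- new
  }
  labels <- relabel_by_size(labels)
  module_partition(labels)
}

#' Standard module color sequence
#'
#' The conventional size-ranked module palette: the largest module is
#' turquoise, then blue, brown, yellow, ...; unassigned genes are grey.
#' @return character vector of color names.
#' @export
module_colors <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
}

#' Map size-ranked module labels to color names
#'
#' Modules sorted by decreasing size receive the standard color sequence;
#' label 0 is always "grey"; labels beyond the palette get numbered
#' fallback names.
#'
#' @param labels integer label vector (0 = unassigned).
#' @return named character vector mapping label -> color (including "0").
#' @export
assign_colors <- function(labels) {
  labels <- relabel_by_size(labels)
  mods <- sort(unique(labels[labels > 0]))
  pal <- module_colors()
  cols <- vapply(seq_along(mods), function(i)
    if (i <= length(pal)) pal[i] else paste0("module", i), "")
  stats::setNames(c("grey", cols), c("0", as.character(mods)))
}

#' Module partition object
#'
#' @param labels integer labels named by gene ID (0 = unassigned).
#' @return list of class \code{module_partition} with \code{labels},
#'   \code{colors} (per gene), \code{color_map} and \code{sizes}.
#' @export
module_partition <- function(labels) {
  labels <- relabel_by_size(labels)
  cmap <- assign_colors(labels)
  sizes <- table(factor(labels[labels > 0]))
  structure(list(
    labels = labels,
    colors = stats::setNames(unname(cmap[as.character(labels)]), names(labels)),
    color_map = cmap,
    sizes = stats::setNames(as.integer(sizes), cmap[names(sizes)])
  ), class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", length(x$sizes), "modules over",
      length(x$labels), "genes;", sum(x$labels == 0), "unassigned (grey)\n")
  if (length(x$sizes) > 0) print(x$sizes)
  invisible(x)
}

#' Detect co-expression modules from a TOM
#'
#' Convenience wrapper chaining dissimilarity, average-linkage clustering,
#' the adaptive tree cut and eigengene merging.
#'
#' @param expr gene x sample matrix (needed for eigengene merging).
#' @param tom TOM matrix for the same genes.
#' @param min_module_size,merge_cut_height,cut_height_frac,tightness,pam_cohesion
#'   passed to the respective steps.
#' @return a \code{module_partition}.
#' @export
detect_modules <- function(expr, tom, min_module_size = 10L,
                           merge_cut_height = 0.25,
                           cut_height_frac = 0.995, tightness = 2,
                           pam_cohesion = 0.35) {
  d <- tom_dissimilarity(tom)
  dend <- hierarchical_cluster(d)
  labels <- cut_tree_dynamic(dend, d, min_module_size = min_module_size,
                             cut_height_frac = cut_height_frac,
                             tightness = tightness,
                             pam_cohesion = pam_cohesion)
  merge_close_modules(expr, labels, merge_cut_height = merge_cut_height)
}
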