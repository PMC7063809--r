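#' TOM quantile connection cutoff
#'
#' Empirical q-quantile (linear interpolation) of the upper-triangle
#' off-diagonal TOM entries; two genes count as connected when their overlap
#' exceeds this threshold. The unit diagonal is excluded so it cannot bias
#' the quantile upward.
#'
#' @param tom TOM matrix.
#' @param q quantile level in (0,1) (default 0.95).
#' @return the threshold (scalar).
#' @export
tom_quantile_cutoff <- function(tom, q = 0.95) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1)
    stop("input error: q must lie strictly in (0,1), got ", q)
  vals <- tom[upper.tri(tom)]
  if (length(vals) == 0) stop("input error: TOM has no off-diagonal entries")
  unname(stats::quantile(vals, probs = q, type = 7))
}

#' Intramodular connectivity under a TOM threshold
#'
#' Gene i is connected to gene j when \eqn{TOM_{ij} >} threshold (strict)
#' and both genes carry the same non-grey module label; the connectivity of
#' a gene is its number of such within-module connections. Grey (label 0)
#' genes are excluded.
#'
#' @param tom TOM matrix.
#' @param partition a \code{\link{module_partition}} covering the TOM genes.
#' @param threshold connection cutoff, normally from
#'   \code{\link{tom_quantile_cutoff}}.
#' @return data.frame with columns module (color), gene_id, connectivity,
#'   plus attributes \code{threshold}.
#' @export
intramodular_connectivity <- function(tom, partition, threshold) {
  labels <- partition$labels[rownames(tom)]
  if (anyNA(labels))
    stop("input error: partition does not cover all TOM genes")
  rows <- list()
  for (m in sort(unique(labels[labels > 0]))) {
    genes <- names(labels)[labels == m]
    sub <- tom[genes, genes, drop = FALSE] > threshold
    diag(sub) <- FALSE
    rows[[length(rows) + 1]] <- data.frame(
      module = unname(partition$color_map[as.character(m)]),
      gene_id = genes,
      connectivity = as.integer(rowSums(sub)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(module = character(0), gene_id = character(0),
                      connectivity = integer(0))
  attr(out, "threshold") <- threshold
  out
}

#' Identify hub genes by top intramodular connectivity
#'
#' Per module, ranks genes by connectivity (descending; ties broken by gene
#' ID) and flags the top \code{ceiling(top_fraction * module_size)} as hubs,
#' so every module at least the minimum size contributes at least one hub.
#' When ties at the boundary make the hub set ambiguous, the tie is flagged.
#'
#' @param counts data.frame from \code{\link{intramodular_connectivity}}.
#' @param top_fraction fraction of each module flagged (default 0.10).
#' @param pooled if TRUE, rank all candidate-module genes in one pool
#'   instead of per module.
#' @return the input data.frame with added columns is_hub and tie_at_cutoff,
#'   ordered by module then decreasing connectivity.
#' @export
identify_hubs <- function(counts, top_fraction = 0.10, pooled = FALSE) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("input error: top_fraction must lie in (0,1]")
  counts$is_hub <- FALSE
  counts$tie_at_cutoff <- FALSE
  groups <- if (pooled) list(seq_len(nrow(counts)))
            else split(seq_len(nrow(counts)), counts$module)
  for (idx in groups) {
    if (length(idx) == 0) next
    ord <- idx[order(-counts$connectivity[idx], counts$gene_id[idx],
                     method = "radix")]
    n_hub <- ceiling(top_fraction * length(idx))
    hubs <- ord[seq_len(n_hub)]
    counts$is_hub[hubs] <- TRUE
    if (n_hub < length(idx) &&
        counts$connectivity[ord[n_hub]] == counts$connectivity[ord[n_hub + 1]])
      counts$tie_at_cutoff[c(hubs, ord[n_hub + 1])] <- TRUE
  }
  ord <- order(counts$module, -counts$connectivity, counts$gene_id,
               method = "radix")
  counts[ord, , drop = FALSE]
}

#' Full hub-gene analysis
#'
#' Chains the TOM quantile cutoff, intramodular connectivity and top-fraction
#' hub selection.
#'
#' @param tom TOM matrix.
#' @param partition a \code{\link{module_partition}}.
#' @param quantile_level TOM quantile for the connection cutoff.
#' @param top_fraction hub fraction per module.
#' @return data.frame with module, gene_id, connectivity, is_hub,
#'   tie_at_cutoff, threshold, quantile.
#' @export
hub_analysis <- function(tom, partition, quantile_level = 0.95,
                         top_fraction = 0.10) {
  thr <- tom_quantile_cutoff(tom, q = quantile_level)
  counts <- intramodular_connectivity(tom, partition, thr)
  res <- identify_hubs(counts, top_fraction = top_fraction)
  res$threshold <- thr
  res$quantile <- quantile_level
  res
}
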