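## Community-ecology metrics and comparisons.
##
## Standard descriptors of cultivated communities: richness, Shannon
## diversity (natural log), richness restricted to taxa rare in stool,
## rank-abundance curves, <1% -> >1% amplification calls, Bray-Curtis
## dissimilarity with average-linkage clustering, and distribution tests.
## The diversity, distance and test computations delegate to vegan / stats;
## this module fixes the conventions (cutoffs, tie-breaks, natural log).

#' Richness, Shannon diversity and rare-taxon richness
#'
#' @param counts Non-negative count (or abundance) vector for the sample.
#' @param stool_counts Reference stool counts over the same ASVs; used only
#'   for `r_low`.
#' @param cutoff Stool-abundance cutoff defining "rare" (default 1%).
#' @return A list with `richness` (detected ASVs), `shannon` (H', nats) and
#'   `r_low` (detected ASVs whose stool abundance is below the cutoff).
#' @export
community_metrics <- function(counts, stool_counts, cutoff = 0.01) {
  if (all(counts == 0)) stop_invalid("all-zero sample column")
  if (length(counts) != length(stool_counts)) {
    stop_invalid("sample and stool columns must share the ASV index")
  }
  p <- props(counts)
  q <- props(stool_counts)
  list(
    richness = sum(p > 0),
    shannon = unname(vegan::diversity(counts, index = "shannon")),
    r_low = sum(p > 0 & q < cutoff)
  )
}

#' Rank-abundance curve
#'
#' Orders proportional abundances by decreasing value; ties broken by ASV
#' id (lexicographic) so the curve is deterministic.
#'
#' @param profile Named proportional-abundance (or count) vector.
#' @return Data frame with columns `rank`, `asv_id`, `proportion`.
#' @export
rank_abundance <- function(profile) {
  p <- props(profile)
  ids <- names(p) %||% as.character(seq_along(p))
  ord <- order(-p, ids)
  data.frame(
    rank = seq_along(p),
    asv_id = ids[ord],
    proportion = unname(p[ord]),
    stringsAsFactors = FALSE
  )
}

#' Amplification calls for taxa rare in stool
#'
#' An ASV below the stool-abundance cutoff is called amplified when its
#' relative abundance in the cultured/sorted sample exceeds the cutoff
#' (default 1% on both sides).
#'
#' @param stool_counts,sample_counts Count vectors sharing the ASV index.
#' @param cutoff Relative-abundance cutoff (default 0.01).
#' @return Data frame with one row per candidate ASV (stool abundance below
#'   the cutoff): `asv_id`, `stool_prop`, `sample_prop`, `ratio`
#'   (`Inf` when absent from stool), `amplified`.
#' @export
amplified_asvs <- function(stool_counts, sample_counts, cutoff = 0.01) {
  if (length(stool_counts) != length(sample_counts)) {
    stop_invalid("sample and stool columns must share the ASV index")
  }
  q <- props(stool_counts)
  p <- props(sample_counts)
  ids <- names(q) %||% as.character(seq_along(q))
  cand <- which(q < cutoff)
  data.frame(
    asv_id = ids[cand],
    stool_prop = unname(q[cand]),
    sample_prop = unname(p[cand]),
    ratio = unname(ifelse(q[cand] > 0, p[cand] / q[cand], Inf)),
    amplified = unname(p[cand] > cutoff),
    stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' `1 - sum_i min(a_i, b_i)` on proportion-normalized profiles; 0 for
#' identical communities, 1 for disjoint supports.
#'
#' @param a,b Count or proportion vectors over the same ASVs.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("profiles must share the ASV index")
  1 - sum(pmin(props(a), props(b)))
}

#' Hierarchical clustering of samples on Bray-Curtis distances
#'
#' Proportion-normalizes each sample, computes the Bray-Curtis distance
#' matrix (via `vegan::vegdist`) and clusters agglomeratively
#' (average linkage / UPGMA by default).
#'
#' @param table ASV count matrix, rows = ASVs, columns = samples (as read
#'   by [read_asv_table()]).
#' @param method Linkage passed to [stats::hclust()].
#' @return An `hclust` object.
#' @export
cluster_samples <- function(table, method = "average") {
  if (ncol(table) < 2) stop_invalid("clustering needs at least 2 samples")
  prop <- apply(table, 2, props)
  d <- vegan::vegdist(t(prop), method = "bray")
  stats::hclust(d, method = method)
}

#' Serialize a dendrogram as Newick
#'
#' @param hc An `hclust` from [cluster_samples()].
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_dendrogram <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Two-sample Kolmogorov-Smirnov comparison of abundance curves
#'
#' Thin wrapper over [stats::ks.test()] on the value distributions of two
#' rank-abundance curves (plumbing, not a novel statistic).
#'
#' @param a,b Numeric vectors (e.g. the `proportion` columns of two
#'   [rank_abundance()] curves).
#' @return List with `statistic` and `p_value`.
#' @export
compare_distributions <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop_invalid("curves must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Mann-Whitney U comparison of a metric across two groups
#'
#' Thin wrapper over [stats::wilcox.test()] (plumbing, not a novel
#' statistic).
#'
#' @param x,y Metric values for the two groups.
#' @return List with `statistic` and `p_value`.
#' @export
compare_groups <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(wt$statistic), p_value = unname(wt$p.value))
}
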