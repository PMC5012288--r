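#' Bray-Curtis dissimilarity
#'
#' `BC(p, q) = sum |p_i - q_i| / sum (p_i + q_i)` over a shared species
#' universe (species absent from one profile count as 0). Bounded in
#' \[0, 1\] for non-negative data.
#'
#' @param p,q named numeric vectors of non-negative abundances.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(a = 60, b = 40), c(a = 40, b = 40, c = 20)) # 0.2
#' @export
bray_curtis <- function(p, q) {
  species <- union(names(p), names(q))
  if (is.null(species)) {
    if (length(p) != length(q)) stopf("unnamed profiles must be same length")
    pp <- p; qq <- q
  } else {
    pp <- stats::setNames(rep(0, length(species)), species)
    qq <- pp
    pp[names(p)] <- p
    qq[names(q)] <- q
  }
  if (any(c(pp, qq) < 0)) stopf("abundances must be non-negative")
  tot <- sum(pp + qq)
  if (tot == 0) stopf("both profiles are all-zero")
  sum(abs(pp - qq)) / tot
}

#' Bray-Curtis dissimilarity matrix over a profile matrix
#'
#' @param profiles strains x species non-negative matrix.
#' @return A `dist` object (via [vegan::vegdist()]).
#' @export
bray_curtis_matrix <- function(profiles) {
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("strain", seq_len(nrow(profiles)))
  vegan::vegdist(profiles, method = "bray")
}

#' UPGMA (average-linkage) dendrogram
#'
#' Agglomerates the closest pair at each step; the distance from a merged
#' cluster to any other is the size-weighted arithmetic mean of the member
#' distances, and the merge height is the merging pair's dissimilarity.
#' Labels are sorted before clustering so that exact ties resolve by
#' lexicographic label order.
#'
#' @param d a `dist` object or symmetric matrix with labels.
#' @return An `hclust` object.
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 2) stopf("need at least 2 items")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("item", seq_len(nrow(m)))
  }
  if (max(abs(m - t(m))) > 1e-12) stopf("matrix must be symmetric")
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(m), method = "average")
}

#' Cophenetic correlation of a dendrogram against its source distances
#'
#' Pearson correlation between the original pairwise dissimilarities and
#' the cophenetic distances (heights at which pairs first merge). Values
#' near 1 indicate the dendrogram faithfully preserves the distances.
#'
#' @param hc an `hclust` object (e.g. from [upgma()]).
#' @param d the `dist` object or matrix the dendrogram was built from.
#' @return Pearson correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(hc, d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stopf("cophenetic correlation needs at least 3 items")
  cm <- as.matrix(stats::cophenetic(hc))
  labs <- rownames(cm)
  m <- m[labs, labs]
  lower <- lower.tri(m)
  stats::cor(m[lower], cm[lower])
}

#' Bootstrap support for dendrogram nodes by species resampling
#'
#' Resamples fatty-acid species (columns of the profile matrix) with
#' replacement `B` times, rebuilds the Bray-Curtis UPGMA dendrogram for
#' each replicate, and scores every internal node of the original
#' dendrogram by the percentage of replicates containing the same leaf
#' set.
#'
#' @param profiles strains x species non-negative matrix (>= 3 strains,
#'   >= 2 species).
#' @param B number of bootstrap replicates; `B = 0` returns the dendrogram
#'   without supports.
#' @param seed integer seed for the resampling stream.
#' @return The `hclust` dendrogram of the original matrix with an extra
#'   element `node_support`: a data.frame mapping each internal node's leaf
#'   set (`members`, comma-separated sorted labels) and merge `height` to
#'   its `support` in \[0, 100\] (`NA` when `B = 0`).
#' @export
bootstrap_support <- function(profiles, B = 1000, seed = 1) {
  if (nrow(profiles) < 3) stopf("need at least 3 profiles")
  if (ncol(profiles) < 2)
    stopf("bootstrap over species requires at least 2 species")
  hc <- upgma(bray_curtis_matrix(profiles))
  clades <- hclust_clades(hc)
  keys <- vapply(clades$members, paste, character(1), collapse = ",")
  support <- rep(NA_real_, length(keys))
  if (B > 0) {
    counts <- stats::setNames(rep(0, length(keys)), keys)
    with_seed(seed, {
      for (b in seq_len(B)) {
        cols <- sample.int(ncol(profiles), replace = TRUE)
        bp <- profiles[, cols, drop = FALSE]
        keep <- rowSums(bp) > 0
        if (sum(keep) < 2) next
        hb <- upgma(bray_curtis_matrix(bp[keep, , drop = FALSE]))
        kb <- vapply(hclust_clades(hb)$members, paste, character(1),
                     collapse = ",")
        hit <- keys %in% kb
        counts[hit] <- counts[hit] + 1
      }
    })
    support <- 100 * unname(counts) / B
  }
  hc$node_support <- data.frame(members = keys, height = clades$height,
                                support = support,
                                stringsAsFactors = FALSE)
  hc
}

# Leaf sets under every internal node of an hclust tree, labels sorted.
hclust_clades <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    mem <- unlist(lapply(kids, function(x) {
      if (x < 0) hc$labels[-x] else members[[x]]
    }))
    members[[k]] <- sort(mem)
  }
  list(members = members, height = hc$height)
}

#' Write a dendrogram as Newick with heights as branch lengths
#'
#' @param hc an `hclust` object.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
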