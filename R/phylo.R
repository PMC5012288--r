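#' Read an aligned FASTA file
#'
#' @param path FASTA file of equal-length nucleotide sequences.
#' @return Character matrix (taxa in rows, columns are alignment sites,
#'   uppercase over A, C, G, T, -, N).
#' @export
read_alignment_fasta <- function(path) {
  seqs <- ape::read.FASTA(path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stopf("%s: sequences are not aligned (lengths %s)", path,
          paste(sort(unique(lens)), collapse = ", "))
  m <- toupper(as.character(as.matrix(seqs)))
  rownames(m) <- names(seqs)
  m
}

#' Write an alignment matrix as FASTA
#'
#' @param aln character matrix (taxa x sites).
#' @param path output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  }
  invisible(path)
}

aln_to_dnabin <- function(aln) {
  ape::as.DNAbin(matrix(tolower(aln), nrow = nrow(aln),
                        dimnames = dimnames(aln)))
}

#' Filter sequences by ungapped length
#'
#' Retains sequences whose ungapped length is strictly greater than
#' `min_bp`; gap characters do not count towards the length.
#'
#' @param aln character matrix (taxa x sites).
#' @param min_bp length threshold in bases (default 400).
#' @return The retained sub-alignment; excluded taxa are reported in a
#'   message and in attribute `excluded`.
#' @export
length_filter <- function(aln, min_bp = 400) {
  ungapped <- apply(aln, 1, function(s) sum(s != "-"))
  keep <- ungapped > min_bp
  if (!all(keep))
    message("length_filter: excluding ",
            paste(rownames(aln)[!keep], collapse = ", "),
            " (ungapped length <= ", min_bp, ")")
  if (!any(keep)) warning("length_filter retained no sequences",
                          call. = FALSE)
  out <- aln[keep, , drop = FALSE]
  attr(out, "excluded") <- rownames(aln)[!keep]
  out
}

#' Block-based alignment cleaning
#'
#' Removes ambiguous alignment regions before distance computation, using
#' the classic block-filtering procedure: (1) each column is classified as
#' a gap column (any gap, when `allow_gap_columns = FALSE`), conserved
#' (modal residue frequency strictly above `conserved_fraction`) or
#' flank-conserved (at least `flank_fraction`); (2) gap columns are
#' dropped; (3) runs of more than `max_contiguous_nonconserved`
#' consecutive non-conserved columns are rejected; (4) the surviving
#' blocks are trimmed so they start and end on flank-conserved columns;
#' (5) blocks shorter than `min_block_length` are discarded and the rest
#' concatenated.
#'
#' @param aln character matrix (taxa x sites).
#' @param min_block_length minimum retained block length (default 10).
#' @param allow_gap_columns keep columns containing gaps (default FALSE).
#' @param max_contiguous_nonconserved longest tolerated run of
#'   non-conserved columns (default 8).
#' @param flank_fraction minimum modal-residue fraction for block
#'   boundaries (default 0.85).
#' @param conserved_fraction strictly-exceeded modal-residue fraction for
#'   a conserved column (default 0.5).
#' @return List with `alignment` (cleaned matrix, possibly 0 columns) and
#'   `kept_columns` (original column indices, increasing).
#' @export
clean_alignment <- function(aln, min_block_length = 10,
                            allow_gap_columns = FALSE,
                            max_contiguous_nonconserved = 8,
                            flank_fraction = 0.85,
                            conserved_fraction = 0.5) {
  if (flank_fraction < conserved_fraction)
    stopf("flank_fraction must be >= conserved_fraction")
  n <- nrow(aln)
  ncols <- ncol(aln)
  if (ncols == 0L)
    return(list(alignment = aln, kept_columns = integer(0)))
  modal_frac <- apply(aln, 2, function(col) {
    res <- col[col %in% c("A", "C", "G", "T")]
    if (length(res) == 0) 0 else max(table(res)) / n
  })
  has_gap <- apply(aln, 2, function(col) any(col == "-"))
  conserved <- modal_frac > conserved_fraction
  flank <- modal_frac >= flank_fraction

  keep <- if (allow_gap_columns) seq_len(ncols) else which(!has_gap)
  if (length(keep) == 0L)
    return(empty_clean(aln))

  # reject long non-conserved runs; runs are counted in original
  # coordinates, so removed gap columns break a run
  adjacent <- c(FALSE, diff(keep) == 1)
  state <- conserved[keep]
  run_id <- cumsum(!adjacent | c(FALSE, state[-1] != state[-length(state)]))
  survivors <- rep(TRUE, length(keep))
  for (rid in unique(run_id)) {
    idx <- which(run_id == rid)
    if (!state[idx[1]] && length(idx) > max_contiguous_nonconserved)
      survivors[idx] <- FALSE
  }
  # blocks: maximal surviving stretches contiguous in the original
  # alignment (gap-column and run removals both end a block)
  surv_cols <- keep[survivors]
  if (length(surv_cols) == 0L) {
    warning("clean_alignment: no columns survived filtering", call. = FALSE)
    return(empty_clean(aln))
  }
  block_id <- cumsum(c(1, diff(surv_cols) > 1))
  kept_blocks <- split(surv_cols, block_id)

  final <- integer(0)
  for (blk in kept_blocks) {
    fl <- flank[blk]
    first <- which(fl)[1]
    last <- if (any(fl)) max(which(fl)) else NA
    if (is.na(first)) next
    blk <- blk[first:last]
    if (length(blk) >= min_block_length) final <- c(final, blk)
  }
  if (length(final) == 0L) {
    warning("clean_alignment: no columns survived filtering", call. = FALSE)
    return(empty_clean(aln))
  }
  list(alignment = aln[, final, drop = FALSE], kept_columns = final)
}

empty_clean <- function(aln) {
  list(alignment = aln[, integer(0), drop = FALSE],
       kept_columns = integer(0))
}

#' Pairwise distances from an alignment
#'
#' p-distance (proportion of mismatched sites, gaps and ambiguities
#' deleted pairwise) or its Jukes-Cantor correction
#' `d = -(3/4) ln(1 - 4p/3)`. Pairs with `p >= 0.75` have no JC69
#' distance and are returned as `NaN` with a warning.
#'
#' @param aln character matrix (taxa x sites), >= 2 taxa.
#' @param model `"p_distance"` or `"jc69"`.
#' @return A `dist` object.
#' @export
pairwise_distance <- function(aln, model = c("p_distance", "jc69")) {
  model <- match.arg(model)
  if (nrow(aln) < 2) stopf("need at least 2 taxa")
  dna <- aln_to_dnabin(aln)
  p <- ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE)
  if (model == "p_distance") return(p)
  if (any(p >= 0.75))
    warning("jc69 distance undefined for pair(s) with p >= 0.75; returning NaN",
            call. = FALSE)
  d <- p
  d[] <- ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NaN)
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix; exact on additive
#' distances. Negative branch lengths (possible on noisy data) are set to
#' zero with the deficit transferred to the sister branch, preserving
#' tip-to-tip path lengths through the parent node.
#'
#' @param d `dist` object or symmetric matrix, >= 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stopf("need at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-9) stopf("distance matrix must be symmetric")
  if (any(!is.finite(m))) stopf("distance matrix contains non-finite entries")
  tree <- ape::nj(stats::as.dist(m))
  clamp_negative_branches(tree)
}

clamp_negative_branches <- function(tree) {
  neg <- which(tree$edge.length < 0)
  if (length(neg)) {
    message("neighbor_joining: clamping ", length(neg),
            " negative branch length(s) to 0")
    for (e in neg) {
      parent <- tree$edge[e, 1]
      sib <- which(tree$edge[, 1] == parent & seq_len(nrow(tree$edge)) != e)
      if (length(sib)) {
        sib <- sib[1]
        tree$edge.length[sib] <- tree$edge.length[sib] + tree$edge.length[e]
      }
      tree$edge.length[e] <- 0
    }
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the
#' NJ tree from each replicate, and labels every internal branch of the
#' original tree with the percentage of replicates containing the same
#' bipartition.
#'
#' @param aln character matrix (taxa x sites), ideally already cleaned.
#' @param B number of replicates (default 1000).
#' @param model distance model, as in [pairwise_distance()].
#' @param seed integer seed.
#' @return A `phylo` tree whose `node.label` holds supports in
#'   \[0, 100\] (root label empty).
#' @export
bootstrap_tree <- function(aln, B = 1000, model = "p_distance", seed = 1) {
  if (B < 1) stopf("B must be at least 1")
  tree <- neighbor_joining(pairwise_distance(aln, model = model))
  boots <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(ncol(aln), replace = TRUE)
      neighbor_joining(pairwise_distance(aln[, cols, drop = FALSE],
                                         model = model))
    })
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / B, 1)
  tree$node.label <- as.character(support)
  tree$node.label[1] <- ""  # root of the unrooted representation
  tree
}

#' Demarcate phylotypes by patristic distance
#'
#' Single-linkage clustering of the leaves: two leaves belong to the same
#' phylotype when their patristic distance (sum of branch lengths along
#' the connecting path) is at most `threshold`; transitive closure
#' completes the partition.
#'
#' @param tree a `phylo` tree with branch lengths in substitutions/site.
#' @param threshold patristic-distance threshold (default 0.001).
#' @return Object of class `phylotype_assignment`: list with `assignment`
#'   (named integer vector, taxon -> phylotype id), `n_phylotypes` and
#'   `threshold`.
#' @export
demarcate_phylotypes <- function(tree, threshold = 0.001) {
  pd <- ape::cophenetic.phylo(tree)
  hc <- stats::hclust(stats::as.dist(pd), method = "single")
  assignment <- stats::cutree(hc, h = threshold)
  res <- list(assignment = assignment,
              n_phylotypes = length(unique(assignment)),
              threshold = threshold)
  class(res) <- "phylotype_assignment"
  res
}

#' @export
print.phylotype_assignment <- function(x, ...) {
  cat(sprintf("%d phylotype(s) at patristic threshold %g subs/site\n",
              x$n_phylotypes, x$threshold))
  for (k in sort(unique(x$assignment))) {
    cat(sprintf("  %d: %s\n", k,
                paste(names(x$assignment)[x$assignment == k],
                      collapse = ", ")))
  }
  invisible(x)
}
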