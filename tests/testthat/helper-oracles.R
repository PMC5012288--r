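# Independent oracles used across test files. These deliberately recompute
# everything from first principles and never call the package internals.

# Brute-force UPGMA: clusters kept as leaf-index sets; the distance between
# two clusters is re-averaged over ALL original leaf pairs at every step.
brute_upgma <- function(d) {
  m <- as.matrix(d)
  labs <- rownames(m)
  clusters <- as.list(seq_len(nrow(m)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      avg <- mean(m[clusters[[i]], clusters[[j]]])
      if (is.null(best) || avg < best$avg - 1e-15)
        best <- list(i = i, j = j, avg = avg)
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1]] <- list(
      members = sort(labs[merged]), height = best$avg)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  merges
}

# Cophenetic matrix implied by a brute_upgma merge list.
brute_cophenetic <- function(merges, labs) {
  n <- length(labs)
  cm <- matrix(0, n, n, dimnames = list(labs, labs))
  for (a in seq_len(n - 1)) for (b in seq((a + 1), n)) {
    h <- Inf
    for (mg in merges) {
      if (all(c(labs[a], labs[b]) %in% mg$members)) h <- min(h, mg$height)
    }
    cm[a, b] <- cm[b, a] <- h
  }
  cm
}

# Random additive distance matrix with its generating tree.
random_additive <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
}

# Random ultrametric matrix via coalescent-style tree heights.
random_ultrametric <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rcoal(n)
    ape::cophenetic.phylo(tr)
  })
}

expect_setequal_clades <- function(a, b) {
  key <- function(x) paste(x, collapse = ",")
  expect_setequal(vapply(a, key, ""), vapply(b, key, ""))
}

# Leaf sets under every internal node of an hclust tree (test-side reader).
hclust_clades_test <- function(hc) {
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    mem <- unlist(lapply(kids, function(x) {
      if (x < 0) hc$labels[-x] else members[[x]]$members
    }))
    members[[k]] <- list(members = sort(mem), height = hc$height[k])
  }
  members
}
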