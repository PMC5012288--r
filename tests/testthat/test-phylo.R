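toy_aln <- function(rows) {
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- paste0("t", seq_along(rows))
  m
}

test_that("length filter uses strict ungapped length", {
  base <- paste(rep("A", 450), collapse = "")
  aln <- rbind(
    short = strsplit(paste(c(rep("A", 399), rep("-", 51)), collapse = ""), "")[[1]],
    exact = strsplit(paste(c(rep("A", 400), rep("-", 50)), collapse = ""), "")[[1]],
    long = strsplit(paste(c(rep("A", 401), rep("-", 49)), collapse = ""), "")[[1]],
    gappy = strsplit(paste(c(rep("A", 390), rep("-", 60)), collapse = ""), "")[[1]])
  suppressMessages(kept <- length_filter(aln))
  expect_equal(rownames(kept), "long")
  expect_setequal(attr(kept, "excluded"), c("short", "exact", "gappy"))
  suppressMessages(suppressWarnings(none <- length_filter(aln, min_bp = 500)))
  expect_equal(nrow(none), 0)
})

test_that("alignment cleaning removes gap columns and keeps conserved blocks", {
  # identical gap-free alignment: untouched
  aln <- toy_aln(rep(paste(rep("ACGT", 5), collapse = ""), 4))
  cl <- clean_alignment(aln, min_block_length = 5)
  expect_equal(cl$alignment, aln)
  expect_equal(cl$kept_columns, 1:20)
  # one all-gap column removed, everything else kept
  aln2 <- aln
  aln2[, 7] <- "-"
  cl2 <- clean_alignment(aln2, min_block_length = 5)
  expect_equal(cl2$kept_columns, setdiff(1:20, 7))
  # idempotent and order-preserving
  cl3 <- clean_alignment(cl2$alignment, min_block_length = 5)
  expect_equal(cl3$alignment, cl2$alignment)
  expect_true(all(diff(cl2$kept_columns) > 0))
})

test_that("long non-conserved runs are rejected, short ones kept", {
  # 40 columns, 4 taxa; a run of non-conserved columns in the middle.
  make <- function(run_len) {
    m <- toy_aln(rep(paste(rep("A", 40), collapse = ""), 4))
    # non-conserved: all four residues distinct (modal 1/4 <= 0.5)
    for (j in seq_len(run_len)) m[, 15 + j] <- c("A", "C", "G", "T")
    m
  }
  cl9 <- clean_alignment(make(9))
  expect_false(any(16:24 %in% cl9$kept_columns))  # run of 9 rejected
  cl8 <- clean_alignment(make(8))
  expect_true(all(16:23 %in% cl8$kept_columns))   # run of 8 retained
  expect_equal(cl8$kept_columns, 1:40)
})

test_that("short trimmed blocks are discarded entirely", {
  m <- toy_aln(rep(paste(rep("A", 12), collapse = ""), 4))
  m[, 6] <- "-"  # splits into blocks of 5 and 6 after gap removal
  expect_warning(cl <- clean_alignment(m, min_block_length = 10),
                 "no columns")
  expect_equal(length(cl$kept_columns), 0)
})

test_that("pairwise distances match the p and JC69 formulas", {
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("C", 10), rep("A", 90)), collapse = "")
  aln <- toy_aln(c(s1, s2, s1))
  p <- as.matrix(pairwise_distance(aln, "p_distance"))
  expect_equal(p["t1", "t2"], 0.10)
  expect_equal(p["t1", "t3"], 0)
  jc <- as.matrix(pairwise_distance(aln, "jc69"))
  expect_equal(jc["t1", "t2"], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(jc["t1", "t2"], 0.10732, tolerance = 1e-4)
  # gaps are pairwise-deleted
  aln2 <- aln
  aln2[1, 1:10] <- "-"
  p2 <- as.matrix(pairwise_distance(aln2, "p_distance"))
  expect_equal(p2["t1", "t2"], 0)
  # correction always at least the raw distance; saturation flagged
  withr::with_seed(4, {
    for (i in 1:5) {
      a <- toy_aln(c(paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
                     paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")))
      pr <- as.matrix(pairwise_distance(a, "p_distance"))[1, 2]
      if (pr < 0.75) {
        jcr <- as.matrix(pairwise_distance(a, "jc69"))[1, 2]
        expect_gte(jcr, pr)
      } else {
        expect_warning(pairwise_distance(a, "jc69"), "undefined")
      }
    }
  })
})

test_that("neighbour joining is exact on additive matrices", {
  # hand-built 4-taxon additive matrix from tree ((A:1,B:2):1,(C:3,D:4))
  labs <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  tr <- neighbor_joining(d)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[labs, labs], d,
               tolerance = 1e-10)
  split_ab <- ape::prop.part(tr)
  # AB|CD bipartition present: A,B form a cherry
  pairs <- ape::cophenetic.phylo(tr)
  expect_equal(pairs["A", "B"], 3)
  # 3-taxon closed form
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(d3)
  expect_equal(sort(tr3$edge.length), c(0.5, 1.5, 2.5))
  # random additive 5-7 leaf trees: topology and lengths recovered
  for (n in 5:7) for (seed in c(1, 2)) {
    ra <- random_additive(n, seed = 100 * n + seed)
    tr_n <- neighbor_joining(ra$d)
    expect_equal(phangorn::RF.dist(ape::unroot(tr_n), ape::unroot(ra$tree)), 0)
    labs_n <- rownames(ra$d)
    expect_equal(as.matrix(ape::cophenetic.phylo(tr_n))[labs_n, labs_n],
                 ra$d[labs_n, labs_n], tolerance = 1e-8)
  }
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
})

test_that("NJ matches UPGMA topology on ultrametric matrices", {
  for (seed in c(11, 12)) {
    um <- random_ultrametric(6, seed = seed)
    tr <- neighbor_joining(um)
    hc <- upgma(um)
    hc_tree <- ape::as.phylo(hc)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(hc_tree)), 0)
  }
})

test_that("bootstrap supports separate clean clades and are reproducible", {
  sim <- simulate_alignment(4, 5000, 0.2, seed = 17)
  tr <- bootstrap_tree(sim$alignment, B = 50, seed = 2)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(max(sup, na.rm = TRUE), 99)
  tr2 <- bootstrap_tree(sim$alignment, B = 50, seed = 2)
  expect_identical(tr$node.label, tr2$node.label)
  # B = 1: supports only 0 or 100
  tr1 <- bootstrap_tree(sim$alignment, B = 1, seed = 5)
  s1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))
  expect_error(bootstrap_tree(sim$alignment, B = 0), "at least 1")
})

test_that("phylotype demarcation partitions by patristic threshold", {
  # star tree with all zero branches: a single phylotype
  tr0 <- ape::read.tree(text = "(a:0,b:0,c:0,d:0);")
  p0 <- demarcate_phylotypes(tr0)
  expect_equal(p0$n_phylotypes, 1)
  # strictly positive distances at threshold 0: all singletons
  tr1 <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01);")
  p1 <- demarcate_phylotypes(tr1, threshold = 0)
  expect_equal(p1$n_phylotypes, 4)
  # two tight pairs among distant tips: n - 2 phylotypes
  tr2 <- ape::read.tree(text = paste0(
    "((a:0.00025,b:0.00025):0.02,((c:0.00025,d:0.00025):0.02,",
    "(e:0.05,f:0.05):0.02):0.02);"))
  p2 <- demarcate_phylotypes(tr2, threshold = 0.001)
  expect_equal(p2$n_phylotypes, 4)
  expect_equal(p2$assignment[["a"]], p2$assignment[["b"]])
  expect_equal(p2$assignment[["c"]], p2$assignment[["d"]])
  # partition validity and monotonicity in the threshold
  sim <- simulate_alignment(6, 800, 0.15, phylotype_pairs = 2, seed = 23)
  for (th in c(0, 0.001, 0.01, 1)) {
    p <- demarcate_phylotypes(sim$tree, threshold = th)
    expect_setequal(names(p$assignment), sim$tree$tip.label)
  }
  ns <- vapply(c(0, 0.001, 0.01, 0.1, 1),
               function(th) demarcate_phylotypes(sim$tree, th)$n_phylotypes,
               numeric(1))
  expect_true(all(diff(ns) <= 0))
  # duplicated tips sit below the demarcation threshold
  pd <- demarcate_phylotypes(sim$tree, 0.001)$assignment
  dups <- grep("_dup$", names(pd), value = TRUE)
  for (dp in dups)
    expect_equal(pd[[dp]], pd[[sub("_dup$", "", dp)]])
})

test_that("aligned FASTA round-trips and ragged input is rejected", {
  sim <- simulate_alignment(4, 60, 0.1, gap_column_fraction = 0.05, seed = 3)
  path <- file.path(tempdir(), "aln.fasta")
  write_alignment_fasta(sim$alignment, path)
  back <- read_alignment_fasta(path)
  expect_equal(back, sim$alignment)
  writeLines(c(">a", "ACGT", ">b", "ACGTAC"), path)
  expect_error(read_alignment_fasta(path), "not aligned")
})
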