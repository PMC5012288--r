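#' Simulate a batch-culture growth curve
#'
#' Density follows a lag phase, then logistic growth with intrinsic rate
#' `mu_true` towards `carrying_capacity` (pure exponential when the
#' capacity is infinite), sampled at fixed intervals with multiplicative
#' lognormal noise of the stated coefficient of variation. Noise never
#' drives the density to zero or below.
#'
#' @param mu_true intrinsic specific growth rate, d^-1 (>= 0).
#' @param n0 initial density (> 0; OD units or cells/mL).
#' @param carrying_capacity saturation density (>= `n0`; `Inf` for pure
#'   exponential growth).
#' @param lag_h lag-phase duration in hours (>= 0).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param sample_interval_h sampling interval in hours (default 24).
#' @param duration_h total duration in hours (default 168, i.e. daily
#'   sampling for seven days); at least 3 samples are required.
#' @param seed integer seed; a fixed seed fixes the output exactly.
#' @param strain_id optional label.
#' @return data.frame with columns `strain`, `time_h`, `value`, `measure`
#'   and attribute `truth` (list of the generating parameters).
#' @export
simulate_growth_curve <- function(mu_true, n0, carrying_capacity = Inf,
                                  lag_h = 0, noise_cv = 0,
                                  sample_interval_h = 24, duration_h = 168,
                                  seed = 1, strain_id = "sim") {
  if (mu_true < 0) stopf("mu_true must be non-negative")
  if (n0 <= 0) stopf("n0 must be positive")
  if (carrying_capacity < n0) stopf("carrying_capacity must be >= n0")
  if (lag_h < 0 || noise_cv < 0) stopf("lag_h and noise_cv must be >= 0")
  if (sample_interval_h <= 0) stopf("sample_interval_h must be positive")
  times <- seq(0, duration_h, by = sample_interval_h)
  if (length(times) < 3)
    stopf("duration_h / sample_interval_h must allow at least 3 samples")
  mean_density <- vapply(times, function(t) {
    te <- max(t - lag_h, 0)
    g <- exp(mu_true * te / 24)
    if (is.infinite(carrying_capacity)) n0 * g
    else carrying_capacity * n0 * g /
      (carrying_capacity + n0 * (g - 1))
  }, numeric(1))
  dens <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    with_seed(seed,
      mean_density * stats::rlnorm(length(times), -sdlog^2 / 2, sdlog))
  } else mean_density
  out <- data.frame(strain = strain_id, time_h = times, value = dens,
                    measure = "od550", stringsAsFactors = FALSE)
  attr(out, "truth") <- list(mu_true = mu_true, n0 = n0,
                             carrying_capacity = carrying_capacity,
                             lag_h = lag_h, noise_cv = noise_cv,
                             seed = seed)
  out
}

#' Simulate phylotype-structured FAME profiles
#'
#' Each phylotype draws a base composition from a Dirichlet distribution
#' over the species pool; member strains perturb the base on the log
#' scale with sd `within_phylotype_sd` and are renormalised to 100 wt%.
#' Sub-streams are derived per phylotype and strain, so adding a strain
#' does not reshuffle the others.
#'
#' @param n_phylotypes number of phylotypes (>= 1).
#' @param strains_per_phylotype strains per phylotype (>= 1).
#' @param species_pool character vector of fatty-acid shorthand labels.
#' @param base_concentration Dirichlet concentration (scalar or one value
#'   per species, > 0).
#' @param within_phylotype_sd within-phylotype perturbation scale.
#' @param seed integer seed.
#' @return List with `profiles` (strains x species wt% matrix, rows sum
#'   to 100) and `phylotype` (named integer vector of true labels).
#' @export
simulate_fame_profiles <- function(n_phylotypes, strains_per_phylotype,
                                   species_pool = c("C12:0", "C16:0",
                                                    "C16:4(n-3)", "C18:1",
                                                    "C18:2", "C20:4"),
                                   base_concentration = 0.8,
                                   within_phylotype_sd = 0.1, seed = 1) {
  if (length(species_pool) == 0L) stopf("species_pool must be non-empty")
  if (n_phylotypes < 1 || strains_per_phylotype < 1)
    stopf("need at least one phylotype and one strain per phylotype")
  if (any(base_concentration <= 0))
    stopf("base_concentration must be positive")
  if (within_phylotype_sd < 0) stopf("within_phylotype_sd must be >= 0")
  parse_fatty_acid(species_pool)  # validates labels
  alpha <- rep_len(base_concentration, length(species_pool))
  profiles <- NULL
  labels <- integer(0)
  strain_names <- character(0)
  for (k in seq_len(n_phylotypes)) {
    base <- with_seed(substream_seed(seed, k), {
      g <- stats::rgamma(length(species_pool), shape = alpha)
      g / sum(g)
    })
    for (s in seq_len(strains_per_phylotype)) {
      pert <- if (within_phylotype_sd > 0) {
        with_seed(substream_seed(seed, k * 100000 + s),
                  exp(stats::rnorm(length(base), 0, within_phylotype_sd)))
      } else rep(1, length(base))
      p <- base * pert
      profiles <- rbind(profiles, 100 * p / sum(p))
      labels <- c(labels, k)
      strain_names <- c(strain_names, sprintf("P%02dS%02d", k, s))
    }
  }
  dimnames(profiles) <- list(strain_names, species_pool)
  names(labels) <- strain_names
  list(profiles = profiles, phylotype = labels)
}

#' Simulate a copper dose-response bioassay panel
#'
#' Replicate growth rates are drawn around the log-logistic (Hill) mean
#' `mu(c) = mu0 / (1 + (c/ec50)^hill)` with multiplicative lognormal
#' noise; when the mean rate falls below `growth_floor` the culture is in
#' the zero-growth regime and its fluorescence stays flat. Each
#' replicate's fluorescence series is exponential in its realised rate,
#' sampled at 24-h intervals over the assay window. A control
#' (concentration 0) is always included.
#'
#' @param mu0 control growth rate, d^-1 (> 0).
#' @param ec50 concentration halving the growth rate, mg/L (> 0).
#' @param hill Hill slope (> 0).
#' @param concentrations test concentrations in mg/L, ascending (default
#'   0.01, 0.1, 0.32, 1.0, 3.2).
#' @param reps replicates per concentration (default 3).
#' @param noise_cv coefficient of variation of the rate noise.
#' @param growth_floor rate (d^-1) below which growth is treated as nil.
#' @param f0 initial fluorescence (arbitrary units).
#' @param duration_h assay duration (default 72 h).
#' @param seed integer seed.
#' @return data.frame with columns `strain`, `concentration`, `replicate`,
#'   `time_h`, `fluorescence` and attribute `truth`.
#' @export
simulate_dose_response <- function(mu0, ec50, hill = 2,
                                   concentrations = c(0.01, 0.1, 0.32,
                                                      1.0, 3.2),
                                   reps = 3, noise_cv = 0,
                                   growth_floor = 0.05, f0 = 100,
                                   duration_h = 72, seed = 1) {
  if (mu0 <= 0 || ec50 <= 0 || hill <= 0)
    stopf("mu0, ec50 and hill must be positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    stopf("concentrations must be sorted ascending")
  if (reps < 1) stopf("reps must be at least 1")
  times <- seq(0, duration_h, by = 24)
  conc_all <- c(0, concentrations)
  rows <- list()
  for (ci in seq_along(conc_all)) {
    cc <- conc_all[ci]
    mu_c <- if (cc == 0) mu0 else mu0 / (1 + (cc / ec50)^hill)
    for (r in seq_len(reps)) {
      rate <- if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        with_seed(substream_seed(seed, ci * 1000 + r),
                  mu_c * stats::rlnorm(1, -sdlog^2 / 2, sdlog))
      } else mu_c
      if (mu_c < growth_floor) rate <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        strain = "sim", concentration = cc, replicate = r,
        time_h = times, fluorescence = f0 * exp(rate * times / 24),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(mu0 = mu0, ec50 = ec50, hill = hill,
                             noise_cv = noise_cv,
                             growth_floor = growth_floor, seed = seed)
  out
}

#' Simulate an aligned sequence set on a known tree
#'
#' Sequences evolve under an equal-rates (Jukes-Cantor) substitution
#' process along a random bifurcating tree scaled so the mean root-to-tip
#' path equals `subs_rate` expected substitutions per site. Optionally a
#' fraction of columns receive injected gaps, and `phylotype_pairs` tips
#' are duplicated at near-zero divergence (patristic distance 5e-4) to
#' emulate conspecific isolates.
#'
#' @param n_taxa number of taxa before duplication (>= 3).
#' @param seq_length alignment length in bases.
#' @param subs_rate expected substitutions/site from root to tip (>= 0).
#' @param gap_column_fraction probability that a column receives gaps.
#' @param phylotype_pairs number of tips to duplicate.
#' @param seed integer seed.
#' @return List with `alignment` (character matrix) and `tree` (the true
#'   `phylo` tree, including duplicated tips).
#' @export
simulate_alignment <- function(n_taxa, seq_length, subs_rate,
                               gap_column_fraction = 0,
                               phylotype_pairs = 0, seed = 1) {
  if (n_taxa < 3) stopf("n_taxa must be at least 3")
  if (seq_length < 1) stopf("seq_length must be positive")
  if (subs_rate < 0) stopf("subs_rate must be >= 0")
  if (gap_column_fraction < 0 || gap_column_fraction >= 1)
    stopf("gap_column_fraction must be in [0, 1)")
  with_seed(seed, {
    tree <- ape::rtree(n_taxa)
    depth <- mean(diag(ape::vcv(tree)))
    tree$edge.length <- if (subs_rate == 0 || depth == 0)
      rep(0, length(tree$edge.length))
    else tree$edge.length * subs_rate / depth
    eps <- 2.5e-4
    if (phylotype_pairs > 0) {
      picks <- sample(tree$tip.label, min(phylotype_pairs, n_taxa))
      for (tp in picks) {
        where <- which(tree$tip.label == tp)
        pos <- min(eps, tree$edge.length[tree$edge[, 2] == where] / 2)
        tree <- phytools::bind.tip(tree, paste0(tp, "_dup"),
                                   edge.length = eps, where = where,
                                   position = pos)
      }
    }
    sim <- phangorn::simSeq(tree, l = seq_length, type = "DNA")
    aln <- toupper(as.character(as.matrix(ape::as.DNAbin(sim))))
    rownames(aln) <- names(sim)
    aln <- aln[tree$tip.label, , drop = FALSE]
    if (gap_column_fraction > 0) {
      gap_cols <- which(stats::runif(seq_length) < gap_column_fraction)
      for (j in gap_cols) {
        hit <- which(stats::runif(nrow(aln)) < 0.3)
        if (length(hit) == 0) hit <- sample.int(nrow(aln), 1)
        aln[hit, j] <- "-"
      }
    }
    list(alignment = aln, tree = tree)
  })
}
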