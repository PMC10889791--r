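# Shared fixtures and independent brute-force oracles.

# Quick ct_table from a plain matrix (genes x samples).
make_ct <- function(m, group = NULL, amp_factor = 2, genes = NULL) {
  if (is.null(genes))
    genes <- if (!is.null(rownames(m))) rownames(m)
             else paste0("G", seq_len(nrow(m)))
  rownames(m) <- genes
  samples <- data.frame(sample_id = paste0("S", seq_len(ncol(m))),
                        stringsAsFactors = FALSE)
  if (!is.null(group)) samples$group <- group
  ct_table(m, samples = samples, amp_factor = amp_factor)
}

# Seeded random Ct matrix with mild per-gene noise.
random_ct <- function(k, n, seed, sd = 0.5, base = seq(18, 26, length.out = k)) {
  set.seed(seed)
  m <- matrix(rep(base, n), k, n) + rnorm(k * n, 0, sd)
  make_ct(m)
}

# Explicit n-1 standard deviation, used by the oracles so they do not share
# code with the implementation path.
sd_oracle <- function(x) sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1))

# Brute-force geNorm M over a subset: double loop on the log2 quantities.
oracle_genorm_m <- function(tab, subset = tab$genes) {
  A <- tab$amp_factor
  Q <- matrix(NA_real_, length(tab$genes), ncol(tab$ct),
              dimnames = dimnames(tab$ct))
  for (g in seq_along(tab$genes))
    Q[g, ] <- A[g]^(min(tab$ct[g, ]) - tab$ct[g, ])
  out <- numeric(length(subset))
  names(out) <- subset
  for (i in subset) {
    acc <- c()
    for (j in subset) {
      if (i == j) next
      acc <- c(acc, sd_oracle(log2(Q[i, ]) - log2(Q[j, ])))
    }
    out[i] <- mean(acc)
  }
  out
}

# Brute-force pairwise-variation curve from explicit geometric means.
oracle_pairwise_v <- function(tab, ranking) {
  A <- tab$amp_factor
  Q <- matrix(NA_real_, length(tab$genes), ncol(tab$ct),
              dimnames = dimnames(tab$ct))
  for (g in seq_along(tab$genes))
    Q[g, ] <- A[g]^(min(tab$ct[g, ]) - tab$ct[g, ])
  nf <- function(n) {
    gs <- ranking[seq_len(n)]
    apply(Q[gs, , drop = FALSE], 2L, function(q) prod(q)^(1 / length(q)))
  }
  k <- length(ranking)
  vapply(2:(k - 1L), function(n) sd_oracle(log2(nf(n) / nf(n + 1L))), 0)
}

# One-perturbed-gene simulation spec used by the parameter-recovery checks:
# the 15-gene study panel, one gene carrying condition-effect SD `sd_hot`,
# all others 0; 3 groups x 3 biological x 3 technical replicates. Loading
# noise is off: it cancels in the ratio-based methods and merely masks
# BestKeeper's view of the condition effect, so the recovery experiment
# isolates the effect it is meant to detect.
recovery_spec <- function(seed, sd_hot = 2, hot = 8L, tech_sd = 0.3) {
  base <- study_like_spec(seed = 1)$genes
  base$condition_sd <- 0
  base$condition_sd[hot] <- sd_hot
  simulation_spec(base,
                  groups = data.frame(label = c("g1", "g2", "g3"),
                                      n_bio = 3L),
                  n_tech = 3L, sample_loading_sd = 0, tech_sd = tech_sd,
                  seed = seed)
}
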