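#' Specification for a synthetic Ct experiment
#'
#' Describes the additive Gaussian model used by [simulate_ct()]:
#' Ct\\[g, gamma, b, tau\\] = baseline_g + delta_(g,gamma) + a_(gamma,b) + eps,
#' where delta ~ N(0, condition_sd_g) is drawn once per (gene, group) and
#' represents treatment-driven dysregulation, a ~ N(0, sample_loading_sd)
#' is drawn once per biological sample and shared by all genes (the
#' RNA-input/loading effect every normalization method must cancel), and
#' eps ~ N(0, tech_sd) is per-well technical noise.
#'
#' @param genes data.frame with columns `name`, `baseline_ct` (cycles, in
#'   (10, 35)), `condition_sd` (cycles, >= 0) and optionally `amp_factor`
#'   (default 2).
#' @param groups data.frame with columns `label` and `n_bio` (>= 1).
#' @param n_tech technical replicates per biological sample (>= 1).
#' @param sample_loading_sd SD of the per-sample loading offset, cycles.
#' @param tech_sd SD of per-well technical noise, cycles.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @param target optional list describing a target gene on top of the
#'   reference panel: `name`, `baseline_ct`, and `log2_effects`, a named
#'   vector of per-group log2 fold changes (converted to Ct shifts through
#'   the gene's amplification factor), plus optional `amp_factor`.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(genes, groups, n_tech = 3,
                            sample_loading_sd = 0.5, tech_sd = 0.3,
                            seed = 1L, target = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "baseline_ct", "condition_sd") %in% names(genes)),
            all(c("label", "n_bio") %in% names(groups)))
  if (is.null(genes$amp_factor)) genes$amp_factor <- 2
  if (any(genes$baseline_ct <= 10 | genes$baseline_ct >= 35))
    stop("baseline Ct must lie in (10, 35)")
  if (any(genes$condition_sd < 0) || sample_loading_sd < 0 || tech_sd < 0)
    stop("all SDs must be >= 0")
  if (any(groups$n_bio < 1L) || n_tech < 1L)
    stop("n_bio and n_tech must be >= 1")
  if (anyDuplicated(genes$name)) stop("gene names must be unique")
  if (!is.null(target)) {
    stopifnot(is.list(target),
              all(c("name", "baseline_ct", "log2_effects") %in% names(target)))
    if (is.null(target$amp_factor)) target$amp_factor <- 2
    miss <- setdiff(groups$label, names(target$log2_effects))
    if (length(miss))
      stop("target log2_effects missing for group(s): ",
           paste(miss, collapse = ", "))
  }
  structure(list(genes = genes, groups = groups, n_tech = as.integer(n_tech),
                 sample_loading_sd = sample_loading_sd, tech_sd = tech_sd,
                 seed = as.integer(seed), target = target),
            class = "simulation_spec")
}

#' Study-design preset for the simulator
#'
#' A 15-gene reference panel with baselines spread over 17-31 cycles,
#' graded per-gene condition-effect SDs (so a ground-truth stability
#' ordering exists), six treatment groups of 3 biological x 3 technical
#' replicates, loading SD 0.5 and technical SD 0.3 cycles — the shape of a
#' typical insect RT-qPCR reference-gene screen (five insecticide
#' treatments plus an untreated control).
#'
#' @param seed integer seed.
#' @param target if `TRUE`, adds a `CYP6a1`-like target gene that is
#'   2-fold induced in the `Imidacloprid` group relative to `Control`.
#' @return a `simulation_spec`.
#' @export
study_like_spec <- function(seed = 1L, target = FALSE) {
  nm <- c("beta-actin", "EF1a", "EF2", "Ferritin", "GAPDH", "alpha-TUB",
          "beta-TUB", "AK", "GST", "RPL8", "RPL10", "RPL32", "RPS11",
          "RPS15", "RPS20")
  genes <- data.frame(
    name = nm,
    baseline_ct = seq(17, 31, length.out = 15),
    condition_sd = seq(0.05, 1.2, length.out = 15),
    amp_factor = 2,
    stringsAsFactors = FALSE)
  groups <- data.frame(
    label = c("Control", "Imidacloprid", "Thiamethoxam", "Cyhalothrin",
              "Abamectin", "Matrine"),
    n_bio = 3L, stringsAsFactors = FALSE)
  tgt <- if (isTRUE(target))
    list(name = "CYP6a1", baseline_ct = 26,
         log2_effects = c(Control = 0, Imidacloprid = 1, Thiamethoxam = 0,
                          Cyhalothrin = 0, Abamectin = 0, Matrine = 0))
  simulation_spec(genes, groups, n_tech = 3, sample_loading_sd = 0.5,
                  tech_sd = 0.3, seed = seed, target = tgt)
}

#' Simulate a Ct table with known stability structure
#'
#' Draws Ct values from the additive model described in
#' [simulation_spec()]. Values falling outside (5, 45) are clipped and
#' recorded in the `clipped` attribute. The caller's RNG state is left
#' untouched.
#'
#' @param spec a `simulation_spec`.
#' @return list with `ct` (a `ct_table`, wells as columns, `tech_rep`
#'   metadata set) and `ground_truth` (data.frame: `gene`,
#'   `condition_sd`, `true_rank` ascending by condition SD — the ordering
#'   the stability methods should recover).
#' @export
simulate_ct <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  gdf <- spec$genes
  if (!is.null(spec$target))
    gdf <- rbind(gdf, data.frame(name = spec$target$name,
                                 baseline_ct = spec$target$baseline_ct,
                                 condition_sd = 0,
                                 amp_factor = spec$target$amp_factor))
  ng <- nrow(gdf); G <- nrow(spec$groups)
  # one delta per (gene, group)
  delta <- matrix(stats::rnorm(ng * G, 0, rep(gdf$condition_sd, G)),
                  ng, G)
  # target: deterministic group shift on the Ct scale
  if (!is.null(spec$target)) {
    shift <- -spec$target$log2_effects[spec$groups$label] /
      log2(spec$target$amp_factor)
    delta[ng, ] <- delta[ng, ] + shift
  }
  rows <- list(); cols <- 0L
  smeta <- list()
  m <- NULL
  for (gi in seq_len(G)) {
    for (b in seq_len(spec$groups$n_bio[gi])) {
      loading <- stats::rnorm(1L, 0, spec$sample_loading_sd)
      for (tau in seq_len(spec$n_tech)) {
        eps <- stats::rnorm(ng, 0, spec$tech_sd)
        ctv <- gdf$baseline_ct + delta[, gi] + loading + eps
        cols <- cols + 1L
        rows[[cols]] <- ctv
        smeta[[cols]] <- data.frame(
          sample_id = paste0(spec$groups$label[gi], "_b", b),
          group = spec$groups$label[gi], bio_rep = b, tech_rep = tau,
          stringsAsFactors = FALSE)
      }
    }
  }
  m <- do.call(cbind, rows)
  rownames(m) <- gdf$name
  clipped <- sum(m <= 5 | m >= 45)
  m <- pmin(pmax(m, 5 + 1e-9), 45)
  out <- ct_table(m, samples = do.call(rbind, smeta),
                  amp_factor = stats::setNames(gdf$amp_factor, gdf$name))
  attr(out, "clipped") <- clipped
  truth <- data.frame(gene = spec$genes$name,
                      condition_sd = spec$genes$condition_sd,
                      stringsAsFactors = FALSE)
  truth$true_rank <- rank(truth$condition_sd, ties.method = "average")
  list(ct = out, ground_truth = truth)
}

#' Simulate a dilution series for standard-curve fitting
#'
#' Generates Ct values on the line
#' Ct = intercept - log10(c) / log10(1 + E/100) plus Gaussian noise, for
#' each dilution `c` repeated `reps` times.
#'
#' @param true_efficiency_pct true amplification efficiency in percent,
#'   in (50, 120].
#' @param intercept Ct at relative concentration 1, cycles.
#' @param noise_sd Gaussian noise SD in cycles.
#' @param dilutions relative concentrations; default is the 5-fold series
#'   1/5 ... 1/3125.
#' @param reps replicates per dilution.
#' @param seed integer seed.
#' @return a [dilution_series()].
#' @export
simulate_dilution_series <- function(true_efficiency_pct, intercept = 30,
                                     noise_sd = 0,
                                     dilutions = 5^-(1:5), reps = 1L,
                                     seed = 1L) {
  if (true_efficiency_pct <= 50 || true_efficiency_pct > 120)
    stop("true efficiency must lie in (50, 120]%")
  if (any(dilutions <= 0)) stop("dilutions must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  conc <- rep(dilutions, each = reps)
  slope <- slope_from_efficiency(true_efficiency_pct)
  ct <- intercept + slope * log10(conc) +
    stats::rnorm(length(conc), 0, noise_sd)
  dilution_series(conc, ct)
}
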