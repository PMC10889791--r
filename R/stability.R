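#' @noRd
.stability_table <- function(method, genes, values, ties = "average",
                             extra = NULL) {
  rk <- rank(values, ties.method = ties)
  df <- data.frame(gene = genes, value = unname(values), rank = unname(rk),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  attr(df, "method") <- method
  class(df) <- c("stability_table", "data.frame")
  df
}

#' @export
print.stability_table <- function(x, ...) {
  cat("<stability_table> method:", attr(x, "method"), "\n")
  print.data.frame(x[order(x$rank), , drop = FALSE], row.names = FALSE, ...)
  invisible(x)
}

#' Comparative Delta-Ct stability
#'
#' For each gene the stability value is the mean, over all other genes, of
#' the sample standard deviation of the per-sample Ct differences. A gene
#' that co-varies tightly with the rest of the panel has small pairwise
#' difference SDs and is ranked stable. Values are in cycles; lower is more
#' stable.
#'
#' @param x a complete `ct_table` with >= 2 genes and >= 3 samples.
#' @param ties tie-handling for ranks, `"average"` (default) or `"min"`.
#' @return a `stability_table` (data.frame: `gene`, `value`, `rank`).
#' @export
delta_ct_stability <- function(x, ties = c("average", "min")) {
  ties <- match.arg(ties)
  stopifnot(inherits(x, "ct_table"))
  k <- length(x$genes); n <- ncol(x$ct)
  if (k < 2L) stop("need at least 2 genes")
  if (n < 3L) stop("need at least 3 samples")
  if (anyNA(x$ct)) stop("complete Ct matrix required")
  sdmat <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    s <- stats::sd(x$ct[i, ] - x$ct[j, ])
    sdmat[i, j] <- sdmat[j, i] <- s
  }
  vals <- rowSums(sdmat) / (k - 1L)
  .stability_table("delta_ct", x$genes, vals, ties)
}

#' geNorm M-value on a gene subset
#'
#' The M-value of gene i is the mean over the other genes j of the sample
#' standard deviation of the log2 expression ratio
#' log2(Q\\[i, .\\]) - log2(Q\\[j, .\\]), with Q the relative quantities from
#' [relative_quantities()]. Lower M = more stable.
#'
#' @param x a complete `ct_table`.
#' @param subset character vector of >= 2 gene names (default: all genes).
#' @return named numeric vector of M-values over `subset`.
#' @export
genorm_m <- function(x, subset = NULL) {
  stopifnot(inherits(x, "ct_table"))
  if (is.null(subset)) subset <- x$genes
  if (length(subset) < 2L) stop("geNorm needs at least 2 genes")
  miss <- setdiff(subset, x$genes)
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  L <- log2(relative_quantities(x))[subset, , drop = FALSE]
  k <- length(subset)
  m <- numeric(k)
  for (i in seq_len(k)) {
    v <- vapply(seq_len(k)[-i],
                function(j) stats::sd(L[i, ] - L[j, ]), 0)
    m[i] <- mean(v)
  }
  stats::setNames(m, subset)
}

#' geNorm stepwise ranking
#'
#' Iteratively removes the gene with the highest M-value until two genes
#' remain. Each gene's reported stability value is its M at the step it was
#' excluded; the final pair both carry the two-gene M and take ranks 1 and 2
#' ordered by their M in the last three-gene step. Ties are broken by
#' removing the lexicographically last gene name.
#'
#' @param x a complete `ct_table` with >= 3 genes (2 genes are returned
#'   as the trivial final pair with a warning).
#' @param ties tie-handling for ranks of the removed genes.
#' @return list with `trace` (data.frame `step`, `gene`, `m`,
#'   `n_remaining`; first row = first/least-stable removal), `final_pair`
#'   (2 gene names, most stable first) and `stability` (a
#'   `stability_table`).
#' @export
genorm_rank <- function(x, ties = c("average", "min")) {
  ties <- match.arg(ties)
  stopifnot(inherits(x, "ct_table"))
  k <- length(x$genes)
  if (k < 2L) stop("geNorm needs at least 2 genes")
  if (k == 2L) {
    warning("only 2 genes: no exclusion possible, both form the final pair")
    m <- genorm_m(x)
    ord <- order(m, x$genes)
    st <- .stability_table("genorm", x$genes, m, ties)
    return(list(trace = data.frame(step = integer(0), gene = character(0),
                                   m = numeric(0), n_remaining = integer(0)),
                final_pair = x$genes[ord], stability = st))
  }
  current <- x$genes
  removed <- character(0); m_rem <- numeric(0)
  last3 <- NULL
  step <- 0L
  while (length(current) > 2L) {
    step <- step + 1L
    m <- genorm_m(x, current)
    if (length(current) == 3L) last3 <- m
    # worst gene; ties -> remove the lexicographically last name
    worst <- current[order(m, current)][length(current)]
    removed <- c(removed, worst)
    m_rem <- c(m_rem, unname(m[worst]))
    current <- setdiff(current, worst)
  }
  m2 <- genorm_m(x, current)
  pair_ord <- order(last3[current], current)
  final_pair <- current[pair_ord]
  vals <- stats::setNames(numeric(k), x$genes)
  vals[removed] <- m_rem
  vals[current] <- unname(m2[current])
  # ranks: final pair occupy 1 and 2 by their M in the last 3-gene step,
  # removed genes follow in reverse removal order
  rk <- stats::setNames(numeric(k), x$genes)
  rk[final_pair] <- c(1, 2)
  rk[rev(removed)] <- 2 + seq_along(removed)
  df <- data.frame(gene = x$genes, value = unname(vals[x$genes]),
                   rank = unname(rk[x$genes]), stringsAsFactors = FALSE)
  attr(df, "method") <- "genorm"
  class(df) <- c("stability_table", "data.frame")
  trace <- data.frame(step = seq_along(removed), gene = removed, m = m_rem,
                      n_remaining = k - seq_along(removed),
                      stringsAsFactors = FALSE)
  list(trace = trace, final_pair = final_pair, stability = df)
}

#' geNorm pairwise variation curve
#'
#' V_n is the standard deviation over samples of
#' log2(NF_n / NF_(n+1)), where NF_n is the geometric mean of the relative
#' quantities of the n best-ranked genes. A V_n below the cutoff
#' (conventionally 0.15) indicates that the (n+1)-th gene adds no useful
#' information.
#'
#' @param x a complete `ct_table`.
#' @param ranking character vector of >= 3 gene names, best first.
#' @param cutoff stored decision threshold (default 0.15).
#' @return object of class `pairwise_variation`: data.frame with columns
#'   `n` (2..k-1) and `v`, plus a `cutoff` attribute.
#' @export
pairwise_variation <- function(x, ranking, cutoff = 0.15) {
  stopifnot(inherits(x, "ct_table"))
  k <- length(ranking)
  if (k < 3L) stop("pairwise variation needs at least 3 ranked genes")
  miss <- setdiff(ranking, x$genes)
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  L <- log2(relative_quantities(x))[ranking, , drop = FALSE]
  # log2 NF_n per sample = mean of log2 Q over the n best genes
  nf_log <- apply(L, 2L, cumsum) / seq_len(k)   # k x samples
  v <- vapply(2:(k - 1L), function(n)
    stats::sd(nf_log[n, ] - nf_log[n + 1L, ]), 0)
  out <- data.frame(n = 2:(k - 1L), v = v)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("pairwise_variation", "data.frame")
  out
}

# NormFinder intragroup variance estimate with gene-mean-subtraction bias
# correction; `xc` is the sample-centred log-quantity matrix (genes x
# samples) of one group.
.normfinder_sigma2 <- function(xc) {
  k <- nrow(xc); n <- ncol(xc)
  r <- xc - rowMeans(xc)
  v <- rowSums(r^2) / (n - 1L)
  total <- sum(v) / (1 - 1 / k)
  sigma2 <- pmax((v - total / k^2) / (1 - 2 / k), 0)
  list(v = v, total = total, sigma2 = sigma2)
}

#' NormFinder model-based stability
#'
#' Decomposes, on the log2 relative-quantity scale after centring each
#' sample on its gene average, the variation of each candidate gene into
#' gene-specific (intragroup) variance and, when group labels are supplied,
#' a systematic intergroup bias. The raw per-gene variances are corrected
#' for the bias introduced by subtracting the gene mean of each sample.
#' Without groups the stability value is the gene-specific standard
#' deviation; with groups it is the average over groups of the
#' shrinkage-weighted absolute intergroup difference plus the standard
#' error of the group mean. Lower = more stable.
#'
#' @param x a complete `ct_table` with >= 3 genes.
#' @param groups optional character vector of group labels per sample
#'   (every group needs >= 2 samples), or `TRUE` to take them from the
#'   sample metadata.
#' @param ties tie-handling for ranks.
#' @return a `stability_table`; its `decomposition` attribute holds the
#'   per-gene (and per-group) variance components.
#' @export
normfinder_stability <- function(x, groups = NULL,
                                 ties = c("average", "min")) {
  ties <- match.arg(ties)
  stopifnot(inherits(x, "ct_table"))
  k <- length(x$genes)
  if (k < 3L) stop("NormFinder needs at least 3 genes")
  if (anyNA(x$ct)) stop("complete Ct matrix required")
  if (isTRUE(groups)) groups <- x$samples$group
  z <- log2(relative_quantities(x))
  xc <- sweep(z, 2L, colMeans(z))   # remove per-sample loading
  if (is.null(groups) || all(is.na(groups))) {
    est <- .normfinder_sigma2(xc)
    vals <- sqrt(est$sigma2)
    st <- .stability_table("normfinder", x$genes, vals, ties)
    attr(st, "decomposition") <- list(raw_var = est$v, total = est$total,
                                      sigma2 = est$sigma2)
    return(st)
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(xc))
    stop("`groups` must have one label per sample")
  gl <- unique(groups)
  G <- length(gl)
  ngam <- table(factor(groups, levels = gl))
  if (any(ngam < 2L))
    stop("every group needs >= 2 samples; group '",
         gl[which(ngam < 2L)[1L]], "' has ", min(ngam))
  if (G == 1L) return(normfinder_stability(x, groups = NULL, ties = ties))
  xbar <- sapply(gl, function(g) rowMeans(xc[, groups == g, drop = FALSE]))
  sigma2 <- sapply(gl, function(g)
    .normfinder_sigma2(xc[, groups == g, drop = FALSE])$sigma2)
  # intergroup differences, centred per gene over groups
  d <- xbar - rowMeans(xbar)
  s2n <- sweep(sigma2, 2L, as.numeric(ngam), "/")   # sigma^2_{g,gamma}/n_gamma
  gamma_hat <- max(sum(d^2) / (k * (G - 1L)) - mean(s2n), 0)
  w <- gamma_hat / (gamma_hat + s2n)
  w[!is.finite(w)] <- 0   # gamma_hat = 0 and zero variance
  vals <- rowMeans(abs(d * w) + sqrt(s2n))
  st <- .stability_table("normfinder", x$genes, vals, ties)
  attr(st, "decomposition") <- list(group_means = xbar, sigma2 = sigma2,
                                    d = d, gamma_hat = gamma_hat,
                                    weights = w)
  st
}

#' BestKeeper descriptive stability
#'
#' Works on raw Ct values (no quantity transform). For each gene it reports
#' the number of samples, geometric and arithmetic mean Ct, min, max, the
#' dispersion (`sd`: sample SD; `mad`: mean absolute deviation from the
#' arithmetic mean), the coefficient of variation
#' CV = 100 x dispersion / mean Ct, and the Pearson correlation of the
#' gene's Ct with the BestKeeper index (the per-sample geometric mean Ct
#' over all genes). Ranking is ascending by dispersion, ties broken by CV
#' then gene name.
#'
#' @param x a complete `ct_table` with >= 3 samples; all Ct must be > 0.
#' @param deviation `"sd"` (default) or `"mad"`.
#' @param ties tie-handling for ranks (applied after the CV/name
#'   tie-break).
#' @return a `stability_table` with extra columns `cv`, `n`, `geo_mean`,
#'   `ar_mean`, `min`, `max`, `r_index`; `value` holds the dispersion in
#'   cycles.
#' @export
bestkeeper_stats <- function(x, deviation = c("sd", "mad"),
                             ties = c("average", "min")) {
  deviation <- match.arg(deviation)
  ties <- match.arg(ties)
  stopifnot(inherits(x, "ct_table"))
  if (ncol(x$ct) < 3L) stop("need at least 3 samples")
  if (anyNA(x$ct)) stop("complete Ct matrix required")
  if (any(x$ct <= 0)) stop("all Ct must be > 0 (geometric mean undefined)")
  ar <- rowMeans(x$ct)
  dev <- if (deviation == "sd") apply(x$ct, 1L, stats::sd)
         else rowMeans(abs(x$ct - ar))
  cv <- 100 * dev / ar
  index <- exp(colMeans(log(x$ct)))
  r <- if (length(x$genes) > 0)
    apply(x$ct, 1L, function(row)
      if (stats::sd(row) == 0 || stats::sd(index) == 0) NA_real_
      else stats::cor(row, index))
  else numeric(0)
  # deterministic ordering by (deviation, cv, name); ranks on that order
  ord <- order(dev, cv, x$genes)
  rk <- numeric(length(dev))
  rk[ord] <- seq_along(dev)
  df <- data.frame(gene = x$genes, value = unname(dev), rank = rk,
                   cv = unname(cv), n = ncol(x$ct),
                   geo_mean = unname(exp(rowMeans(log(x$ct)))),
                   ar_mean = unname(ar),
                   min = apply(x$ct, 1L, min), max = apply(x$ct, 1L, max),
                   r_index = unname(r),
                   stringsAsFactors = FALSE)
  ties_mask <- duplicated(paste(dev, cv)) | duplicated(paste(dev, cv),
                                                       fromLast = TRUE)
  if (any(ties_mask) && ties == "average") {
    key <- paste(dev, cv)
    df$rank <- stats::ave(df$rank, key, FUN = mean)
  }
  attr(df, "method") <- "bestkeeper"
  attr(df, "index") <- index
  class(df) <- c("stability_table", "data.frame")
  df
}

#' Run all four stability algorithms
#'
#' @param x a complete `ct_table`.
#' @param groups optional per-sample group labels for NormFinder (`TRUE` to
#'   use the sample metadata).
#' @param methods subset of `c("delta_ct", "genorm", "normfinder",
#'   "bestkeeper")`.
#' @param deviation BestKeeper dispersion mode.
#' @param ties rank tie-handling.
#' @return named list of `stability_table`s; the geNorm entry carries the
#'   stepwise `trace` and `final_pair` as attributes.
#' @export
stability_all <- function(x, groups = TRUE,
                          methods = c("delta_ct", "genorm", "normfinder",
                                      "bestkeeper"),
                          deviation = "sd", ties = "average") {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  if ("delta_ct" %in% methods)
    out$delta_ct <- delta_ct_stability(x, ties = ties)
  if ("genorm" %in% methods) {
    gr <- genorm_rank(x, ties = ties)
    st <- gr$stability
    attr(st, "trace") <- gr$trace
    attr(st, "final_pair") <- gr$final_pair
    out$genorm <- st
  }
  if ("normfinder" %in% methods)
    out$normfinder <- normfinder_stability(x, groups = groups, ties = ties)
  if ("bestkeeper" %in% methods)
    out$bestkeeper <- bestkeeper_stats(x, deviation = deviation, ties = ties)
  out
}
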