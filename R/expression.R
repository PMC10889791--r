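#' Relative expression by the 2^-ddCt method with multiple reference genes
#'
#' Normalizes a target gene against the arithmetic mean Ct of one or more
#' reference genes (equivalent, at equal amplification factors, to the
#' geometric mean of their relative quantities), then calibrates against
#' the mean delta-Ct of the calibrator group:
#' fold\\[s\\] = 2^-(dCt\\[s\\] - mean dCt over calibrator samples).
#' With `efficiency_correct = TRUE` the per-gene amplification factors of
#' the table are used instead of the assumed perfect doubling: the fold
#' change becomes A_t^-(ddCt target) divided by the geometric mean of
#' A_r^-(ddCt ref) over references.
#'
#' @param x a complete (aggregated) `ct_table` whose samples carry group
#'   labels.
#' @param target target gene name.
#' @param refs character vector of reference gene names (non-empty).
#' @param calibrator_group group label used as the calibrator; its mean
#'   delta-Ct defines fold = 1.
#' @param efficiency_correct logical, default `FALSE` (assume A = 2 for
#'   all genes).
#' @param log_scale_summary logical; if `TRUE`, group means and SEs are
#'   also reported on the log2 fold-change scale.
#' @return object of class `expression_result`: list with `samples`
#'   (data.frame: sample_id, group, dct, ddct, fold), `groups`
#'   (data.frame: group, n, mean_fold, se_fold, and log2 summaries if
#'   requested), `target`, `refs`, `calibrator_group`.
#' @export
ddct_expression <- function(x, target, refs, calibrator_group,
                            efficiency_correct = FALSE,
                            log_scale_summary = FALSE) {
  stopifnot(inherits(x, "ct_table"))
  if (!length(refs)) stop("`refs` must name at least one reference gene")
  miss <- setdiff(c(target, refs), x$genes)
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  if (target %in% refs) stop("target cannot be one of the reference genes")
  if (anyNA(x$ct)) stop("aggregate technical replicates first")
  grp <- x$samples$group
  cal <- which(grp == calibrator_group)
  if (!length(cal)) stop("calibrator group '", calibrator_group,
                         "' not present in sample metadata")
  if (efficiency_correct) {
    # per-sample log2 quantities with gene-specific amplification factors,
    # calibrated to the mean of the calibrator group
    l2 <- x$ct * log2(x$amp_factor)          # recycles by gene (rows)
    dct <- l2[target, ] - colMeans(l2[refs, , drop = FALSE])
  } else {
    dct <- x$ct[target, ] - colMeans(x$ct[refs, , drop = FALSE])
  }
  ddct <- dct - mean(dct[cal])
  fold <- 2^(-ddct)
  samples <- data.frame(sample_id = x$samples$sample_id, group = grp,
                        dct = unname(dct), ddct = unname(ddct),
                        fold = unname(fold), stringsAsFactors = FALSE)
  gl <- unique(grp[!is.na(grp)])
  groups <- do.call(rbind, lapply(gl, function(g) {
    f <- fold[grp == g & !is.na(grp)]
    out <- data.frame(group = g, n = length(f), mean_fold = mean(f),
                      se_fold = if (length(f) > 1L)
                        stats::sd(f) / sqrt(length(f)) else 0,
                      stringsAsFactors = FALSE)
    if (log_scale_summary) {
      lf <- log2(f)
      out$mean_log2_fold <- mean(lf)
      out$se_log2_fold <- if (length(f) > 1L)
        stats::sd(lf) / sqrt(length(lf)) else 0
    }
    out
  }))
  structure(list(samples = samples, groups = groups, target = target,
                 refs = refs, calibrator_group = calibrator_group,
                 efficiency_correct = efficiency_correct),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat("<expression_result> target:", x$target, " refs:",
      paste(x$refs, collapse = " + "),
      " calibrator:", x$calibrator_group, "\n")
  print.data.frame(x$groups, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pooled-variance Student's t test between two groups
#'
#' @param values numeric vector of per-sample values (fold changes or Ct).
#' @param groups vector of exactly 2 distinct labels, one per value.
#' @return list: `t`, `df`, `p`, `means` (named, per group), `degenerate`
#'   (`TRUE` when both groups have zero variance but different means, in
#'   which case `p` is 0 and `t` infinite).
#' @export
two_group_test <- function(values, groups) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  gl <- unique(groups)
  if (length(gl) != 2L) stop("need exactly 2 groups, got ", length(gl))
  a <- values[groups == gl[1L]]; b <- values[groups == gl[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  df <- length(a) + length(b) - 2L
  means <- stats::setNames(c(mean(a), mean(b)), gl)
  if (sp2 == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = df, p = 1, means = means, degenerate = FALSE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0,
                means = means, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, means = means, degenerate = FALSE)
}

# Compact letter display by insert-and-absorb on the significance graph.
# `diffmat` is a logical symmetric matrix: TRUE where the pair differs
# significantly. Group order = decreasing mean (letters start from the
# largest mean).
.compact_letters <- function(diffmat, order_by) {
  gl <- rownames(diffmat)
  ord <- order(-order_by)
  gl <- gl[ord]
  diffmat <- diffmat[ord, ord, drop = FALSE]
  cols <- list(gl)   # start: one letter containing all groups
  for (i in seq_along(gl)) for (j in seq_along(gl)) {
    if (j <= i || !diffmat[i, j]) next
    for (ci in seq_along(cols)) {
      if (all(c(gl[i], gl[j]) %in% cols[[ci]])) {
        # duplicate the column, separate the offending pair
        cols[[ci]] <- setdiff(cols[[ci]], gl[j])
        cols[[length(cols) + 1L]] <- setdiff(c(cols[[ci]], gl[j]), gl[i])
      }
    }
    # absorb: drop columns that are subsets of (or duplicate) another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a == b || !keep[a] || !keep[b]) next
      if (all(cols[[a]] %in% cols[[b]]) &&
          (length(cols[[a]]) < length(cols[[b]]) || a > b))
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  # order letter columns by the position of their first (largest-mean) member
  firsts <- vapply(cols, function(cc) min(match(cc, gl)), 0)
  cols <- cols[order(firsts)]
  letters_out <- stats::setNames(rep("", length(gl)), gl)
  for (ci in seq_along(cols))
    for (g in cols[[ci]])
      letters_out[g] <- paste0(letters_out[g], letters[ci])
  letters_out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA, performs Tukey's honestly-significant-difference
#' pairwise comparisons via the studentized-range distribution, and
#' summarizes them as compact letters: groups sharing no letter differ at
#' level `alpha`. Letters are assigned by insert-and-absorb on the
#' significance graph, starting alphabetically from the group with the
#' largest mean.
#'
#' @param values numeric vector of per-sample values.
#' @param groups vector of >= 3 distinct labels, one per value; every
#'   group needs >= 2 values.
#' @param alpha significance level (default 0.05).
#' @return list: `F`, `df`, `p`, `tukey` (data.frame: pair, diff, lwr,
#'   upr, p_adj), `letters` (named character vector per group), `alpha`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  gl <- unique(groups)
  if (length(gl) < 3L)
    stop("need at least 3 groups (use two_group_test for 2)")
  cnt <- table(factor(groups, levels = gl))
  if (any(cnt < 2L))
    stop("every group needs >= 2 values; group '",
         gl[which(cnt < 2L)[1L]], "' has ", min(cnt))
  g <- factor(groups, levels = gl)
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- rownames(tk)
  tukey <- data.frame(pair = pairs, diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)
  diffmat <- matrix(FALSE, length(gl), length(gl),
                    dimnames = list(gl, gl))
  split_pair <- strsplit(pairs, "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    ab <- split_pair[[i]]
    if (length(ab) != 2L) {  # group names containing '-': match by levels
      ab <- rep(NA_character_, 2L)
      for (a in gl) for (b in gl)
        if (paste0(a, "-", b) == pairs[i]) { ab <- c(a, b); break }
    }
    if (tukey$p_adj[i] < alpha) diffmat[ab[1L], ab[2L]] <-
        diffmat[ab[2L], ab[1L]] <- TRUE
  }
  means <- tapply(values, g, mean)
  letters_out <- .compact_letters(diffmat, order_by = as.numeric(means[gl]))
  list(F = an[["F value"]][1L], df = an[["Df"]],
       p = an[["Pr(>F)"]][1L], tukey = tukey,
       letters = letters_out[gl], means = means[gl], alpha = alpha)
}
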