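#' Comprehensive consensus ranking (RefFinder-style)
#'
#' Merges the rankings of several stability methods into one ordering by
#' the geometric mean of each gene's per-method ranks: the lower the
#' geomean, the more stable the gene. The final order is ascending by
#' geomean, with ties broken by arithmetic mean rank and then gene name.
#'
#' @param ranks_by_method named list of per-method rankings (>= 2 methods).
#'   Each element is either a `stability_table` or a named numeric vector
#'   of ranks; every method must rank every gene.
#' @return object of class `consensus_ranking`: data.frame with one column
#'   of ranks per method, `geomean`, and `final_rank`; rows ordered by
#'   `final_rank`. The `methods` attribute lists the contributing methods.
#' @export
reffinder_geomean <- function(ranks_by_method) {
  if (!is.list(ranks_by_method) || length(ranks_by_method) < 2L)
    stop("need rankings from at least 2 methods")
  if (is.null(names(ranks_by_method)))
    names(ranks_by_method) <- paste0("method", seq_along(ranks_by_method))
  as_rankvec <- function(r) {
    if (inherits(r, "stability_table") ||
        (is.data.frame(r) && all(c("gene", "rank") %in% names(r))))
      stats::setNames(r$rank, r$gene)
    else if (is.numeric(r) && !is.null(names(r))) r
    else stop("each ranking must be a stability_table or named numeric vector")
  }
  rl <- lapply(ranks_by_method, as_rankvec)
  genes <- names(rl[[1L]])
  for (m in names(rl)) {
    miss <- setdiff(genes, names(rl[[m]]))
    extra <- setdiff(names(rl[[m]]), genes)
    if (length(miss) || length(extra))
      stop("gene '", c(miss, extra)[1L], "' missing from method '",
           if (length(miss)) m else names(rl)[1L], "'")
  }
  rmat <- sapply(rl, function(r) unname(r[genes]))
  if (is.null(dim(rmat))) rmat <- matrix(rmat, nrow = 1L)
  geomean <- exp(rowMeans(log(rmat)))
  amean <- rowMeans(rmat)
  out <- data.frame(gene = genes, rmat, geomean = geomean,
                    stringsAsFactors = FALSE, check.names = FALSE)
  ord <- order(geomean, amean, genes)
  out <- out[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "methods") <- names(rl)
  class(out) <- c("consensus_ranking", "data.frame")
  out
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("<consensus_ranking> methods:",
      paste(attr(x, "methods"), collapse = ", "), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}

#' Optimal number and combination of reference genes
#'
#' Applies the V < cutoff rule to a pairwise-variation curve to choose how
#' many reference genes to use, then takes that many genes from the top of
#' the consensus ranking. `optimal_n` is the smallest n with V_n below the
#' cutoff; if no V_n clears it, the n minimising V is used and the
#' `fallback` flag is set.
#'
#' @param consensus a `consensus_ranking`.
#' @param v a `pairwise_variation` curve computed on the same gene set.
#' @param cutoff decision threshold on V (default: the curve's stored
#'   cutoff, conventionally 0.15).
#' @return list of class `rg_recommendation`: `single_best`, `optimal_n`,
#'   `combination`, `v_used`, `fallback`.
#' @export
select_optimal <- function(consensus, v, cutoff = NULL) {
  stopifnot(inherits(consensus, "consensus_ranking"))
  if (!is.data.frame(v) || !all(c("n", "v") %in% names(v)))
    stop("`v` must be a pairwise_variation curve (columns n, v)")
  if (is.null(cutoff)) cutoff <- attr(v, "cutoff")
  if (is.null(cutoff)) cutoff <- 0.15
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  below <- which(v$v < cutoff)
  if (length(below)) {
    i <- below[1L]; fallback <- FALSE
  } else {
    i <- which.min(v$v); fallback <- TRUE
  }
  n <- v$n[i]
  comb <- consensus$gene[seq_len(n)]
  structure(list(single_best = comb[1L], optimal_n = as.integer(n),
                 combination = comb, v_used = v$v[i], fallback = fallback),
            class = "rg_recommendation")
}

#' @export
print.rg_recommendation <- function(x, ...) {
  cat("<rg_recommendation>\n")
  cat("  single best:", x$single_best, "\n")
  cat(sprintf("  optimal n: %d (V = %.4f%s)\n", x$optimal_n, x$v_used,
              if (x$fallback) ", fallback: no V below cutoff" else ""))
  cat("  combination:", paste(x$combination, collapse = " + "), "\n")
  invisible(x)
}
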