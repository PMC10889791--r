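#' Construct a Ct table
#'
#' The central container for RT-qPCR cycle-threshold data: a genes x samples
#' matrix of Ct values together with per-sample metadata (treatment group,
#' biological and technical replicate) and per-gene amplification factors.
#' All stability algorithms, the consensus ranking and the ddCt expression
#' module consume this object.
#'
#' @param ct numeric matrix, genes in rows, samples (wells) in columns.
#'   Row names are gene names (required, unique). Values are cycle-threshold
#'   values in cycles; every non-missing value must lie in (0, 45].
#' @param samples data.frame with one row per column of `ct`. Columns:
#'   `sample_id` (character, required), and optionally `group` (character),
#'   `bio_rep` and `tech_rep` (positive integers, default 1). The pair
#'   (`sample_id`, `tech_rep`) must be unique.
#' @param amp_factor per-gene amplification factor A = 1 + E/100, either a
#'   single number recycled to all genes or a named vector covering every
#'   gene. Must lie in [1.5, 2.3]. Default 2 (perfect doubling), the value
#'   assumed when no standard curve is available.
#' @param allow_missing logical; if `TRUE`, `NA` Ct values are tolerated
#'   (only meaningful before technical-replicate aggregation).
#'
#' @return An object of class `ct_table`: a list with elements `ct`
#'   (the matrix), `samples` (the metadata data.frame), `amp_factor`
#'   (named numeric vector) and `genes` (character vector, row order).
#' @export
ct_table <- function(ct, samples = NULL, amp_factor = 2, allow_missing = FALSE) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(ct))) {
    if (nrow(ct) > 0L) stop("`ct` must have gene names as row names")
    rownames(ct) <- character(0)
  }
  genes <- rownames(ct)
  if (anyDuplicated(genes))
    stop("gene names must be unique; duplicated: ",
         genes[duplicated(genes)][1L])

  if (is.null(samples)) {
    ids <- colnames(ct)
    if (is.null(ids)) ids <- paste0("S", seq_len(ncol(ct)))
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples))
    stop("`samples` must contain a `sample_id` column")
  if (nrow(samples) != ncol(ct))
    stop("`samples` has ", nrow(samples), " rows but `ct` has ",
         ncol(ct), " columns")
  samples$sample_id <- as.character(samples$sample_id)
  if (is.null(samples$group)) samples$group <- NA_character_
  if (is.null(samples$bio_rep)) samples$bio_rep <- 1L
  if (is.null(samples$tech_rep)) samples$tech_rep <- 1L
  samples$bio_rep <- as.integer(samples$bio_rep)
  samples$tech_rep <- as.integer(samples$tech_rep)
  if (any(samples$bio_rep < 1L, na.rm = TRUE) ||
      any(samples$tech_rep < 1L, na.rm = TRUE))
    stop("`bio_rep` and `tech_rep` must be positive integers")
  key <- paste(samples$sample_id, samples$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop("duplicate (sample_id, tech_rep): ('", samples$sample_id[d],
         "', ", samples$tech_rep[d], ")")
  }

  if (length(amp_factor) == 1L && is.null(names(amp_factor)))
    amp_factor <- stats::setNames(rep(as.numeric(amp_factor), length(genes)),
                                  genes)
  if (is.null(names(amp_factor)) || !all(genes %in% names(amp_factor)))
    stop("`amp_factor` must be a single value or a named vector covering all genes")
  amp_factor <- amp_factor[genes]
  if (any(amp_factor < 1.5 | amp_factor > 2.3))
    stop("amplification factors must lie in [1.5, 2.3]")

  bad <- which(!is.na(ct) & (!is.finite(ct) | ct <= 0 | ct > 45))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(ct))
    stop("Ct value out of (0, 45] for gene '", genes[idx[1L]],
         "', sample '", samples$sample_id[idx[2L]], "': ", ct[bad[1L]])
  }
  if (!allow_missing && anyNA(ct)) {
    idx <- arrayInd(which(is.na(ct))[1L], dim(ct))
    stop("missing Ct for gene '", genes[idx[1L]], "', sample '",
         samples$sample_id[idx[2L]],
         "' (use allow_missing = TRUE before aggregation)")
  }

  colnames(ct) <- make.unique(samples$sample_id)
  structure(list(ct = ct, samples = samples, amp_factor = amp_factor,
                 genes = genes),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  ng <- length(x$genes); ns <- nrow(x$samples)
  grp <- unique(x$samples$group)
  grp <- grp[!is.na(grp)]
  cat("<ct_table> ", ng, " genes x ", ns, " samples\n", sep = "")
  if (length(grp))
    cat("  groups: ", paste(grp, collapse = ", "), "\n", sep = "")
  cat("  Ct range: ", round(min(x$ct, na.rm = TRUE), 2), "-",
      round(max(x$ct, na.rm = TRUE), 2),
      if (anyNA(x$ct)) sprintf("  (%d missing)", sum(is.na(x$ct))) else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_table <- function(x) dim(x$ct)

#' Subset a Ct table by gene and/or sample
#'
#' @param x a `ct_table`.
#' @param genes character vector of gene names or integer/logical row index.
#' @param samples integer/logical column index.
#' @return a `ct_table` restricted to the requested genes and samples.
#' @export
subset_ct <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ct_table"))
  gi <- if (is.null(genes)) seq_along(x$genes) else
    if (is.character(genes)) match(genes, x$genes) else genes
  if (is.character(genes) && anyNA(gi))
    stop("unknown gene(s): ", paste(genes[is.na(gi)], collapse = ", "))
  si <- if (is.null(samples)) seq_len(nrow(x$samples)) else samples
  ct_table(x$ct[gi, si, drop = FALSE],
           samples = x$samples[si, , drop = FALSE],
           amp_factor = x$amp_factor[gi],
           allow_missing = anyNA(x$ct[gi, si]))
}

.detect_sep <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

.parse_ct_cell <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "Undetermined", "undetermined", "N/A")] <- NA
  suppressWarnings(as.numeric(x))
}

#' Read a Ct table from delimited text
#'
#' Two layouts are supported. `long`: one row per well with columns
#' `sample_id, gene, ct` and optional `group`, `bio_rep`, `tech_rep`.
#' `wide`: one row per sample with metadata columns followed by one column
#' per gene. The delimiter is inferred from the extension (`.tsv` = tab,
#' anything else = comma). Text cells `"Undetermined"`/`"NA"`/empty map to
#' missing Ct values.
#'
#' @param path file path.
#' @param layout `"long"` or `"wide"`.
#' @param schema optional named list remapping the expected column names,
#'   e.g. `list(sample_id = "Well", ct = "Cq")`.
#' @param amp_factor passed to [ct_table()].
#' @return a `ct_table` preserving the input order of first appearance of
#'   genes and samples.
#' @export
read_ct_table <- function(path, layout = c("long", "wide"), schema = list(),
                          amp_factor = 2) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = .detect_sep(path), header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          fileEncoding = "UTF-8")
  col <- function(std) if (!is.null(schema[[std]])) schema[[std]] else std

  meta_cols <- c("sample_id", "group", "bio_rep", "tech_rep")
  if (layout == "long") {
    need <- vapply(c("sample_id", "gene", "ct"), col, "")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing required column(s): ",
                           paste(miss, collapse = ", "))
    sample_id <- df[[col("sample_id")]]
    gene <- df[[col("gene")]]
    tech <- if (col("tech_rep") %in% names(df))
      as.integer(df[[col("tech_rep")]]) else rep(1L, nrow(df))
    key <- paste(sample_id, tech, gene, sep = "\r")
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1L]
      stop("duplicate (sample_id, tech_rep, gene) row at line ", d + 1L,
           ": ('", sample_id[d], "', ", tech[d], ", '", gene[d], "')")
    }
    ctv <- .parse_ct_cell(df[[col("ct")]])
    bad <- which(!is.na(ctv) & (ctv <= 0 | ctv > 45))
    if (length(bad))
      stop("Ct outside (0, 45] at row ", bad[1L], ": ", ctv[bad[1L]])

    genes <- unique(gene)
    wkey <- paste(sample_id, tech, sep = "\r")
    wells <- !duplicated(wkey)
    smeta <- data.frame(sample_id = sample_id[wells],
                        group = if (col("group") %in% names(df))
                          df[[col("group")]][wells] else NA_character_,
                        bio_rep = if (col("bio_rep") %in% names(df))
                          as.integer(df[[col("bio_rep")]][wells]) else 1L,
                        tech_rep = tech[wells],
                        stringsAsFactors = FALSE)
    m <- matrix(NA_real_, length(genes), sum(wells),
                dimnames = list(genes, NULL))
    m[cbind(match(gene, genes), match(wkey, wkey[wells]))] <- ctv
    ct_table(m, samples = smeta, amp_factor = amp_factor,
             allow_missing = TRUE)
  } else {
    idcol <- col("sample_id")
    if (!idcol %in% names(df)) stop("missing required column: ", idcol)
    present_meta <- intersect(vapply(meta_cols, col, ""), names(df))
    gene_cols <- setdiff(names(df), present_meta)
    if (!length(gene_cols)) stop("wide layout: no gene columns found")
    m <- t(vapply(df[gene_cols], .parse_ct_cell, numeric(nrow(df))))
    if (nrow(df) == 1L) m <- matrix(m, ncol = 1L,
                                    dimnames = list(gene_cols, NULL))
    rownames(m) <- gene_cols
    bad <- which(!is.na(m) & (m <= 0 | m > 45))
    if (length(bad)) {
      idx <- arrayInd(bad[1L], dim(m))
      stop("Ct outside (0, 45] at row ", idx[2L], " (gene '",
           gene_cols[idx[1L]], "'): ", m[bad[1L]])
    }
    smeta <- data.frame(sample_id = df[[idcol]], stringsAsFactors = FALSE)
    for (std in c("group", "bio_rep", "tech_rep")) {
      cn <- col(std)
      if (cn %in% names(df))
        smeta[[std]] <- if (std == "group") df[[cn]] else as.integer(df[[cn]])
    }
    ct_table(m, samples = smeta, amp_factor = amp_factor,
             allow_missing = TRUE)
  }
}

#' Write a Ct table to delimited text
#'
#' Inverse of [read_ct_table()]; round-trips gene names, sample metadata and
#' Ct values at full precision (up to 15 significant digits).
#'
#' @param x a `ct_table`.
#' @param path output path; `.tsv` writes tab-separated, else comma.
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  stopifnot(inherits(x, "ct_table"))
  sep <- .detect_sep(path)
  fmt <- function(v) formatC(v, digits = 15, format = "g")
  if (layout == "long") {
    n <- length(x$genes); s <- nrow(x$samples)
    df <- data.frame(
      sample_id = rep(x$samples$sample_id, each = n),
      group = rep(x$samples$group, each = n),
      bio_rep = rep(x$samples$bio_rep, each = n),
      tech_rep = rep(x$samples$tech_rep, each = n),
      gene = rep(x$genes, times = s),
      ct = ifelse(is.na(as.vector(x$ct)), "NA", fmt(as.vector(x$ct))),
      stringsAsFactors = FALSE)
  } else {
    df <- x$samples
    for (g in x$genes)
      df[[g]] <- ifelse(is.na(x$ct[g, ]), "NA", fmt(x$ct[g, ]))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Average technical replicates
#'
#' Collapses wells sharing a `sample_id` to a single column per sample by
#' the arithmetic mean of the non-missing technical-replicate Ct values of
#' each gene. Cells whose technical standard deviation exceeds `max_tech_sd`
#' are recorded in the `aggregation_warnings` attribute of the result (a
#' data.frame with columns `sample_id`, `gene`, `tech_sd`, `n`).
#'
#' @param x a `ct_table` (may contain missing wells).
#' @param max_tech_sd warning threshold on the within-sample technical SD,
#'   in cycles. Default 0.5.
#' @param drop_incomplete_samples if `TRUE`, samples for which some gene has
#'   no non-missing replicate are dropped (and listed in the
#'   `dropped_samples` attribute) instead of raising an error.
#' @return a complete `ct_table` with one column per sample and
#'   `tech_rep = 1` throughout.
#' @export
aggregate_technical_replicates <- function(x, max_tech_sd = 0.5,
                                           drop_incomplete_samples = FALSE) {
  stopifnot(inherits(x, "ct_table"))
  ids <- unique(x$samples$sample_id)
  ng <- length(x$genes)
  m <- matrix(NA_real_, ng, length(ids), dimnames = list(x$genes, NULL))
  warn <- list()
  incomplete <- character(0)
  for (j in seq_along(ids)) {
    cols <- which(x$samples$sample_id == ids[j])
    sub <- x$ct[, cols, drop = FALSE]
    nn <- rowSums(!is.na(sub))
    if (any(nn == 0L)) {
      incomplete <- c(incomplete, ids[j])
      if (!drop_incomplete_samples)
        stop("all technical replicates missing for sample '", ids[j],
             "', gene '", x$genes[which(nn == 0L)[1L]], "'")
      next
    }
    m[, j] <- rowMeans(sub, na.rm = TRUE)
    if (ng && ncol(sub) > 1L) {
      sds <- apply(sub, 1L, stats::sd, na.rm = TRUE)
      over <- which(!is.na(sds) & sds > max_tech_sd)
      for (g in over)
        warn[[length(warn) + 1L]] <- data.frame(
          sample_id = ids[j], gene = x$genes[g], tech_sd = sds[g],
          n = nn[g], stringsAsFactors = FALSE)
    }
  }
  keep <- !ids %in% incomplete
  first <- x$samples[!duplicated(x$samples$sample_id), , drop = FALSE]
  smeta <- first[match(ids[keep], first$sample_id), , drop = FALSE]
  smeta$tech_rep <- 1L
  rownames(smeta) <- NULL
  out <- ct_table(m[, keep, drop = FALSE], samples = smeta,
                  amp_factor = x$amp_factor)
  attr(out, "aggregation_warnings") <- if (length(warn))
    do.call(rbind, warn)
  else
    data.frame(sample_id = character(0), gene = character(0),
               tech_sd = numeric(0), n = integer(0))
  attr(out, "dropped_samples") <- incomplete
  out
}

#' Per-gene descriptive Ct statistics
#'
#' @param x a complete (aggregated) `ct_table`.
#' @return a data.frame with one row per gene: `gene`, `n`, `mean`, `sd`,
#'   `se` (= sd / sqrt(n)), `min`, `median`, `max`, all in cycles; gene
#'   order preserved.
#' @export
summarize_ct <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  if (anyNA(x$ct)) stop("aggregate technical replicates first (missing Ct)")
  if (!length(x$genes))
    return(data.frame(gene = character(0), n = integer(0), mean = numeric(0),
                      sd = numeric(0), se = numeric(0), min = numeric(0),
                      median = numeric(0), max = numeric(0)))
  n <- ncol(x$ct)
  sds <- apply(x$ct, 1L, stats::sd)
  data.frame(gene = x$genes, n = n,
             mean = rowMeans(x$ct),
             sd = sds,
             se = sds / sqrt(n),
             min = apply(x$ct, 1L, min),
             median = apply(x$ct, 1L, stats::median),
             max = apply(x$ct, 1L, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative quantities from Ct values
#'
#' Converts Ct values to linear-scale relative quantities using each gene's
#' amplification factor A: Q\\[g, s\\] = A_g^(min_s Ct\\[g, .\\] - Ct\\[g, s\\]).
#' The most abundant (lowest-Ct) sample of each gene is the calibrator, so
#' every row has maximum exactly 1 and Q lies in (0, 1].
#'
#' @param x a complete `ct_table`.
#' @return numeric matrix of relative quantities, same dimnames as `x$ct`.
#' @export
relative_quantities <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  if (anyNA(x$ct)) stop("aggregate technical replicates first (missing Ct)")
  mins <- apply(x$ct, 1L, min)
  x$amp_factor ^ (mins - x$ct)
}
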