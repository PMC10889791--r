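#' Run the complete reference-gene selection pipeline
#'
#' Read -> aggregate technical replicates -> four stability algorithms ->
#' consensus ranking -> V-curve -> optimal number/combination, writing one
#' TSV per method (`<method>.tsv`: gene, value, rank), `genorm_v.tsv`
#' (n, V_n), `consensus.tsv`, `recommendation.json`, `ct_summary.tsv`, an
#' `aggregation_warnings.json` sidecar, and `run_log.txt`.
#'
#' The V-curve is computed on the geNorm ranking (which defines how many
#' genes are needed) while the combination itself is drawn from the head
#' of the consensus ranking.
#'
#' @param input path to a Ct table, or a `ct_table` object.
#' @param out_dir output directory (created if absent).
#' @param layout input layout, `"long"` or `"wide"`.
#' @param group_col name of the metadata column holding group labels
#'   (default `"group"`); set `NULL` to run NormFinder ungrouped.
#' @param methods stability methods to run (all four by default).
#' @param deviation BestKeeper dispersion mode, `"sd"` or `"mad"`.
#' @param cutoff V-curve decision threshold in (0, 1), default 0.15.
#' @param ties rank tie-handling, `"average"` or `"min"`.
#' @param max_tech_sd technical-replicate SD warning threshold, cycles.
#' @param drop_incomplete_samples passed to
#'   [aggregate_technical_replicates()].
#' @param verbose log progress to standard error.
#' @return (invisibly) a list with `stability`, `consensus`, `v_curve`,
#'   `recommendation`, `summary` and `files` (paths written).
#' @export
run_full_analysis <- function(input, out_dir,
                              layout = c("long", "wide"),
                              group_col = "group",
                              methods = c("delta_ct", "genorm",
                                          "normfinder", "bestkeeper"),
                              deviation = "sd", cutoff = 0.15,
                              ties = "average", max_tech_sd = 0.5,
                              drop_incomplete_samples = FALSE,
                              verbose = TRUE) {
  layout <- match.arg(layout)
  if (cutoff <= 0 || cutoff >= 1) stop("config: cutoff must lie in (0, 1)")
  say <- function(...) if (verbose) message("[ctstab] ", ...)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))

  tab <- stage("read", {
    if (inherits(input, "ct_table")) input
    else read_ct_table(input, layout = layout)
  })
  say("read ", length(tab$genes), " genes x ", nrow(tab$samples), " wells")

  if (!is.null(group_col) && group_col != "group") {
    if (!group_col %in% names(tab$samples))
      stop("stage 'read': unknown group column '", group_col, "'",
           call. = FALSE)
    tab$samples$group <- as.character(tab$samples[[group_col]])
  }

  agg <- stage("aggregate", aggregate_technical_replicates(
    tab, max_tech_sd = max_tech_sd,
    drop_incomplete_samples = drop_incomplete_samples))
  warns <- attr(agg, "aggregation_warnings")
  say("aggregated to ", ncol(agg$ct), " samples (",
      nrow(warns), " high-SD warnings)")

  groups <- if (is.null(group_col) || all(is.na(agg$samples$group)))
    NULL else agg$samples$group
  stab <- stage("stability", stability_all(
    agg, groups = if (is.null(groups)) NULL else groups,
    methods = methods, deviation = deviation, ties = ties))

  cons <- NULL; vcurve <- NULL; rec <- NULL
  if (length(stab) >= 2L)
    cons <- stage("consensus", reffinder_geomean(stab))
  if ("genorm" %in% names(stab) && length(agg$genes) >= 3L) {
    genorm_order <- stab$genorm$gene[order(stab$genorm$rank)]
    vcurve <- stage("v_curve",
                    pairwise_variation(agg, genorm_order, cutoff = cutoff))
    if (!is.null(cons))
      rec <- stage("selection", select_optimal(cons, vcurve,
                                               cutoff = cutoff))
  }
  summ <- stage("summary", summarize_ct(agg))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
    p
  }
  for (m in names(stab))
    wtsv(as.data.frame(stab[[m]])[order(stab[[m]]$rank),
                                  c("gene", "value", "rank")],
         paste0(m, ".tsv"))
  if (!is.null(vcurve)) wtsv(as.data.frame(vcurve), "genorm_v.tsv")
  if (!is.null(cons)) wtsv(as.data.frame(cons), "consensus.tsv")
  wtsv(summ, "ct_summary.tsv")
  if (!is.null(rec)) {
    p <- file.path(out_dir, "recommendation.json")
    jsonlite::write_json(unclass(rec), p, auto_unbox = TRUE, digits = NA)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "aggregation_warnings.json")
  jsonlite::write_json(warns, p, digits = NA)
  files <- c(files, p)

  log_lines <- c(
    paste0("ctstab ", as.character(utils::packageVersion("ctstab"))),
    paste0("R ", R.version.string),
    paste0("input: ", if (is.character(input)) input else "<ct_table>"),
    paste0("config: layout=", layout, " group_col=",
           if (is.null(group_col)) "<none>" else group_col,
           " methods=", paste(names(stab), collapse = ","),
           " deviation=", deviation, " cutoff=", cutoff, " ties=", ties,
           " max_tech_sd=", max_tech_sd),
    paste0("genes: ", length(agg$genes), "  samples: ", ncol(agg$ct)),
    paste0("aggregation warnings: ", nrow(warns)),
    if (length(attr(agg, "dropped_samples")))
      paste0("dropped samples: ",
             paste(attr(agg, "dropped_samples"), collapse = ", ")),
    if (!is.null(rec))
      paste0("recommendation: ", paste(rec$combination, collapse = " + "),
             " (n=", rec$optimal_n, ", V=", signif(rec$v_used, 4),
             if (rec$fallback) ", FALLBACK" else "", ")"))
  p <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, p)
  files <- c(files, p)
  say("wrote ", length(files), " files to ", out_dir)

  invisible(list(stability = stab, consensus = cons, v_curve = vcurve,
                 recommendation = rec, summary = summ, files = files))
}
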