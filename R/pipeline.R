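# Per-family orchestration: filtering rules, best-copy selection, flank
# extension, and the full family run
# (filter -> root -> merge -> reconcile -> homologies -> K-score ranking).

#' Pipeline configuration
#'
#' @param min_family_size families with fewer genes are skipped (default 3).
#' @param max_group_size maximum genes per tree-building group (default 400).
#' @param fast_mode_threshold total input sequence (bp) above which fast
#'   tree building is used (default 150000, strict).
#' @param dcs_threshold duplications below this DCS are dubious (default
#'   0.25).
#' @param synteny_window synteny search window in bp (default 5000).
#' @param flank_factor genomic flank extension as a multiple of gene length
#'   (default 2).
#' @param seed master seed forwarded to the synthetic providers.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_family_size = 3L, max_group_size = 400L,
                            fast_mode_threshold = 150000, dcs_threshold = 0.25,
                            synteny_window = 5000, flank_factor = 2.0,
                            seed = 1L) {
  stopifnot(min_family_size > 0, max_group_size > 0, fast_mode_threshold > 0,
            dcs_threshold > 0, synteny_window > 0, flank_factor >= 0)
  structure(list(min_family_size = as.integer(min_family_size),
                 max_group_size = as.integer(max_group_size),
                 fast_mode_threshold = fast_mode_threshold,
                 dcs_threshold = dcs_threshold,
                 synteny_window = synteny_window,
                 flank_factor = flank_factor, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Family size filter
#'
#' A family needs at least `min_family_size` genes to proceed to
#' phylogenetic inference.
#'
#' @param genes character vector of gene ids.
#' @param min_family_size minimum size (default 3).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_family <- function(genes, min_family_size = 3L) {
  length(genes) >= min_family_size
}

#' Select the best copy among redundant gene annotations
#'
#' When several copies of a gene are annotated in a fragmented assembly,
#' only the copy at the locus with the highest alignment identity is kept.
#' Ties go to the lexicographically smallest gene id.
#'
#' @param copies data.frame with columns `gene_id` and `identity` (in
#'   \[0, 1\]).
#' @return the selected gene id.
#' @export
select_best_copy <- function(copies) {
  if (!nrow(copies)) stop("no copies supplied")
  best <- copies[copies$identity == max(copies$identity), , drop = FALSE]
  min(best$gene_id)
}

#' Extend a gene interval by flanking sequence
#'
#' The interval is extended by `factor` times the gene length on both the 5'
#' and 3' ends (strand-agnostic), clipped to the chromosome; with the
#' default factor 2 an unclipped window is 5 gene-lengths long.
#'
#' @param gene list or one-row data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive) and optionally `strand`.
#' @param factor flank multiple (default 2).
#' @param chrom_length chromosome length in bp.
#' @return list with `chrom`, `start`, `end` of the extended interval.
#' @export
flank_region <- function(gene, factor = 2.0, chrom_length) {
  start <- gene$start; end <- gene$end
  stopifnot(start <= end)
  if (start < 1 || end > chrom_length)
    stop("gene lies outside the chromosome")
  L <- end - start + 1
  list(chrom = gene$chrom,
       start = max(1, start - factor * L),
       end = min(chrom_length, end + factor * L))
}

#' Run the analysis for one gene family
#'
#' Executes the per-family pipeline: size filter, duplication-loss rooting
#' of every input tree, consensus merging, reconciliation with dubious-node
#' flagging, orthologue/paralogue inference and K-score ranking of the
#' input trees against the final tree. Any stage error is caught and
#' reported as a structured diagnostic for that family only.
#'
#' @param family_id identifier used in reports and file names.
#' @param input_trees named list of candidate [gene_tree()]s over the same
#'   gene set.
#' @param species_tree the [species_tree()].
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the final NHX tree, the
#'   homology and ranking tables (TSV) and a JSON report are written there.
#' @return a list of class `family_report`.
#' @export
run_family <- function(family_id, input_trees, species_tree,
                       config = pipeline_config(), out_dir = NULL) {
  report <- list(family_id = family_id, status = "ok", stages = character(0))
  stage <- function(name, expr) {
    report$stages <<- c(report$stages, name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  result <- tryCatch({
    genes <- leaf_genes(input_trees[[1L]])
    report$n_genes <- length(genes)
    if (!filter_family(genes, config$min_family_size)) {
      report$status <- "filtered"
      report$reason <- sprintf("fewer than %d genes", config$min_family_size)
      return(finish_family_report(report, out_dir))
    }
    report$oversized <- length(genes) > config$max_group_size
    rooted <- stage("root", lapply(input_trees, root_by_dl, species_tree))
    merged <- stage("merge", mmerge(rooted, species_tree))
    rec <- stage("reconcile", {
      r <- reconcile(merged, species_tree)
      r$tree$supporters <- merged$supporters
      flag_dubious(r, config$dcs_threshold)
    })
    pairs <- stage("homology", infer_homologies(rec, config$dcs_threshold))
    ranking <- stage("kscore", rank_trees(rec$tree, rooted))
    final <- rec$tree
    attr(final, "input_ids") <- attr(merged, "input_ids")
    report$tree <- write_newick(final)
    report$n_duplications <- rec$total_dup
    report$n_losses <- rec$total_loss
    report$n_dubious <- sum(final$event == "dubious", na.rm = TRUE)
    report$homologies <- pairs
    report$ranking <- ranking
    report$support <- branch_support_summary(final)
    report$final_tree <- final
    finish_family_report(report, out_dir)
  }, error = function(e) {
    report$status <- "error"
    report$message <- conditionMessage(e)
    finish_family_report(report, out_dir)
  })
  result
}

finish_family_report <- function(report, out_dir) {
  class(report) <- "family_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    base <- file.path(out_dir, report$family_id)
    if (!is.null(report$tree))
      writeLines(report$tree, paste0(base, ".nhx"))
    if (!is.null(report$homologies))
      utils::write.table(report$homologies, paste0(base, ".homologies.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$ranking))
      utils::write.table(report$ranking, paste0(base, ".ranking.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    json <- report[setdiff(names(report), "final_tree")]
    jsonlite::write_json(json, paste0(base, ".report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}

#' @export
print.family_report <- function(x, ...) {
  cat(sprintf("family %s: %s (%d genes)\n", x$family_id, x$status,
              x$n_genes %||% NA_integer_))
  if (x$status == "ok") {
    cat(sprintf("  %d duplications (%d dubious), %g losses, %d homology pairs\n",
                x$n_duplications, x$n_dubious, x$n_losses,
                nrow(x$homologies)))
  }
  invisible(x)
}
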