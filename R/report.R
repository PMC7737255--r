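# Pipeline driver: read -> build -> detect -> derive -> write, with a
# machine-readable run report. Counts in the report are the row counts of
# the emitted files; stage timings are informational and are kept out of
# report.json so artifacts stay byte-identical across runs.

#' Run the full fire ladder detection pipeline
#'
#' Reads the RRF inputs, builds and de-cycles the per-terminology
#' hierarchies, enumerates all ordered triples of the configured SABs,
#' detects fire ladder patterns, derives both candidate data sets and the
#' per-triple summary, and writes `patterns.tsv`, `patterns.json`,
#' `summary.tsv`, `dataset1.tsv`, `dataset2.tsv`, `removed_edges.tsv`, and
#' `report.json` under `out_dir`.
#'
#' @param mrconso,mrrel paths to the RRF input files.
#' @param out_dir output directory (created if needed).
#' @param config a [source_config()] or the path of a key-value
#'   configuration file ([read_source_config()]).
#' @param quiet suppress per-stage log messages.
#' @return object of class `fl_report` (invisibly printable): SAB list,
#'   per-SAB atom/node/edge counts, removed-edge count, triple count,
#'   pattern count, data set counts, stage timings in seconds.
#' @export
run_detect <- function(mrconso, mrrel, out_dir,
                       config = umls_default_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_source_config(config)
  stopifnot(inherits(config, "source_config"))
  say <- function(...) if (!quiet) message(...)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  atoms <- stage("read_mrconso", read_mrconso(mrconso, config))
  say(sprintf("read %d atom rows", nrow(atoms)))
  rels <- stage("read_mrrel", read_mrrel(mrrel, config))
  say(sprintf("read %d IS-A rows", nrow(rels)))
  dags <- stage("build_ontdag", build_ontdag(atoms, rels, config))
  if (nrow(dags$removed))
    say(sprintf("removed %d self-loop/cycle edge(s)", nrow(dags$removed)))
  triples <- stage("enumerate_triples", enumerate_triples(config$included_sabs))
  say(sprintf("enumerated %d ordered terminology triples", nrow(triples)))
  patterns <- stage("detect_fire_ladders", detect_fire_ladders(dags, triples))
  say(sprintf("detected %d fire ladder pattern(s)", nrow(patterns)))
  patterns <- stage("annotate", annotate_patterns(patterns, atoms))
  ds1 <- stage("dataset1", build_dataset1(patterns))
  ds2 <- stage("dataset2", build_dataset2(dags, patterns, config$dataset2_mode))
  summ <- stage("summarize", summarize_by_triple(patterns))

  stage("write", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_patterns(patterns, file.path(out_dir, "patterns.tsv"), "tsv")
    write_patterns(patterns, file.path(out_dir, "patterns.json"), "json")
    fwrite(summ, file.path(out_dir, "summary.tsv"), sep = "\t", eol = "\n")
    fwrite(ds1, file.path(out_dir, "dataset1.tsv"), sep = "\t", eol = "\n")
    fwrite(ds2, file.path(out_dir, "dataset2.tsv"), sep = "\t", eol = "\n")
    fwrite(dags$removed, file.path(out_dir, "removed_edges.tsv"),
           sep = "\t", eol = "\n")
  })

  report <- structure(list(
    sabs = config$included_sabs,
    atom_counts = vapply(dags$presence, length, 1L),
    node_counts = vapply(dags$graphs, function(g) length(graph_nodes(g)), 1L),
    edge_counts = vapply(dags$graphs, function(g) nrow(graph_edges(g)), 1L),
    removed_edge_count = nrow(dags$removed),
    dangling_edge_count = dags$dangling_edge_count,
    triple_count = nrow(triples),
    pattern_count = nrow(patterns),
    dataset1_count = nrow(ds1),
    dataset2_count = nrow(ds2),
    dataset2_mode = config$dataset2_mode,
    timings = timings
  ), class = "fl_report")

  json <- report[setdiff(names(report), "timings")]
  write_json(json, file.path(out_dir, "report.json"), auto_unbox = TRUE)
  say(sprintf("total elapsed %.2fs", sum(unlist(timings))))
  invisible(report)
}

#' @export
print.fl_report <- function(x, ...) {
  cat("<fl_report>\n")
  cat("  SABs:          ", paste(x$sabs, collapse = ", "), "\n", sep = "")
  cat("  triples:       ", x$triple_count, "\n")
  cat("  patterns:      ", x$pattern_count, "\n")
  cat("  data set 1:    ", x$dataset1_count, "\n")
  cat("  data set 2:    ", x$dataset2_count, " (", x$dataset2_mode, ")\n", sep = "")
  cat("  removed edges: ", x$removed_edge_count, "\n")
  invisible(x)
}

#' Compute the two-rater agreement statistics
#'
#' Accepts exactly one of: the four contingency cells, the marginal counts
#' (solved via [contingency_from_marginals()]), or a unit-level rating
#' table (data frame or TSV path, tabulated via [tabulate_ratings()]).
#'
#' @param cells numeric vector `c(a, b, c, d)`.
#' @param marginals numeric vector `c(n, r1_import, r2_import, both_import)`.
#' @param ratings data frame or TSV path of unit-level decisions.
#' @return object of class `fl_agreement`: the contingency, `kappa` and
#'   `alpha` at full precision, and `kappa_printed` / `alpha_printed`
#'   rounded half-up to 3 and 2 decimals respectively.
#' @export
run_agreement <- function(cells = NULL, marginals = NULL, ratings = NULL) {
  n_given <- sum(!is.null(cells), !is.null(marginals), !is.null(ratings))
  if (n_given != 1L)
    stop("provide exactly one of `cells`, `marginals`, `ratings`", call. = FALSE)
  ct <- if (!is.null(cells)) {
    if (length(cells) != 4L) stop("`cells` must be c(a, b, c, d)", call. = FALSE)
    rating_contingency(cells[1L], cells[2L], cells[3L], cells[4L])
  } else if (!is.null(marginals)) {
    if (length(marginals) != 4L)
      stop("`marginals` must be c(n, r1_import, r2_import, both_import)", call. = FALSE)
    contingency_from_marginals(marginals[1L], marginals[2L], marginals[3L],
                               marginals[4L])
  } else {
    if (is.character(ratings)) ratings <- read_ratings(ratings)
    tabulate_ratings(ratings)
  }
  kappa <- cohen_kappa(ct)
  alpha <- krippendorff_alpha(ct)
  structure(list(contingency = ct, kappa = kappa, alpha = alpha,
                 kappa_printed = round_half_up(kappa, 3L),
                 alpha_printed = round_half_up(alpha, 2L)),
            class = "fl_agreement")
}

#' @export
print.fl_agreement <- function(x, ...) {
  ct <- x$contingency
  cat(sprintf("n = %d  (a=%d, b=%d, c=%d, d=%d)\n",
              ct$n, ct$a, ct$b, ct$c, ct$d))
  cat(sprintf("Cohen's kappa:        %.3f  (full precision %.10f)\n",
              x$kappa_printed, x$kappa))
  cat(sprintf("Krippendorff's alpha: %.2f   (full precision %.10f)\n",
              x$alpha_printed, x$alpha))
  invisible(x)
}
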