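#' Source-vocabulary configuration
#'
#' Bundles the filters applied when reading a UMLS-style RRF release and the
#' knobs of the downstream pipeline: which source vocabularies (SABs)
#' participate, the atom language, whether suppressed rows are dropped, the
#' depth bound used during cycle removal, and the default Data Set 2 mode.
#'
#' @param included_sabs character vector of SABs to retain; non-empty, no
#'   duplicates.
#' @param excluded_sabs character vector of SABs explicitly excluded
#'   (disjoint from `included_sabs`). Exclusion is redundant with inclusion
#'   filtering but kept explicit so a configuration documents *why* a
#'   vocabulary is absent (e.g. subsets of another source).
#' @param language atom language code retained from MRCONSO (default
#'   `"ENG"`).
#' @param drop_suppressed drop rows whose SUPPRESS flag is not `"N"`
#'   (default `TRUE`).
#' @param max_cycle_depth depth bound (levels) for the depth-first cycle
#'   sweep; cycles longer than this bound may survive. Default 5.
#' @param dataset2_mode default mode for [build_dataset2()]: `"anchored"` or
#'   `"strict"`.
#' @param seed optional integer seed recorded for fixture generation runs.
#' @return an object of class `source_config`.
#' @seealso [umls_default_config()], [read_source_config()]
#' @export
source_config <- function(included_sabs,
                          excluded_sabs = character(),
                          language = "ENG",
                          drop_suppressed = TRUE,
                          max_cycle_depth = 5L,
                          dataset2_mode = c("anchored", "strict"),
                          seed = NULL) {
  included_sabs <- as.character(included_sabs)
  excluded_sabs <- as.character(excluded_sabs)
  if (length(included_sabs) == 0L || !all(nzchar(included_sabs)))
    stop("`included_sabs` must be a non-empty vector of non-empty SABs", call. = FALSE)
  if (anyDuplicated(included_sabs))
    stop("`included_sabs` contains duplicates: ",
         paste(unique(included_sabs[duplicated(included_sabs)]), collapse = ", "),
         call. = FALSE)
  overlap <- intersect(included_sabs, excluded_sabs)
  if (length(overlap))
    stop("SABs cannot be both included and excluded: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  stopifnot(is.character(language), length(language) == 1L, nzchar(language))
  max_cycle_depth <- as.integer(max_cycle_depth)
  if (is.na(max_cycle_depth) || max_cycle_depth < 1L)
    stop("`max_cycle_depth` must be a positive integer", call. = FALSE)
  dataset2_mode <- match.arg(dataset2_mode)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(
      included_sabs = included_sabs,
      excluded_sabs = excluded_sabs,
      language = language,
      drop_suppressed = isTRUE(drop_suppressed),
      max_cycle_depth = max_cycle_depth,
      dataset2_mode = dataset2_mode,
      seed = seed
    ),
    class = "source_config"
  )
}

#' Default configuration: the ten English IS-A terminologies
#'
#' The ten UMLS source vocabularies whose IS-A hierarchies are mined for
#' fire ladder patterns, under 2018AB release SAB naming, with the two
#' subset vocabularies (the veterinary extension of SNOMED CT and UWDA,
#' a subset of FMA) listed as excluded.
#'
#' @param ... overrides passed on to [source_config()].
#' @return a `source_config`.
#' @export
umls_default_config <- function(...) {
  defaults <- list(
    included_sabs = c("SNOMEDCT_US", "NCI", "MEDCIN", "ATC", "CPM",
                      "CPT", "FMA", "GO", "HPO", "UMD"),
    excluded_sabs = c("SNOMEDCT_VET", "UWDA")
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(source_config, args)
}

#' Read a configuration from a plain-text key-value file
#'
#' Lines have the form `key = value`; blank lines and lines starting with
#' `#` are ignored. List values are comma-separated. Recognized keys:
#' `sabs`, `excluded_sabs`, `language`, `drop_suppressed`,
#' `max_cycle_depth`, `dataset2_mode`, `seed`.
#'
#' @param path file path.
#' @return a `source_config`.
#' @export
read_source_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad))
    stop("malformed config line: ", lines[which(bad)[1L]], call. = FALSE)
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  known <- c("sabs", "excluded_sabs", "language", "drop_suppressed",
             "max_cycle_depth", "dataset2_mode", "seed")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  get_val <- function(key) if (key %in% keys) trimws(vals[match(key, keys)]) else NULL
  split_list <- function(x) {
    if (is.null(x) || !nzchar(x)) return(character())
    trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  }
  args <- list()
  if (!is.null(get_val("sabs"))) args$included_sabs <- split_list(get_val("sabs"))
  args$excluded_sabs <- split_list(get_val("excluded_sabs"))
  if (!is.null(get_val("language"))) args$language <- get_val("language")
  if (!is.null(get_val("drop_suppressed")))
    args$drop_suppressed <- tolower(get_val("drop_suppressed")) %in% c("true", "yes", "1")
  if (!is.null(get_val("max_cycle_depth")))
    args$max_cycle_depth <- as.integer(get_val("max_cycle_depth"))
  if (!is.null(get_val("dataset2_mode"))) args$dataset2_mode <- get_val("dataset2_mode")
  if (!is.null(get_val("seed"))) args$seed <- as.integer(get_val("seed"))
  if (is.null(args$included_sabs))
    stop("config file must set `sabs`", call. = FALSE)
  do.call(source_config, args)
}

#' @export
print.source_config <- function(x, ...) {
  cat("<source_config>\n")
  cat("  included SABs:  ", paste(x$included_sabs, collapse = ", "), "\n", sep = "")
  if (length(x$excluded_sabs))
    cat("  excluded SABs:  ", paste(x$excluded_sabs, collapse = ", "), "\n", sep = "")
  cat("  language:       ", x$language, "\n", sep = "")
  cat("  drop suppressed:", x$drop_suppressed, "\n")
  cat("  max cycle depth:", x$max_cycle_depth, "\n")
  cat("  dataset2 mode:  ", x$dataset2_mode, "\n", sep = "")
  invisible(x)
}
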