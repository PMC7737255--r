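# Candidate data sets derived from detected fire ladder patterns.
#
# Data Set 1: import B2 into the target terminology as a child of A1 and a
# parent of A3 (= C3). Patterns sharing (target, a1, b2, c3) but produced
# by different (upper, lower) source permutations are one candidate.
#
# Data Set 2: import C3 into the upper source B as a child of B2 —
# constrained from above only.

#' Build Data Set 1 (import B2 into the target terminology)
#'
#' Groups patterns by (target SAB, a1, b2, c3); each group becomes one
#' import candidate carrying all contributing (upper, lower) source pairs.
#' `|result| <= |patterns|`, and the operation is idempotent in the sense
#' that re-grouping the candidate keys changes nothing.
#'
#' @param patterns pattern collection from [detect_fire_ladders()]
#'   (optionally name-annotated).
#' @return `data.table` with columns `target_sab`, `a1`, `b2`, `c3`,
#'   name columns when present in the input, `sources` (semicolon-joined
#'   sorted `upper/lower` pairs) and `n_sources`.
#' @export
build_dataset1 <- function(patterns) {
  p <- as.data.table(patterns)
  if (!nrow(p)) {
    return(data.table(target_sab = character(), a1 = character(),
                      b2 = character(), c3 = character(),
                      sources = character(), n_sources = integer()))
  }
  has_names <- all(c("a1_name", "b2_name", "c3_name") %in% names(p))
  p <- copy(p)
  p[, src := paste0(upper_sab, "/", lower_sab)]
  out <- p[, {
    s <- csort(unique(src))
    res <- list(sources = paste(s, collapse = ";"), n_sources = length(s))
    if (has_names) res <- c(list(a1_name = a1_name[1L], b2_name = b2_name[1L],
                                 c3_name = c3_name[1L]), res)
    res
  }, by = .(target_sab, a1, b2, c3)]
  setorder(out, target_sab, a1, b2, c3)
  out[]
}

#' Build Data Set 2 (import C3 into the upper source terminology)
#'
#' In `"strict"` mode the result is the distinct (upper, lower, b2, c3)
#' projection of the pattern set. In `"anchored"` mode (the default), every
#' stem (a1, b2, upper, lower) that appears in at least one pattern admits
#' *all* children of b2 in the lower source that are absent from the upper
#' source — siblings of the pattern's own c3 under the same anchored stem
#' are legitimate candidates for the same horizontal import, which is why
#' this data set can be larger than the pattern set. Strict output is a
#' subset of anchored output on every input.
#'
#' @param dags the `ontdag` the patterns were detected on (used in anchored
#'   mode to look up children and presence).
#' @param patterns pattern collection from [detect_fire_ladders()].
#' @param mode `"anchored"` or `"strict"`.
#' @return `data.table` with columns `upper_sab`, `lower_sab`, `b2`, `c3`,
#'   `anchor_a1` (first anchoring a1 in canonical order; `NA` never occurs
#'   from pattern-derived stems), unique by (upper, lower, b2, c3).
#' @export
build_dataset2 <- function(dags, patterns, mode = c("anchored", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dags, "ontdag"))
  p <- as.data.table(patterns)
  empty <- data.table(upper_sab = character(), lower_sab = character(),
                      b2 = character(), c3 = character(),
                      anchor_a1 = character())
  if (!nrow(p)) return(empty)
  if (mode == "strict") {
    out <- p[, .(anchor_a1 = csort(a1)[1L]), by = .(upper_sab, lower_sab, b2, c3)]
  } else {
    stems <- unique(p[, .(a1, b2, upper_sab, lower_sab)])
    setorder(stems, upper_sab, lower_sab, b2, a1)
    acc <- list()
    for (i in seq_len(nrow(stems))) {
      B <- stems$upper_sab[i]; C <- stems$lower_sab[i]
      b2i <- stems$b2[i]
      kids <- dags$graphs[[C]]$children[[b2i]] %||% character()
      kids <- kids[!(kids %chin% dags$presence[[B]])]
      if (length(kids)) {
        acc[[length(acc) + 1L]] <- data.table(
          upper_sab = B, lower_sab = C, b2 = b2i, c3 = csort(kids),
          anchor_a1 = stems$a1[i])
      }
    }
    if (!length(acc)) return(empty)
    out <- rbindlist(acc)
    setorder(out, upper_sab, lower_sab, b2, c3, anchor_a1)
    out <- out[, .(anchor_a1 = anchor_a1[1L]), by = .(upper_sab, lower_sab, b2, c3)]
  }
  setorder(out, upper_sab, lower_sab, b2, c3)
  setcolorder(out, c("upper_sab", "lower_sab", "b2", "c3", "anchor_a1"))
  out[]
}

#' Summarize pattern counts by unordered terminology triple
#'
#' Groups patterns by the unordered set of their three SABs (all source
#' permutations of the same three terminologies pool into one row). Counts
#' sum to the total pattern count.
#'
#' @param patterns pattern collection from [detect_fire_ladders()].
#' @return `data.table` with columns `sab_set` (comma-joined sorted SABs)
#'   and `pattern_count`, ordered by decreasing count then `sab_set`.
#' @export
summarize_by_triple <- function(patterns) {
  p <- as.data.table(patterns)
  if (!nrow(p))
    return(data.table(sab_set = character(), pattern_count = integer()))
  key <- vapply(seq_len(nrow(p)), function(i) {
    paste(csort(c(p$target_sab[i], p$upper_sab[i], p$lower_sab[i])),
          collapse = ",")
  }, "")
  out <- data.table(sab_set = key)[, .(pattern_count = .N), by = sab_set]
  setorder(out, -pattern_count, sab_set)
  out[]
}
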