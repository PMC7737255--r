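# Two-rater agreement statistics over binary import / non-import
# decisions, parameterized by the 2x2 contingency
#   a = both import, b = rater1 import only, c = rater2 import only,
#   d = both non-import.

#' Construct a 2x2 rating contingency
#'
#' @param a both-import count.
#' @param b rater-1-import / rater-2-non-import count.
#' @param c rater-1-non-import / rater-2-import count.
#' @param d both-non-import count.
#' @return object of class `rating_contingency` (list `a`, `b`, `c`, `d`,
#'   `n`).
#' @export
rating_contingency <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  cells_int <- suppressWarnings(as.integer(cells))
  if (any(is.na(cells_int)) || any(cells_int != cells) || any(cells_int < 0L))
    stop("contingency cells must be non-negative integers", call. = FALSE)
  n <- sum(cells_int)
  if (n == 0L) stop("contingency is empty (n = 0)", call. = FALSE)
  structure(list(a = cells_int[[1L]], b = cells_int[[2L]],
                 c = cells_int[[3L]], d = cells_int[[4L]], n = n),
            class = "rating_contingency")
}

#' @export
print.rating_contingency <- function(x, ...) {
  cat("<rating_contingency> n =", x$n, "\n")
  m <- matrix(c(x$a, x$b, x$c, x$d), 2L, 2L, byrow = TRUE,
              dimnames = list(rater1 = c("import", "non_import"),
                              rater2 = c("import", "non_import")))
  print(m)
  invisible(x)
}

#' Solve the contingency cells from marginal counts
#'
#' Given the number of rated units, each rater's import count, and the
#' both-import count, the four cells are uniquely determined:
#' `a = both_import`, `b = r1_import - a`, `c = r2_import - a`,
#' `d = n - a - b - c`.
#'
#' @param n total rated units.
#' @param r1_import rater 1's import count.
#' @param r2_import rater 2's import count.
#' @param both_import count of units both raters marked import.
#' @return a [rating_contingency()].
#' @export
contingency_from_marginals <- function(n, r1_import, r2_import, both_import) {
  a <- both_import
  b <- r1_import - a
  c <- r2_import - a
  d <- n - a - b - c
  lab <- c(a = a, b = b, c = c, d = d)
  neg <- lab < 0
  if (any(neg))
    stop("inconsistent marginals: derived cell ",
         paste(sprintf("%s = %d", names(lab)[neg], lab[neg]), collapse = ", "),
         " is negative", call. = FALSE)
  rating_contingency(a, b, c, d)
}

#' Cohen's kappa for two raters
#'
#' `kappa = (po - pe) / (1 - pe)` with observed agreement
#' `po = (a + d)/n` and chance agreement
#' `pe = ((a+b)(a+c) + (c+d)(b+d)) / n^2`.
#'
#' @param ct a [rating_contingency()].
#' @return kappa in \[-1, 1\], full precision.
#' @export
cohen_kappa <- function(ct) {
  stopifnot(inherits(ct, "rating_contingency"))
  n <- ct$n
  po <- (ct$a + ct$d) / n
  pe <- ((ct$a + ct$b) * (ct$a + ct$c) + (ct$c + ct$d) * (ct$b + ct$d)) / n^2
  if (pe >= 1)
    stop("Cohen's kappa undefined: chance agreement pe = 1 ",
         "(all ratings fall in one category)", call. = FALSE)
  (po - pe) / (1 - pe)
}

#' Krippendorff's alpha for two raters, binary nominal, no missing data
#'
#' Closed-form special case: observed disagreement `Do = (b + c)/n`;
#' with value frequencies `n_imp = 2a + b + c`, `n_non = 2d + b + c` over
#' `N = 2n` ratings, expected disagreement `De = 2 n_imp n_non / (N(N-1))`;
#' `alpha = 1 - Do/De`. Equals the general coincidence-matrix computation
#' for this design.
#'
#' @param ct a [rating_contingency()].
#' @return alpha (at most 1), full precision.
#' @export
krippendorff_alpha <- function(ct) {
  stopifnot(inherits(ct, "rating_contingency"))
  n <- ct$n
  N <- 2 * n
  if (N < 2) stop("need at least one rated unit", call. = FALSE)
  n_imp <- 2 * ct$a + ct$b + ct$c
  n_non <- 2 * ct$d + ct$b + ct$c
  De <- 2 * n_imp * n_non / (N * (N - 1))
  if (De == 0)
    stop("Krippendorff's alpha undefined: expected disagreement De = 0 ",
         "(fewer than two distinct values observed)", call. = FALSE)
  Do <- (ct$b + ct$c) / n
  1 - Do / De
}

#' Tabulate a two-rater decision table into a contingency
#'
#' @param table data frame with three columns: unit id, rater 1 decision,
#'   rater 2 decision; decisions must be `"import"` or `"non_import"`.
#' @return a [rating_contingency()].
#' @export
tabulate_ratings <- function(table) {
  t <- as.data.frame(table)
  if (ncol(t) < 3L)
    stop("rating table needs columns: unit id, rater 1, rater 2", call. = FALSE)
  if (nrow(t) == 0L) stop("rating table is empty", call. = FALSE)
  ids <- as.character(t[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate unit id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  r1 <- as.character(t[[2L]])
  r2 <- as.character(t[[3L]])
  valid <- c("import", "non_import")
  bad <- !(r1 %in% valid) | !(r2 %in% valid)
  if (any(bad))
    stop("invalid decision value(s) at unit id(s): ",
         paste(ids[bad], collapse = ", "),
         " (must be 'import' or 'non_import')", call. = FALSE)
  rating_contingency(
    a = sum(r1 == "import" & r2 == "import"),
    b = sum(r1 == "import" & r2 == "non_import"),
    c = sum(r1 == "non_import" & r2 == "import"),
    d = sum(r1 == "non_import" & r2 == "non_import")
  )
}

#' Expand a contingency into a unit-level rating table
#'
#' Inverse of [tabulate_ratings()] up to unit labeling; useful for
#' round-trip checks and for feeding tools that require unit-level data.
#'
#' @param ct a [rating_contingency()].
#' @return data frame with columns `unit_id`, `rater1`, `rater2`.
#' @export
expand_contingency <- function(ct) {
  stopifnot(inherits(ct, "rating_contingency"))
  r1 <- c(rep("import", ct$a), rep("import", ct$b),
          rep("non_import", ct$c), rep("non_import", ct$d))
  r2 <- c(rep("import", ct$a), rep("non_import", ct$b),
          rep("import", ct$c), rep("non_import", ct$d))
  data.frame(unit_id = sprintf("u%03d", seq_along(r1)),
             rater1 = r1, rater2 = r2, stringsAsFactors = FALSE)
}

#' Read a two-rater decision table from TSV
#'
#' Expects a header row `unit_id  rater1  rater2`.
#'
#' @param path TSV file path.
#' @return data frame suitable for [tabulate_ratings()].
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path, call. = FALSE)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("unit_id", "rater1", "rater2")
  if (!all(need %in% names(dt)))
    stop("ratings TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  as.data.frame(dt[, need, with = FALSE])
}
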