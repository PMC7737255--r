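# RRF dialect: UTF-8, pipe-delimited, trailing pipe, no quoting or escape
# mechanism. RRF files carry no header; columns are addressed by 2018AB
# position (0-based indices in the release documentation; 1-based here).

# MRCONSO 2018AB: CUI|LAT|TS|LUI|STT|SUI|ISPREF|AUI|SAUI|SCUI|SDUI|SAB|TTY|CODE|STR|SRL|SUPPRESS|CVF|
.mrconso_ncol <- 18L
.mrconso_cols <- c(cui = 1L, lat = 2L, sab = 12L, tty = 13L, code = 14L,
                   str_name = 15L, suppress = 17L)

# MRREL 2018AB: CUI1|AUI1|STYPE1|REL|CUI2|AUI2|STYPE2|RELA|RUI|SRUI|SAB|SL|RG|DIR|SUPPRESS|CVF|
.mrrel_ncol <- 16L
.mrrel_cols <- c(cui1 = 1L, rel = 4L, cui2 = 5L, rela = 8L, sab = 11L,
                 suppress = 15L)

# Split pipe-delimited lines and project the named columns. A line
# "f1|...|fn|" yields exactly n fields (strsplit drops the single empty
# token after the trailing delimiter, and only that one).
.read_rrf <- function(path, ncol, cols, label) {
  if (!file.exists(path)) stop(label, " file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- as.data.table(c(
    lapply(cols, function(i) character()),
    list(line = integer())
  ))
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "|", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != ncol)
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf("%s parse error at line %d: expected %d pipe-delimited fields, found %d",
                 label, lineno[b], ncol, nf[b]), call. = FALSE)
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = ncol, byrow = TRUE)
  dt <- as.data.table(m[, cols, drop = FALSE])
  setnames(dt, names(cols))
  dt[, line := lineno]
  dt
}

.check_cuis <- function(dt, cols, label) {
  for (cl in cols) {
    ok <- is_cui(dt[[cl]])
    if (!all(ok)) {
      b <- which(!ok)[1L]
      stop(sprintf("%s parse error at line %d: malformed CUI '%s' in field %s",
                   label, dt$line[b], dt[[cl]][b], toupper(cl)), call. = FALSE)
    }
  }
  invisible(dt)
}

#' Read concept atoms from an MRCONSO.RRF file
#'
#' Retains only rows whose SAB is configured as included, whose language
#' matches the configured language, and (when `drop_suppressed`) whose
#' SUPPRESS flag is `"N"`. The result is in canonical order
#' (CUI, SAB, code) so downstream output is byte-reproducible.
#'
#' @param path path to a pipe-delimited MRCONSO file (2018AB column layout).
#' @param config a [source_config()].
#' @return `data.table` with columns `cui`, `lat`, `sab`, `tty`, `code`,
#'   `str_name`, `suppress` — one row per retained atom.
#' @export
read_mrconso <- function(path, config) {
  stopifnot(inherits(config, "source_config"))
  dt <- .read_rrf(path, .mrconso_ncol, .mrconso_cols, "MRCONSO")
  had_rows <- nrow(dt) > 0L
  keep <- dt$lat == config$language &
    dt$sab %chin% config$included_sabs &
    !(dt$sab %chin% config$excluded_sabs)
  if (config$drop_suppressed) keep <- keep & dt$suppress == "N"
  out <- dt[keep]
  .check_cuis(out, "cui", "MRCONSO")
  bad_name <- !nzchar(out$str_name)
  if (any(bad_name))
    stop(sprintf("MRCONSO parse error at line %d: empty STR", out$line[which(bad_name)[1L]]),
         call. = FALSE)
  out[, line := NULL]
  setorder(out, cui, sab, code)
  if (had_rows && nrow(out) == 0L)
    warning("MRCONSO: no atom rows retained after filtering", call. = FALSE)
  out[]
}

#' Read IS-A relationship rows from an MRREL.RRF file
#'
#' Only rows encoding a source IS-A link are retained: REL must be `"PAR"`
#' *and* RELA must be `"inverse_isa"`; PAR rows without the attribute are
#' ignored. SAB inclusion and suppression filtering follow the
#' configuration. A row `(CUI1, PAR, CUI2)` states that CUI2 is a parent of
#' CUI1 (CUI1 IS-A CUI2).
#'
#' @inheritParams read_mrconso
#' @return `data.table` with columns `cui1`, `rel`, `cui2`, `rela`, `sab`,
#'   `suppress`, in canonical (SAB, CUI1, CUI2) order.
#' @export
read_mrrel <- function(path, config) {
  stopifnot(inherits(config, "source_config"))
  dt <- .read_rrf(path, .mrrel_ncol, .mrrel_cols, "MRREL")
  had_rows <- nrow(dt) > 0L
  keep <- dt$rel == "PAR" & dt$rela == "inverse_isa" &
    dt$sab %chin% config$included_sabs &
    !(dt$sab %chin% config$excluded_sabs)
  if (config$drop_suppressed) keep <- keep & dt$suppress == "N"
  out <- dt[keep]
  .check_cuis(out, c("cui1", "cui2"), "MRREL")
  out[, line := NULL]
  setorder(out, sab, cui1, cui2)
  if (had_rows && nrow(out) == 0L)
    warning("MRREL: no IS-A rows retained after filtering", call. = FALSE)
  out[]
}

# Empty pattern table with the canonical column set.
.empty_patterns <- function() {
  data.table(target_sab = character(), upper_sab = character(),
             lower_sab = character(), a1 = character(),
             b2 = character(), c3 = character())
}

# Coerce a pattern collection to canonical column order and sort.
.canonical_patterns <- function(patterns) {
  p <- as.data.table(patterns)
  need <- c("target_sab", "upper_sab", "lower_sab", "a1", "b2", "c3")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("pattern collection lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in c("a1_name", "b2_name", "c3_name"))
    if (!nm %in% names(p)) p[, (nm) := ""]
  p <- p[, c(need, c("a1_name", "b2_name", "c3_name")), with = FALSE]
  setorder(p, target_sab, upper_sab, lower_sab, a1, b2, c3)
  p
}

#' Write detected patterns to TSV or JSON
#'
#' Output is canonically sorted (target, upper, lower SAB, then A1, B2, C3
#' CUIs) so that identical pattern sets produce byte-identical files
#' regardless of input order.
#'
#' @param patterns pattern collection as returned by
#'   [detect_fire_ladders()] (optionally name-annotated via
#'   [annotate_patterns()]).
#' @param path output file path.
#' @param format `"tsv"` (tab-separated with header) or `"json"` (array of
#'   pattern objects).
#' @return the output path, invisibly.
#' @export
write_patterns <- function(patterns, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  p <- .canonical_patterns(patterns)
  out <- data.table(
    target_sab = p$target_sab, upper_sab = p$upper_sab, lower_sab = p$lower_sab,
    a1_cui = p$a1, a1_name = p$a1_name,
    b2_cui = p$b2, b2_name = p$b2_name,
    c3_cui = p$c3, c3_name = p$c3_name
  )
  if (format == "tsv") {
    fwrite(out, path, sep = "\t", quote = FALSE, eol = "\n", na = "")
  } else {
    writeLines(toJSON(out, dataframe = "rows", pretty = 2L), path, useBytes = TRUE)
  }
  invisible(path)
}
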