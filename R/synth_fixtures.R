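# Synthetic RRF fixture generator. Emits MRCONSO/MRREL files in the exact
# dialect the readers expect, with known ground truth: planted fire
# ladders, near-miss decoys (each violating exactly one of the nine
# constraints), planted IS-A cycles, plus chaff that the default read
# configuration must filter out (a non-English atom, suppressed rows, and
# a CUI shared across SABs without edges).
#
# CUI allocation uses reserved high ranges so synthetic identifiers can
# never collide with the printed identifiers of the worked example:
#   C90xxxxx background, C91xxxxx planted ladders, C92xxxxx decoys,
#   C93xxxxx cycles, C98xxxxx worked-example stand-ins.

#' Specify a synthetic fixture
#'
#' @param sabs at least three distinct SAB strings.
#' @param n_concepts_per_sab concept budget per SAB; planted structures
#'   count against it and at least two background concepts per SAB must
#'   remain (the chaff anchors).
#' @param n_planted_ladders,n_decoys,n_cycles number of planted fire
#'   ladders, single-constraint decoys (decoy `i` violates constraint
#'   `((i-1) mod 9) + 1`), and planted 3-cycles.
#' @param seed integer seed; generation is deterministic (byte-identical
#'   files) for a given spec.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(sabs, n_concepts_per_sab,
                         n_planted_ladders = 0L, n_decoys = 0L,
                         n_cycles = 0L, seed = 1L) {
  sabs <- as.character(sabs)
  if (length(sabs) < 3L || anyDuplicated(sabs))
    stop("`sabs` must list at least three distinct SABs", call. = FALSE)
  n_concepts_per_sab <- as.integer(n_concepts_per_sab)
  if (is.na(n_concepts_per_sab) || n_concepts_per_sab < 1L)
    stop("`n_concepts_per_sab` must be a positive integer", call. = FALSE)
  counts <- c(n_planted_ladders = n_planted_ladders, n_decoys = n_decoys,
              n_cycles = n_cycles)
  counts <- vapply(counts, as.integer, 1L)
  if (any(is.na(counts)) || any(counts < 0L))
    stop("structure counts must be non-negative integers", call. = FALSE)
  structure(list(sabs = sabs, n_concepts_per_sab = n_concepts_per_sab,
                 n_planted_ladders = counts[[1L]], n_decoys = counts[[2L]],
                 n_cycles = counts[[3L]], seed = as.integer(seed)),
            class = "fixture_spec")
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.syn_name <- function(cui) paste("Synthetic concept", substring(cui, 2L))
.syn_code <- function(cui, sab) paste0(sab, ":", substring(cui, 2L))

.write_mrconso <- function(atoms, path) {
  a <- as.data.table(atoms)
  setorder(a, cui, sab, code, lat, suppress)
  aui <- sprintf("A%07d", seq_len(nrow(a)))
  lines <- paste(a$cui, a$lat, "S", "L0000000", "PF", "S0000000", "Y", aui,
                 "", "", "", a$sab, a$tty, a$code, a$str_name, "0",
                 a$suppress, "", sep = "|")
  lines <- paste0(lines, "|")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.write_mrrel <- function(rels, path) {
  r <- as.data.table(rels)
  setorder(r, sab, cui1, cui2, suppress)
  rui <- sprintf("R%08d", seq_len(nrow(r)))
  lines <- paste(r$cui1, "", "CUI", "PAR", r$cui2, "", "CUI", "inverse_isa",
                 rui, "", r$sab, r$sab, "", "", r$suppress, "", sep = "|")
  lines <- paste0(lines, "|")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Generate a synthetic RRF fixture with known ground truth
#'
#' Writes `MRCONSO.RRF`, `MRREL.RRF`, and `ground_truth.json` under `dir`.
#' Planted ladders are detectable; decoys are not (each violates exactly
#' its named constraint); planted 3-cycles are confined to one SAB each.
#' Chaff always includes one French atom, one suppressed atom, one
#' suppressed relationship row, and one background CUI shared into a
#' second SAB as an atom without edges. Background IS-A edges are random
#' but acyclic by construction (edges always point from later to earlier
#' background concepts), so every cycle in the files is a planted one.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return list with `mrconso` and `mrrel` paths, `config` (a
#'   [source_config()] over the fixture's SABs), and `truth`: a list of
#'   `planted_patterns`, `decoys` (with `decoy_id` and violated
#'   `constraint` index), `cycle_edges`, and the retained `atoms` / `rels`
#'   tables as the default configuration reads them back.
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  sabs <- spec$sabs
  pool <- as.matrix(enumerate_triples(sabs))
  npool <- nrow(pool)

  atoms <- list(); rels <- list()
  add_atom <- function(cui, sab, lat = "ENG", suppress = "N",
                       name = .syn_name(cui), code = .syn_code(cui, sab),
                       tty = "PT") {
    atoms[[length(atoms) + 1L]] <<- data.table(
      cui = cui, lat = lat, sab = sab, tty = tty, code = code,
      str_name = name, suppress = suppress)
  }
  add_rel <- function(child, parent, sab, suppress = "N") {
    rels[[length(rels) + 1L]] <<- data.table(
      cui1 = child, cui2 = parent, sab = sab, suppress = suppress)
  }

  # -- planted ladders ------------------------------------------------
  planted <- list()
  for (i in seq_len(spec$n_planted_ladders)) {
    tri <- pool[(i - 1L) %% npool + 1L, ]
    A <- tri[["target"]]; B <- tri[["upper"]]; C <- tri[["lower"]]
    a <- sprintf("C91%05d", 3L * i - 2L)
    b <- sprintf("C91%05d", 3L * i - 1L)
    c3 <- sprintf("C91%05d", 3L * i)
    add_atom(a, A); add_atom(a, B)
    add_atom(b, B); add_atom(b, C)
    add_atom(c3, C); add_atom(c3, A)
    add_rel(b, a, B)    # b2 IS-A a1 in the upper source
    add_rel(c3, b, C)   # c3 IS-A b2 in the lower source
    add_rel(c3, a, A)   # c3 IS-A a1 in the target
    planted[[i]] <- data.table(target_sab = A, upper_sab = B, lower_sab = C,
                               a1 = a, b2 = b, c3 = c3)
  }

  # -- decoys: one knocked-out constraint each ------------------------
  decoys <- list()
  for (j in seq_len(spec$n_decoys)) {
    k <- (j - 1L) %% 9L + 1L
    tri <- pool[(j - 1L) %% npool + 1L, ]
    A <- tri[["target"]]; B <- tri[["upper"]]; C <- tri[["lower"]]
    a <- sprintf("C92%05d", 3L * j - 2L)
    b <- sprintf("C92%05d", 3L * j - 1L)
    c3 <- sprintf("C92%05d", 3L * j)
    # baseline: a full ladder, then one surgical edit per constraint
    if (k != 1L) add_atom(a, A)
    if (k != 2L) add_atom(a, B)
    if (k == 3L) add_atom(a, C)          # a1 must NOT exist in C
    add_atom(b, B)
    if (k == 5L) add_atom(b, A)          # b2 must NOT exist in A
    if (k != 6L) add_atom(b, C)
    add_atom(c3, C)
    if (k == 8L) add_atom(c3, B)         # c3 must NOT exist in B
    add_atom(c3, A)
    if (k != 4L) add_rel(b, a, B)
    if (k != 7L) add_rel(c3, b, C)
    if (k != 9L) add_rel(c3, a, A)
    decoys[[j]] <- data.table(decoy_id = j, constraint = k,
                              target_sab = A, upper_sab = B, lower_sab = C,
                              a1 = a, b2 = b, c3 = c3)
  }

  # -- planted cycles (3-cycles, one SAB each) ------------------------
  cycles <- list()
  for (m in seq_len(spec$n_cycles)) {
    s <- sabs[(m - 1L) %% length(sabs) + 1L]
    x <- sprintf("C93%05d", 3L * m - 2L)
    y <- sprintf("C93%05d", 3L * m - 1L)
    z <- sprintf("C93%05d", 3L * m)
    for (cc in c(x, y, z)) add_atom(cc, s)
    add_rel(y, x, s); add_rel(z, y, s); add_rel(x, z, s)
    cycles[[m]] <- data.table(sab = s,
                              child = c(y, z, x), parent = c(x, y, z))
  }

  # -- budget check ---------------------------------------------------
  atoms_so_far <- if (length(atoms)) rbindlist(atoms) else
    data.table(cui = character(), sab = character())
  rels_so_far <- if (length(rels)) rbindlist(rels) else
    data.table(cui1 = character(), cui2 = character(), sab = character())
  usage <- vapply(sabs, function(s) {
    length(unique(c(atoms_so_far$cui[atoms_so_far$sab == s],
                    rels_so_far$cui1[rels_so_far$sab == s],
                    rels_so_far$cui2[rels_so_far$sab == s])))
  }, 1L)
  n_bg <- spec$n_concepts_per_sab - usage
  if (any(n_bg < 2L))
    stop("infeasible fixture spec: planted structures leave fewer than ",
         "two background concepts in SAB(s) ",
         paste(sabs[n_bg < 2L], collapse = ", "),
         " (raise `n_concepts_per_sab`)", call. = FALSE)

  # -- background concepts and random (acyclic) edges -----------------
  bg <- vector("list", length(sabs)); names(bg) <- sabs
  .with_seed(spec$seed, {
    counter <- 0L
    for (s in sabs) {
      ids <- sprintf("C90%05d", counter + seq_len(n_bg[[s]]))
      counter <- counter + n_bg[[s]]
      bg[[s]] <- ids
      for (cc in ids) add_atom(cc, s)
      for (i2 in seq_along(ids)[-1L]) {
        if (stats::runif(1L) < 0.7) {
          p <- ids[sample.int(i2 - 1L, 1L)]
          add_rel(ids[i2], p, s)  # later concept IS-A earlier: acyclic
        }
      }
    }
  })

  # -- chaff ----------------------------------------------------------
  s1 <- sabs[1L]; s2 <- sabs[2L]
  bg1 <- bg[[s1]][1L]; bg2 <- bg[[s1]][2L]
  add_atom(bg1, s1, lat = "FRE",
           name = paste("Concept synthetique", substring(bg1, 2L)),
           code = paste0(.syn_code(bg1, s1), "-FR"))
  add_atom(bg2, s1, suppress = "O",
           name = paste(.syn_name(bg2), "(suppressed synonym)"),
           code = paste0(.syn_code(bg2, s1), "-SUP"))
  add_atom(bg1, s2, code = .syn_code(bg1, s2))  # CUI shared across SABs
  add_rel(bg2, bg1, s1, suppress = "O")

  # -- write ----------------------------------------------------------
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atoms <- rbindlist(atoms)
  rels <- rbindlist(rels)
  rels[, `:=`(rel = "PAR", rela = "inverse_isa")]
  mrconso <- file.path(dir, "MRCONSO.RRF")
  mrrel <- file.path(dir, "MRREL.RRF")
  .write_mrconso(atoms, mrconso)
  .write_mrrel(rels, mrrel)

  planted <- if (length(planted)) rbindlist(planted) else .empty_patterns()
  setorder(planted, target_sab, upper_sab, lower_sab, a1, b2, c3)
  decoys <- if (length(decoys)) rbindlist(decoys) else
    data.table(decoy_id = integer(), constraint = integer(),
               target_sab = character(), upper_sab = character(),
               lower_sab = character(), a1 = character(),
               b2 = character(), c3 = character())
  cycles <- if (length(cycles)) rbindlist(cycles) else
    data.table(sab = character(), child = character(), parent = character())

  kept_atoms <- atoms[lat == "ENG" & suppress == "N",
                      .(cui, lat, sab, tty, code, str_name, suppress)]
  setorder(kept_atoms, cui, sab, code)
  kept_rels <- rels[suppress == "N", .(cui1, rel, cui2, rela, sab, suppress)]
  setorder(kept_rels, sab, cui1, cui2)

  truth <- list(planted_patterns = planted, decoys = decoys,
                cycle_edges = cycles, atoms = kept_atoms, rels = kept_rels)
  write_json(list(planted_patterns = planted,
                  decoy_descriptions = decoys[, .(decoy_id, constraint)],
                  planted_cycle_edges = cycles),
             file.path(dir, "ground_truth.json"), dataframe = "rows")

  list(mrconso = mrconso, mrrel = mrrel,
       config = source_config(included_sabs = sabs), truth = truth)
}

#' The worked-example fixture: intestinal atresia across HPO, NCIt, SNOMED CT
#'
#' Transcribes the published worked example into RRF form. HPO (target) and
#' NCIt (upper source) share *Intestinal atresia* (HPO `HP:0011100`, NCIt
#' `C84790`); NCIt's child *Large Intestine Atresia* (`C98827`) is SNOMED
#' CT's *Atresia of large intestine* (`204711007`), CUI `C0345203`; SNOMED
#' CT's child *Congenital atresia of rectum* (`91375006`) is HPO's *Rectal
#' atresia* (`HP:0025023`). HPO's *Colonic atresia* (`HP:0010448`, CUI
#' `C0266190`) — whose synonym string "Large intestinal atresia" names a
#' *different* UMLS concept than `C0345203` — is included as the printed
#' confounder child of *Intestinal atresia*. The CUIs of *Intestinal
#' atresia* and *Congenital atresia of rectum* are not part of the printed
#' example, so the synthetic stand-ins `C9800001` / `C9800002` are used.
#'
#' @param dir output directory.
#' @return same shape as [generate_fixture()]; the single expected pattern
#'   (target HPO, upper NCI, lower SNOMEDCT_US) is in
#'   `truth$planted_patterns`.
#' @export
fig3_fixture <- function(dir = tempfile("fig3")) {
  a1 <- "C9800001"   # Intestinal atresia (synthetic stand-in CUI)
  b2 <- "C0345203"   # Large Intestine Atresia / Atresia of large intestine
  c3 <- "C9800002"   # Congenital atresia of rectum (synthetic stand-in CUI)
  conf <- "C0266190" # Colonic atresia

  atoms <- data.table(
    cui = c(a1, c3, conf, a1, b2, b2, c3),
    lat = "ENG",
    sab = c("HPO", "HPO", "HPO", "NCI", "NCI", "SNOMEDCT_US", "SNOMEDCT_US"),
    tty = "PT",
    code = c("HP:0011100", "HP:0025023", "HP:0010448", "C84790", "C98827",
             "204711007", "91375006"),
    str_name = c("Intestinal atresia", "Rectal atresia", "Colonic atresia",
                 "Intestinal atresia", "Large Intestine Atresia",
                 "Atresia of large intestine", "Congenital atresia of rectum"),
    suppress = "N"
  )
  rels <- data.table(
    cui1 = c(c3, conf, b2, c3),
    cui2 = c(a1, a1, a1, b2),
    sab = c("HPO", "HPO", "NCI", "SNOMEDCT_US"),
    suppress = "N"
  )

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mrconso <- file.path(dir, "MRCONSO.RRF")
  mrrel <- file.path(dir, "MRREL.RRF")
  .write_mrconso(atoms, mrconso)
  .write_mrrel(rels, mrrel)

  planted <- data.table(target_sab = "HPO", upper_sab = "NCI",
                        lower_sab = "SNOMEDCT_US", a1 = a1, b2 = b2, c3 = c3)
  rels_full <- copy(rels)[, `:=`(rel = "PAR", rela = "inverse_isa")]
  setcolorder(rels_full, c("cui1", "rel", "cui2", "rela", "sab", "suppress"))
  kept_atoms <- copy(atoms); setorder(kept_atoms, cui, sab, code)
  setorder(rels_full, sab, cui1, cui2)
  truth <- list(planted_patterns = planted,
                decoys = data.table(decoy_id = integer(), constraint = integer()),
                cycle_edges = data.table(sab = character(), child = character(),
                                         parent = character()),
                atoms = kept_atoms, rels = rels_full)
  write_json(list(planted_patterns = planted),
             file.path(dir, "ground_truth.json"), dataframe = "rows")

  list(mrconso = mrconso, mrrel = mrrel,
       config = source_config(included_sabs = c("HPO", "NCI", "SNOMEDCT_US")),
       truth = truth)
}
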