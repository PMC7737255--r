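# Fire ladder detection. A fire ladder over an ordered terminology triple
# (A = target, B = upper source, C = lower source) is a CUI triple
# (a1, b2, c3) satisfying nine constraints:
#   (1) a1 exists in A            (2) a1 exists in B
#   (3) a1 does not exist in C    (4) b2 is a child of a1 in B
#   (5) b2 does not exist in A    (6) b2 exists in C
#   (7) c3 is a child of b2 in C  (8) c3 does not exist in B
#   (9) c3 is a child of a1 in A
# "Exists in T" is atom presence (the concept has at least one retained
# atom in T), not mere participation in T's edge set: a concept can belong
# to a vocabulary without IS-A links, and under the edge-participation
# reading constraints 1, 2, 6 would be implied by 9, 4, 7 and could never
# fail on their own.

#' Enumerate ordered terminology triples
#'
#' All ordered 3-permutations without repetition of the given SABs, in
#' lexicographic order of the *input list* (position order, not
#' alphabetical). With `n` SABs the result has `n!/(n-3)!` rows.
#'
#' @param sabs character vector of at least three distinct SABs.
#' @return `data.table` with columns `target`, `upper`, `lower`.
#' @export
enumerate_triples <- function(sabs) {
  sabs <- as.character(sabs)
  if (anyDuplicated(sabs))
    stop("`sabs` contains duplicates", call. = FALSE)
  n <- length(sabs)
  if (n < 3L)
    stop("need at least 3 SABs to form ordered triples, got ", n, call. = FALSE)
  # expand.grid varies its first factor fastest; listing (lower, upper,
  # target) therefore yields rows in lexicographic (target, upper, lower)
  # position order
  g <- expand.grid(lower = seq_len(n), upper = seq_len(n), target = seq_len(n),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$target != g$upper & g$target != g$lower & g$upper != g$lower, ]
  data.table(target = sabs[g$target], upper = sabs[g$upper], lower = sabs[g$lower])
}

.check_triples <- function(dags, triples) {
  if (is.null(triples)) triples <- enumerate_triples(names(dags$graphs))
  triples <- as.data.table(triples)
  need <- c("target", "upper", "lower")
  if (!all(need %in% names(triples)))
    stop("`triples` must have columns target, upper, lower", call. = FALSE)
  used <- unique(unlist(triples[, need, with = FALSE], use.names = FALSE))
  missing_sabs <- setdiff(used, names(dags$graphs))
  if (length(missing_sabs))
    stop("triple references SAB(s) absent from the graph collection: ",
         paste(missing_sabs, collapse = ", "), call. = FALSE)
  triples
}

#' Check the nine fire ladder constraints for one candidate
#'
#' @param dags an `ontdag` from [build_ontdag()].
#' @param target,upper,lower SABs of the ordered triple.
#' @param a1,b2,c3 candidate CUIs.
#' @return named logical vector `c1` ... `c9`, `TRUE` where the constraint
#'   holds.
#' @export
check_ladder_constraints <- function(dags, target, upper, lower, a1, b2, c3) {
  stopifnot(inherits(dags, "ontdag"))
  pres <- dags$presence
  chA <- dags$graphs[[target]]$children
  chB <- dags$graphs[[upper]]$children
  chC <- dags$graphs[[lower]]$children
  c(
    c1 = a1 %chin% pres[[target]],
    c2 = a1 %chin% pres[[upper]],
    c3 = !(a1 %chin% pres[[lower]]),
    c4 = b2 %chin% (chB[[a1]] %||% character()),
    c5 = !(b2 %chin% pres[[target]]),
    c6 = b2 %chin% pres[[lower]],
    c7 = c3 %chin% (chC[[b2]] %||% character()),
    c8 = !(c3 %chin% pres[[upper]]),
    c9 = c3 %chin% (chA[[a1]] %||% character())
  )
}

#' Detect fire ladder patterns
#'
#' For each ordered triple, candidate anchors `a1` are the CUIs with
#' children in both the target and the upper graph; candidates then descend
#' one child level in the upper source and one in the lower source, and
#' each surviving combination satisfies all nine constraints. The result is
#' purely set-defined: the same (target, a1, b2, c3) may appear once per
#' (upper, lower) combination — merging across source permutations happens
#' in [build_dataset1()].
#'
#' @param dags an `ontdag` from [build_ontdag()] (cycle-free per graph).
#' @param triples ordered triple table from [enumerate_triples()]; defaults
#'   to all ordered triples of the SABs in `dags`.
#' @return `data.table` with columns `target_sab`, `upper_sab`,
#'   `lower_sab`, `a1`, `b2`, `c3`, canonically sorted.
#' @export
detect_fire_ladders <- function(dags, triples = NULL) {
  stopifnot(inherits(dags, "ontdag"))
  triples <- .check_triples(dags, triples)
  acc <- list()
  for (i in seq_len(nrow(triples))) {
    A <- triples$target[i]; B <- triples$upper[i]; C <- triples$lower[i]
    chA <- dags$graphs[[A]]$children
    chB <- dags$graphs[[B]]$children
    chC <- dags$graphs[[C]]$children
    presA <- dags$presence[[A]]; presB <- dags$presence[[B]]
    presC <- dags$presence[[C]]
    a1s <- intersect(names(chA), names(chB))
    a1s <- a1s[a1s %chin% presA & a1s %chin% presB & !(a1s %chin% presC)]
    for (a1 in a1s) {
      kidsA <- chA[[a1]]
      b2s <- chB[[a1]]
      b2s <- b2s[b2s %chin% presC & !(b2s %chin% presA)]
      for (b2 in b2s) {
        kidsC <- chC[[b2]]
        if (is.null(kidsC)) next
        c3s <- kidsC[kidsC %chin% kidsA & !(kidsC %chin% presB)]
        if (length(c3s)) {
          acc[[length(acc) + 1L]] <- data.table(
            target_sab = A, upper_sab = B, lower_sab = C,
            a1 = a1, b2 = b2, c3 = c3s)
        }
      }
    }
  }
  out <- if (length(acc)) rbindlist(acc) else .empty_patterns()
  setorder(out, target_sab, upper_sab, lower_sab, a1, b2, c3)
  out[]
}

#' Brute-force fire ladder detection (testing oracle)
#'
#' Enumerates every (a1, b2, c3) CUI combination over the union of atoms
#' and graph nodes of each triple's three terminologies and checks the nine
#' constraints directly via [check_ladder_constraints()]. Cost is cubic in
#' the CUI universe; intended for small fixtures only, as the independent
#' oracle against [detect_fire_ladders()].
#'
#' @inheritParams detect_fire_ladders
#' @return same shape as [detect_fire_ladders()].
#' @export
brute_force_ladders <- function(dags, triples = NULL) {
  stopifnot(inherits(dags, "ontdag"))
  triples <- .check_triples(dags, triples)
  acc <- list()
  for (i in seq_len(nrow(triples))) {
    A <- triples$target[i]; B <- triples$upper[i]; C <- triples$lower[i]
    universe <- csort(unique(c(
      dags$presence[[A]], dags$presence[[B]], dags$presence[[C]],
      graph_nodes(dags$graphs[[A]]), graph_nodes(dags$graphs[[B]]),
      graph_nodes(dags$graphs[[C]]))))
    for (a1 in universe) {
      cc <- check_ladder_constraints(dags, A, B, C, a1, universe[1L], universe[1L])
      if (!(cc["c1"] && cc["c2"] && cc["c3"])) next
      for (b2 in universe) {
        cc <- check_ladder_constraints(dags, A, B, C, a1, b2, universe[1L])
        if (!(cc["c4"] && cc["c5"] && cc["c6"])) next
        for (c3 in universe) {
          cc <- check_ladder_constraints(dags, A, B, C, a1, b2, c3)
          if (all(cc)) {
            acc[[length(acc) + 1L]] <- data.table(
              target_sab = A, upper_sab = B, lower_sab = C,
              a1 = a1, b2 = b2, c3 = c3)
          }
        }
      }
    }
  }
  out <- if (length(acc)) rbindlist(acc) else .empty_patterns()
  setorder(out, target_sab, upper_sab, lower_sab, a1, b2, c3)
  out[]
}

#' Attach display names to a pattern collection
#'
#' The display name of a CUI in a SAB is the lexicographically first
#' retained atom string for that (CUI, SAB) — preferred terms differ across
#' sources, so a deterministic tie-break is required. `a1` is named from
#' the target SAB, `b2` from the upper SAB, `c3` from the lower SAB, each
#' falling back to the first name in any SAB when that SAB has no atom.
#'
#' @param patterns pattern collection from [detect_fire_ladders()].
#' @param atoms atom table from [read_mrconso()].
#' @return the pattern table with `a1_name`, `b2_name`, `c3_name` added.
#' @export
annotate_patterns <- function(patterns, atoms) {
  p <- as.data.table(patterns)
  atoms <- as.data.table(atoms)
  if (!nrow(p)) return(.canonical_patterns(p))
  nm <- atoms[, .(name = csort(str_name)[1L]), by = .(cui, sab)]
  any_nm <- nm[, .(name = csort(name)[1L]), by = cui]
  lookup <- function(cuis, sabs) {
    specific <- nm$name[match(paste(cuis, sabs), paste(nm$cui, nm$sab))]
    fallback <- any_nm$name[match(cuis, any_nm$cui)]
    out <- ifelse(is.na(specific), fallback, specific)
    ifelse(is.na(out), "", out)
  }
  p[, a1_name := lookup(a1, target_sab)]
  p[, b2_name := lookup(b2, upper_sab)]
  p[, c3_name := lookup(c3, lower_sab)]
  .canonical_patterns(p)
}
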