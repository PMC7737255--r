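# Per-terminology IS-A hierarchy ("ontDAG"): for one SAB, a map from each
# concept to its parents and to its children. Node membership is defined by
# edge participation; whether a CUI has an atom in the SAB is tracked
# separately as "presence".

.make_graph <- function(sab, edges) {
  # edges: data.table(child, parent), deduplicated, self-loop-free
  if (is.null(edges) || nrow(edges) == 0L) {
    return(structure(list(sab = sab, parents = list(), children = list()),
                     class = "terminology_graph"))
  }
  edges <- as.data.table(edges)
  setorder(edges, parent, child)
  children <- split(edges$child, factor(edges$parent, levels = unique(edges$parent)))
  setorder(edges, child, parent)
  parents <- split(edges$parent, factor(edges$child, levels = unique(edges$child)))
  structure(list(sab = sab, parents = as.list(parents), children = as.list(children)),
            class = "terminology_graph")
}

#' Node set of a terminology graph
#'
#' Nodes are the CUIs participating in at least one retained IS-A edge.
#'
#' @param graph a `terminology_graph`.
#' @return sorted character vector of CUIs.
#' @export
graph_nodes <- function(graph) {
  stopifnot(inherits(graph, "terminology_graph"))
  csort(unique(c(names(graph$parents), names(graph$children))))
}

#' Edge list of a terminology graph
#'
#' @param graph a `terminology_graph`.
#' @return `data.table` with columns `child`, `parent`, canonically sorted.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "terminology_graph"))
  if (!length(graph$children))
    return(data.table(child = character(), parent = character()))
  e <- data.table(
    parent = rep(names(graph$children), lengths(graph$children)),
    child = unlist(graph$children, use.names = FALSE)
  )
  setcolorder(e, c("child", "parent"))
  setorder(e, child, parent)
  e[]
}

.empty_removed <- function() {
  data.table(sab = character(), child = character(), parent = character(),
             reason = character())
}

#' Remove directed cycles from a terminology graph
#'
#' Depth-bounded adaptation of the naive cycle sweep: a depth-first
#' traversal is started from every node in ascending CUI order, following
#' child edges for at most `max_depth` levels below the root. Any edge that
#' closes a path back to a node on the current DFS stack is deleted at the
#' moment of detection and recorded. Roots and neighbors are iterated in
#' ascending CUI order, so the removed edge set is deterministic. Cycles
#' longer than `max_depth` may survive; within the bound the result is
#' acyclic and a second application removes nothing.
#'
#' @param graph a `terminology_graph` (self-loops normally already removed
#'   by [build_ontdag()]; any encountered are removed and flagged).
#' @param max_depth positive integer depth bound (levels below each root).
#' @return list with elements `graph` (the pruned `terminology_graph`) and
#'   `removed` (`data.table`: `sab`, `child`, `parent`, `reason`).
#' @export
remove_cycles <- function(graph, max_depth = 5L) {
  stopifnot(inherits(graph, "terminology_graph"))
  max_depth <- as.integer(max_depth)
  if (is.na(max_depth) || max_depth < 1L)
    stop("`max_depth` must be a positive integer", call. = FALSE)

  nodes <- graph_nodes(graph)
  if (!length(nodes)) return(list(graph = graph, removed = .empty_removed()))

  kids <- new.env(parent = emptyenv())
  for (nm in names(graph$children)) assign(nm, csort(graph$children[[nm]]), envir = kids)

  rem_child <- character(); rem_parent <- character(); rem_reason <- character()

  for (root in nodes) {
    on_stack <- new.env(parent = emptyenv())
    expanded <- new.env(parent = emptyenv())

    visit <- function(node, depth) {
      assign(node, TRUE, envir = on_stack)
      ch <- if (exists(node, envir = kids, inherits = FALSE))
        get(node, envir = kids) else character()
      for (k in ch) {
        if (exists(k, envir = on_stack, inherits = FALSE) &&
            get(k, envir = on_stack)) {
          # back edge node -> k closes a cycle through the stack
          cur <- get(node, envir = kids)
          assign(node, cur[cur != k], envir = kids)
          rem_child <<- c(rem_child, k)
          rem_parent <<- c(rem_parent, node)
          rem_reason <<- c(rem_reason,
                           if (identical(k, node)) "self_loop" else "cycle_back_edge")
        } else {
          dk <- depth + 1L
          if (dk < max_depth) {
            prev <- if (exists(k, envir = expanded, inherits = FALSE))
              get(k, envir = expanded) else NA_integer_
            # re-expand when reached on a shorter path, else depth-bounded
            # pruning could hide a short cycle behind a long first visit
            if (is.na(prev) || dk < prev) {
              assign(k, dk, envir = expanded)
              visit(k, dk)
            }
          }
        }
      }
      assign(node, FALSE, envir = on_stack)
    }

    assign(root, 0L, envir = expanded)
    visit(root, 0L)
  }

  keys <- csort(ls(envir = kids))
  counts <- vapply(keys, function(nm) length(get(nm, envir = kids)), 1L)
  keys <- keys[counts > 0L]
  edges <- if (length(keys)) {
    data.table(
      parent = rep(keys, vapply(keys, function(nm) length(get(nm, envir = kids)), 1L)),
      child = unlist(lapply(keys, function(nm) get(nm, envir = kids)), use.names = FALSE)
    )
  } else data.table(child = character(), parent = character())

  removed <- data.table(sab = rep(graph$sab, length(rem_child)),
                        child = rem_child, parent = rem_parent,
                        reason = rem_reason)
  list(graph = .make_graph(graph$sab, edges), removed = removed)
}

#' Build the per-terminology hierarchy collection from atoms and relations
#'
#' For each included SAB, IS-A edges are assembled from the relationship
#' rows of that SAB (a row `(cui1, PAR, cui2, inverse_isa)` adds the edge
#' parent = `cui2`, child = `cui1`), duplicates collapse to one edge,
#' self-loops are recorded and dropped, and the depth-bounded cycle sweep
#' of [remove_cycles()] is applied. Presence — the CUIs with at least one
#' retained atom per SAB — is computed from the atoms alone. Edges whose
#' endpoints have no atom in their SAB are kept but counted and reported
#' with a warning.
#'
#' @param atoms atom table from [read_mrconso()].
#' @param rels relationship table from [read_mrrel()].
#' @param config a [source_config()].
#' @return object of class `ontdag`: list with `graphs` (named list of
#'   `terminology_graph`), `presence` (named list of sorted CUI vectors),
#'   `removed` (removed-edge `data.table`), and `dangling_edge_count`.
#' @export
build_ontdag <- function(atoms, rels, config) {
  stopifnot(inherits(config, "source_config"))
  atoms <- as.data.table(atoms)
  rels <- as.data.table(rels)
  sabs <- config$included_sabs

  presence <- lapply(sabs, function(s) csort(unique(atoms$cui[atoms$sab == s])))
  names(presence) <- sabs

  graphs <- vector("list", length(sabs))
  names(graphs) <- sabs
  removed <- list()
  dangling <- 0L

  for (s in sabs) {
    er <- if (nrow(rels)) unique(rels[sab == s, .(child = cui1, parent = cui2)])
          else data.table(child = character(), parent = character())
    self <- er[child == parent]
    if (nrow(self)) {
      removed[[length(removed) + 1L]] <-
        data.table(sab = s, child = self$child, parent = self$parent,
                   reason = "self_loop")
      er <- er[child != parent]
    }
    res <- remove_cycles(.make_graph(s, er), config$max_cycle_depth)
    graphs[[s]] <- res$graph
    if (nrow(res$removed)) removed[[length(removed) + 1L]] <- res$removed
    dangling <- dangling +
      sum(!(graph_nodes(res$graph) %chin% presence[[s]]))
  }

  removed <- if (length(removed)) rbindlist(removed) else .empty_removed()
  setorder(removed, sab, child, parent, reason)
  if (dangling > 0L)
    warning(sprintf("%d graph node(s) have no retained atom in their SAB (edges kept)",
                    dangling), call. = FALSE)
  structure(list(graphs = graphs, presence = presence, removed = removed,
                 dangling_edge_count = dangling),
            class = "ontdag")
}

#' @export
print.ontdag <- function(x, ...) {
  cat("<ontdag> ", length(x$graphs), " terminologies\n", sep = "")
  for (s in names(x$graphs)) {
    g <- x$graphs[[s]]
    cat(sprintf("  %-14s %5d atoms, %5d nodes, %5d edges\n",
                s, length(x$presence[[s]]), length(graph_nodes(g)),
                nrow(graph_edges(g))))
  }
  if (nrow(x$removed))
    cat("  removed edges:", nrow(x$removed), "\n")
  invisible(x)
}
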