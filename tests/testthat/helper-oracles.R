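# Independent oracles, deliberately implemented along different paths than
# the package code they check.

# Acyclicity via igraph's topological machinery (independent of the DFS
# sweep in remove_cycles).
is_acyclic_oracle <- function(graph) {
  e <- graph_edges(graph)
  if (nrow(e) == 0L) return(TRUE)
  g <- igraph::graph_from_edgelist(as.matrix(e[, c("parent", "child")]),
                                   directed = TRUE)
  igraph::is_dag(g)
}

# Krippendorff's alpha by the general coincidence-matrix algorithm over
# unit-level ratings (nominal metric), rather than the package's two-rater
# closed form.
kripp_alpha_coincidence <- function(ct) {
  tab <- expand_contingency(ct)
  vals <- sort(unique(c(tab$rater1, tab$rater2)))
  o <- matrix(0, length(vals), length(vals), dimnames = list(vals, vals))
  for (i in seq_len(nrow(tab))) {
    x <- tab$rater1[i]; y <- tab$rater2[i]
    # m_u = 2 pairable ratings per unit -> each ordered pair weight 1/(m_u-1)
    o[x, y] <- o[x, y] + 1
    o[y, x] <- o[y, x] + 1
  }
  n_c <- rowSums(o)
  n_tot <- sum(n_c)
  disagree_obs <- sum(o) - sum(diag(o))
  disagree_exp <- sum(outer(n_c, n_c)) - sum(n_c^2)
  if (disagree_exp == 0) stop("alpha undefined")
  1 - (n_tot - 1) * disagree_obs / disagree_exp
}

# Random valid contingency (at least one unit, both values observed so the
# statistics are defined).
random_contingency <- function() {
  repeat {
    cells <- stats::rpois(4L, lambda = c(8, 2, 2, 5))
    imp <- 2 * cells[1] + cells[2] + cells[3]
    non <- 2 * cells[4] + cells[2] + cells[3]
    if (sum(cells) > 0 && imp > 0 && non > 0) {
      return(rating_contingency(cells[1], cells[2], cells[3], cells[4]))
    }
  }
}
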