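#' BIC network score of a DAG on a complete-case cohort
#'
#' Maximized log-likelihood minus `(free parameters / 2) * log(N)`; higher is
#' better. The score decomposes over families (child + parents), which the
#' hill-climbing search exploits: a single-edge change only rescores the
#' affected child.
#'
#' @param dag a [bn_dag()].
#' @param data complete-case data frame covering the DAG's nodes.
#' @return numeric score.
#' @export
bic_score <- function(dag, data) {
  data <- coerce_states(as.data.frame(data), dag$nodes)
  if (nrow(data) == 0L) stop("empty cohort")
  n <- nrow(data)
  sum(vapply(dag$nodes, function(node)
    family_bic(data, node, dag_parents(dag, node), n), 0))
}

## log-lik at the MLE for one family, minus its BIC penalty
family_bic <- function(data, child, parents, n) {
  counts <- table(data[, c(child, parents), drop = FALSE])
  card <- dim(counts)[1L]
  m <- matrix(counts, nrow = card)          # columns = parent configurations
  tot <- colSums(m)
  pos <- m > 0
  ll <- sum(m[pos] * (log(m[pos]) - log(rep(tot, each = card))[pos]))
  npar <- (card - 1) * prod(dim(counts)[-1L])
  ll - npar / 2 * log(n)
}

#' Learn a DAG by BIC hill climbing
#'
#' Greedy search over single-edge additions, deletions and reversals that
#' maximizes [bic_score()], restarted from `restarts` random seeded DAGs in
#' addition to the empty graph. Ties between equal-scoring moves are broken
#' lexicographically on (child, parent), so the result is deterministic given
#' the seed.
#'
#' @param data data frame of discrete variables (at least two).
#' @param seed integer seed for the random restarts.
#' @param restarts number of random restarts (0 = single run from the empty
#'   graph).
#' @return the best-scoring `bn_dag` found.
#' @export
learn_structure <- function(data, seed = 1L, restarts = 3L) {
  data <- as.data.frame(data)
  vars <- names(data)
  if (length(vars) < 2L) stop("need at least two variables")
  data <- coerce_states(data, vars)
  const <- vars[vapply(data, function(x) length(unique(x)) < 2L, TRUE)]
  if (length(const))
    warning("constant column(s): ", paste(const, collapse = ", "),
            " carry no structural information")
  n <- nrow(data)
  cache <- new.env(parent = emptyenv())
  fam <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- family_bic(data, child, parents, n)
    cache[[key]]
  }
  climb <- function(edges) {
    repeat {
      moves <- propose_moves(vars, edges)
      if (nrow(moves) == 0L) break
      deltas <- vapply(seq_len(nrow(moves)), function(i) {
        mv <- moves[i, ]
        d <- 0
        for (ch in unique(unlist(mv[c("child1", "child2")]))) {
          if (is.na(ch)) next
          d <- d + fam(ch, move_parents(edges, mv, ch)) -
            fam(ch, edge_parents(edges, ch))
        }
        d
      }, 0)
      best <- order(-deltas, moves$child1, moves$parent1)[1L]
      if (deltas[best] <= 1e-9) break
      edges <- apply_move(edges, moves[best, ])
    }
    edges
  }
  run_score <- function(edges) {
    sum(vapply(vars, function(ch) fam(ch, edge_parents(edges, ch)), 0))
  }
  starts <- with_seed(seed, {
    c(list(matrix(character(), 0L, 2L)),
      lapply(seq_len(restarts), function(i) random_dag_edges(vars)))
  })
  best_edges <- NULL; best_score <- -Inf
  for (st in starts) {
    e <- climb(st)
    s <- run_score(e)
    if (s > best_score + 1e-9) { best_score <- s; best_edges <- e }
  }
  bn_dag(vars, best_edges)
}

edge_parents <- function(edges, child)
  if (nrow(edges)) edges[edges[, 2L] == child, 1L] else character(0)

## enumerate legal add / delete / reverse moves (acyclicity enforced)
propose_moves <- function(vars, edges) {
  has <- function(a, b) any(edges[, 1L] == a & edges[, 2L] == b)
  out <- list()
  for (a in vars) for (b in vars) {
    if (a == b) next
    if (!has(a, b) && !has(b, a)) {
      if (acyclic_with(vars, rbind(edges, c(a, b))))
        out[[length(out) + 1L]] <- data.frame(
          op = "add", from = a, to = b, child1 = b, parent1 = a, child2 = NA)
    } else if (has(a, b)) {
      out[[length(out) + 1L]] <- data.frame(
        op = "delete", from = a, to = b, child1 = b, parent1 = a, child2 = NA)
      rev_edges <- rbind(edges[!(edges[, 1L] == a & edges[, 2L] == b), ,
                               drop = FALSE], c(b, a))
      if (acyclic_with(vars, rev_edges))
        out[[length(out) + 1L]] <- data.frame(
          op = "reverse", from = a, to = b, child1 = b, parent1 = a, child2 = a)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(op = character(), from = character(), to = character(),
               child1 = character(), parent1 = character(), child2 = character())
}

acyclic_with <- function(vars, edges) {
  colnames(edges) <- c("from", "to")
  !is.null(topo_sort(structure(list(nodes = vars, edges = edges),
                               class = "bn_dag")))
}

move_parents <- function(edges, mv, child) {
  e2 <- apply_move(edges, mv)
  edge_parents(e2, child)
}

apply_move <- function(edges, mv) {
  a <- mv$from; b <- mv$to
  if (mv$op == "add") rbind(edges, c(a, b))
  else {
    e <- edges[!(edges[, 1L] == a & edges[, 2L] == b), , drop = FALSE]
    if (mv$op == "reverse") rbind(e, c(b, a)) else e
  }
}

## random DAG for restarts: random topological order, each possible edge
## included with probability 1/3
random_dag_edges <- function(vars) {
  ord <- sample(vars)
  out <- matrix(character(), 0L, 2L)
  k <- length(vars)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    if (runif(1) < 1 / 3) out <- rbind(out, c(ord[i], ord[j]))
  out
}
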