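#' Construct a directed acyclic graph over named variables
#'
#' @param nodes character vector of variable names.
#' @param edges two-column character matrix (or data frame) of directed edges,
#'   `from` in column 1 and `to` in column 2; may have zero rows.
#' @return an object of class `bn_dag`.
#' @examples
#' bn_dag(c("a", "b"), rbind(c("a", "b")))
#' @export
bn_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(), 0L, 2L)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "character"
    if (ncol(edges) != 2L) stop("`edges` must have two columns (from, to)")
  }
  colnames(edges) <- c("from", "to")
  bad <- setdiff(c(edges), nodes)
  if (length(bad)) stop("edge references unknown node(s): ",
                        paste(unique(bad), collapse = ", "))
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L]))) stop("duplicate edges")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  d <- structure(list(nodes = nodes, edges = edges), class = "bn_dag")
  if (is.null(topo_sort(d))) stop("edge set contains a directed cycle")
  d
}

#' The canonical study network structure
#'
#' Gender, age group and family history are parentless; each is a parent of
#' the binaural-loss group. All printed sensitivity tables are conditionals
#' of the loss group given subsets of the three predictors, which this
#' structure represents exactly.
#'
#' @return a `bn_dag` over the four study variables.
#' @export
canonical_dag <- function() {
  bn_dag(c("gender", "age_group", "family_history", "loss_group"),
         cbind(c("gender", "age_group", "family_history"),
               rep("loss_group", 3L)))
}

dag_parents <- function(dag, node) dag$edges[dag$edges[, 2L] == node, 1L]

## Kahn's algorithm; returns node order, or NULL if the graph is cyclic
topo_sort <- function(dag) {
  nodes <- dag$nodes
  indeg <- setNames(integer(length(nodes)), nodes)
  for (to in dag$edges[, 2L]) indeg[to] <- indeg[to] + 1L
  order <- character(0)
  ready <- nodes[indeg == 0L]
  while (length(ready)) {
    n <- ready[1L]; ready <- ready[-1L]
    order <- c(order, n)
    ch <- dag$edges[dag$edges[, 1L] == n, 2L]
    for (c_ in ch) {
      indeg[c_] <- indeg[c_] - 1L
      if (indeg[c_] == 0L) ready <- c(ready, c_)
    }
  }
  if (length(order) == length(nodes)) order else NULL
}

#' Number of free parameters of a DAG factorization
#'
#' For each node, `(card(node) - 1) * prod(card(parents))`, summed over nodes
#' — the independent probabilities needed to specify all conditional tables.
#' Contrast with the unfactorized joint, which needs `prod(card) - 1`.
#'
#' @param dag a `bn_dag`.
#' @param cardinalities named integer vector of state counts per node.
#' @return integer parameter count.
#' @examples
#' d <- bn_dag(letters[1:4])          # four binary nodes, no edges
#' parameter_count(d, setNames(rep(2, 4), letters[1:4]))  # 4 (joint needs 15)
#' @export
parameter_count <- function(dag, cardinalities) {
  miss <- setdiff(dag$nodes, names(cardinalities))
  if (length(miss)) stop("no cardinality for node(s): ", paste(miss, collapse = ", "))
  sum(vapply(dag$nodes, function(n) {
    pa <- dag_parents(dag, n)
    (cardinalities[[n]] - 1L) * prod(unlist(cardinalities[pa], use.names = FALSE))
  }, 0))
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("DAG:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L], collapse = "\n"), "\n")
  invisible(x)
}

## ---- factors for sum-product inference ------------------------------------
## a factor is a numeric array whose dimnames are named by variable

factor_vars <- function(f) names(dimnames(f))

## canonical array form: unnamed dim vector, variable-named dimnames
norm_cpt <- function(f) {
  dn <- dimnames(f)
  array(as.vector(f), dim = unname(lengths(dn)), dimnames = dn)
}

## multiply two factors over the union of their scopes
factor_product <- function(a, b) {
  va <- factor_vars(a); vb <- factor_vars(b)
  vars <- union(va, vb)
  dn <- c(dimnames(a), dimnames(b))[!duplicated(c(va, vb))]
  names(dn) <- vars
  grid <- do.call(expand.grid,
                  c(dn, list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  vals <- as.vector(a)[cell_index(grid[va], dimnames(a))] *
          as.vector(b)[cell_index(grid[vb], dimnames(b))]
  array(vals, dim = lengths(dn), dimnames = dn)
}

## linear index of each row of a state grid into an array with given dimnames
cell_index <- function(grid, dn) {
  idx <- 0L
  mult <- 1L
  for (j in seq_along(dn)) {
    idx <- idx + (match(grid[[j]], dn[[j]]) - 1L) * mult
    mult <- mult * length(dn[[j]])
  }
  idx + 1L
}

## sum a variable out of a factor
factor_marginalize <- function(f, var) {
  vars <- factor_vars(f)
  keep <- setdiff(vars, var)
  if (!length(keep)) return(sum(f))
  res <- apply(f, keep, sum)
  if (is.null(dim(res))) {  # single remaining variable
    res <- array(res, dim = length(res),
                 dimnames = setNames(list(dimnames(f)[[keep]]), keep))
  }
  res
}

## fix a variable to one observed state and drop that dimension
factor_reduce <- function(f, var, value) {
  vars <- factor_vars(f)
  if (!var %in% vars) return(f)
  dn <- dimnames(f)
  sel <- lapply(vars, function(v) if (v == var) value else dn[[v]])
  res <- do.call(`[`, c(list(f), sel, list(drop = FALSE)))
  keep <- setdiff(vars, var)
  if (!length(keep)) return(sum(res))
  dn2 <- dimnames(res)[keep]
  array(as.vector(res), dim = lengths(dn2), dimnames = dn2)
}
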