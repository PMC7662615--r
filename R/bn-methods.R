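#' @export
print.discrete_bn <- function(x, ...) {
  cat("Discrete Bayesian network\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("Nodes: %s\n", paste(x$dag$nodes, collapse = ", ")))
  if (nrow(x$dag$edges))
    cat("Edges:", paste(x$dag$edges[, 1L], "->", x$dag$edges[, 2L],
                        collapse = "; "), "\n")
  else cat("Edges: (none)\n")
  if (!is.na(x$nobs))
    cat(sprintf("Fitted to %d records (alpha = %g)\n", x$nobs, x$alpha))
  cat(sprintf("Free parameters: %d\n",
              parameter_count(x$dag, lengths(x$schema))))
  invisible(x)
}

#' @export
summary.discrete_bn <- function(object, ...) {
  marg <- lapply(object$dag$nodes, function(n)
    query_posterior(object, n, list()))
  names(marg) <- object$dag$nodes
  out <- list(net = object, marginals = marg,
              parameters = parameter_count(object$dag, lengths(object$schema)))
  class(out) <- "summary.discrete_bn"
  out
}

#' @export
print.summary.discrete_bn <- function(x, ...) {
  print(x$net)
  cat("\nMarginal distributions:\n")
  for (n in names(x$marginals)) {
    cat(sprintf("  %s:\n", n))
    print(round(x$marginals[[n]], 4))
  }
  invisible(x)
}

#' Extract the conditional probability tables
#'
#' @param object a `discrete_bn`.
#' @param ... unused.
#' @return named list of CPT arrays (child dimension first).
#' @export
coef.discrete_bn <- function(object, ...) object$cpts

#' Log-likelihood of a cohort under a fitted network
#'
#' @param object a `discrete_bn`.
#' @param data cohort to evaluate; defaults must be supplied explicitly (the
#'   fitted object does not store its training data).
#' @param ... unused.
#' @return `logLik` object with `df` = number of free parameters.
#' @export
logLik.discrete_bn <- function(object, data, ...) {
  data <- coerce_states(as.data.frame(data), object$dag$nodes)
  ll <- 0
  for (n in object$dag$nodes) {
    f <- object$cpts[[n]]
    vars <- factor_vars(f)
    grid <- data[vars]
    for (v in vars) grid[[v]] <- as.character(grid[[v]])
    ll <- ll + sum(log(as.vector(f)[cell_index(grid, dimnames(f))]))
  }
  structure(ll, df = parameter_count(object$dag, lengths(object$schema)),
            nobs = nrow(data), class = "logLik")
}

#' Posterior loss-group probabilities for new workers
#'
#' Scores each record by the exact posterior of `target` given the record's
#' values on every other network variable present in `newdata`.
#'
#' @param object a fitted `discrete_bn`.
#' @param newdata data frame of records (missing network columns are simply
#'   not conditioned on; `age_years` is discretized if needed).
#' @param target variable to predict (default: the fit's response, else
#'   `"loss_group"`).
#' @param type `"prob"` for a probability matrix, `"class"` for the maximum
#'   a-posteriori state.
#' @param ... unused.
#' @return matrix (rows = records, columns = target states) or factor.
#' @export
predict.discrete_bn <- function(object, newdata, target = NULL,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(target)) target <- object$response %||% "loss_group"
  newdata <- prepare_bn_data(newdata, character())
  evars <- setdiff(intersect(object$dag$nodes, names(newdata)), target)
  states <- object$schema[[target]]
  if (!length(evars)) {
    p <- query_posterior(object, target, list())
    probs <- matrix(p, nrow(newdata), length(states), byrow = TRUE,
                    dimnames = list(NULL, states))
  } else {
    key <- do.call(paste, c(lapply(newdata[evars], as.character), sep = "\r"))
    uniq <- !duplicated(key)
    post <- vapply(which(uniq), function(i) {
      ev <- lapply(newdata[i, evars, drop = FALSE], as.character)
      query_posterior(object, target, ev)
    }, numeric(length(states)))
    probs <- t(post)[match(key, key[uniq]), , drop = FALSE]
    colnames(probs) <- states
  }
  if (type == "prob") probs
  else factor(states[max.col(probs, ties.method = "first")], levels = states)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ancestral sampling from a fitted network
#'
#' Draws `nsim` complete records by sampling each node in topological order
#' from its CPT given the already-sampled parents.
#'
#' @param object a `discrete_bn`.
#' @param nsim number of records.
#' @param seed integer seed (the caller's RNG state is left untouched).
#' @param ... unused.
#' @return data frame with one factor column per node.
#' @export
simulate.discrete_bn <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(nsim >= 1)
  with_seed(seed, {
    ord <- topo_sort(object$dag)
    out <- vector("list", length(ord))
    names(out) <- ord
    for (n in ord) {
      f <- object$cpts[[n]]
      states <- object$schema[[n]]
      pa <- dag_parents(object$dag, n)
      if (!length(pa)) {
        out[[n]] <- sample(states, nsim, replace = TRUE, prob = as.vector(f))
      } else {
        grid <- as.data.frame(out[pa], stringsAsFactors = FALSE)
        names(grid) <- pa
        ## sample all records sharing a parent configuration in one call
        cfg <- do.call(paste, c(grid, sep = "\r"))
        draws <- character(nsim)
        for (cf in unique(cfg)) {
          rows <- which(cfg == cf)
          p <- f
          for (v in pa) p <- factor_reduce(p, v, grid[[v]][rows[1L]])
          draws[rows] <- sample(states, length(rows), replace = TRUE,
                                prob = as.vector(p))
        }
        out[[n]] <- draws
      }
    }
    res <- as.data.frame(lapply(ord, function(n)
      factor(out[[n]], levels = object$schema[[n]])), col.names = ord)
    names(res) <- ord
    res
  })
}

#' Plot the network structure
#'
#' Simple layered layout: parentless nodes on top, the outcome below, edges
#' drawn as arrows.
#'
#' @param x a `discrete_bn` or `bn_dag`.
#' @param ... unused.
#' @export
plot.discrete_bn <- function(x, ...) plot(x$dag, ...)

#' @export
plot.bn_dag <- function(x, ...) {
  nodes <- x$nodes
  depth <- setNames(rep(0L, length(nodes)), nodes)
  for (n in topo_sort(x)) {
    pa <- dag_parents(x, n)
    if (length(pa)) depth[n] <- max(depth[pa]) + 1L
  }
  ys <- max(depth) - depth
  xs <- ave(seq_along(nodes), depth, FUN = function(i) seq_along(i) / (length(i) + 1))
  plot.new()
  plot.window(xlim = c(0, 1), ylim = c(-0.5, max(depth) + 0.5))
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges))) {
      a <- match(x$edges[i, 1L], nodes); b <- match(x$edges[i, 2L], nodes)
      arrows(xs[a], ys[a] - 0.08, xs[b], ys[b] + 0.08, length = 0.1)
    }
  points(xs, ys, pch = 21, bg = "grey90", cex = 4)
  text(xs, ys, nodes, cex = 0.7)
  invisible(x)
}

#' Serialize a network to JSON
#'
#' Writes `{variables, edges, cpts}` with explicit state ordering and
#' row-major CPT values so that [read_bn()] reproduces the network bit for
#' bit.
#'
#' @param net a `discrete_bn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bn <- function(net, path) {
  doc <- list(
    variables = lapply(net$dag$nodes, function(n)
      list(name = n, states = net$schema[[n]])),
    edges = apply(net$dag$edges, 1L, function(e)
      list(from = e[[1L]], to = e[[2L]])),
    cpts = lapply(net$dag$nodes, function(n) {
      f <- net$cpts[[n]]
      ## %.17g round-trips IEEE doubles exactly; plain JSON numbers do not
      list(child = n, parents = dag_parents(net$dag, n),
           dim = dim(f), values = sprintf("%.17g", as.vector(f)))
    }),
    alpha = net$alpha, nobs = net$nobs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a network written by [write_bn()]
#'
#' @param path path to the JSON document.
#' @return a `discrete_bn`.
#' @export
read_bn <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  nodes <- vapply(doc$variables, `[[`, "", "name")
  states <- setNames(lapply(doc$variables, function(v) unlist(v$states)), nodes)
  edges <- if (length(doc$edges))
    do.call(rbind, lapply(doc$edges, function(e) c(e$from, e$to)))
  dag <- bn_dag(nodes, edges)
  cpts <- setNames(lapply(doc$cpts, function(cp) {
    vars <- c(cp$child, unlist(cp$parents))
    dn <- states[vars]
    array(as.numeric(unlist(cp$values)), dim = unlist(cp$dim), dimnames = dn)
  }), vapply(doc$cpts, `[[`, "", "child"))
  net <- make_bn(dag, cpts)
  net$alpha <- if (is.null(doc$alpha)) NA_real_ else doc$alpha
  net$nobs <- if (is.null(doc$nobs)) NA_integer_ else doc$nobs
  net
}
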