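#' Fit a discrete Bayesian network of hearing loss
#'
#' The main modelling entry point. `hearing_bn()` fits a discrete Bayesian
#' network to a cohort of workers, estimating one conditional probability
#' table (CPT) per variable by (optionally Laplace-smoothed) maximum
#' likelihood. The structure is taken from the model formula — the response
#' gets every right-hand-side term as a parent and the predictors are
#' parentless, which for `loss_group ~ gender + age_group + family_history`
#' is the canonical study network — or, with `structure = "learn"`, from
#' BIC hill-climbing over all variables mentioned in the formula (see
#' [learn_structure()]).
#'
#' @param formula model formula; the response is the outcome variable (by
#'   convention `loss_group`), the right-hand side its parents.
#' @param data a cohort data frame with factor (or factor-coercible) columns
#'   for every variable in the formula. `age_years` is discretized on the fly
#'   if `age_group` is requested but absent.
#' @param alpha Laplace pseudo-count added to every cell count (default 0 =
#'   pure maximum likelihood; parent configurations never observed then fall
#'   back to a uniform distribution).
#' @param structure `"formula"` (default) or `"learn"`.
#' @param seed,restarts passed to [learn_structure()] when `structure = "learn"`.
#' @return an object of class `discrete_bn` with components `dag`, `cpts`
#'   (one named array per node, child dimension first), `schema`, `alpha`,
#'   `nobs` and `call`.
#' @examples
#' cohort <- sample_cohort(default_generating_model(), 2000, seed = 1)
#' fit <- hearing_bn(loss_group ~ gender + age_group + family_history, cohort)
#' fit
#' query_posterior(fit, "loss_group", list(gender = "Women"))
#' @seealso [fit_bn()] for an explicit-DAG interface, [query_posterior()],
#'   [scenario_table()], [cross_validated_auc()]
#' @export
hearing_bn <- function(formula, data, alpha = 0,
                       structure = c("formula", "learn"),
                       seed = 1L, restarts = 3L) {
  structure <- match.arg(structure)
  vars <- all.vars(formula)
  response <- vars[1L]
  data <- prepare_bn_data(data, vars)
  dag <- if (structure == "learn") {
    learn_structure(data[vars], seed = seed, restarts = restarts)
  } else {
    bn_dag(vars, if (length(vars) > 1L) cbind(vars[-1L], response))
  }
  fit <- fit_bn(dag, data, alpha = alpha)
  fit$call <- match.call()
  fit$response <- response
  fit
}

## discretize age on demand and check/coerce factor columns
prepare_bn_data <- function(data, vars) {
  data <- as.data.frame(data)
  if ("age_group" %in% vars && !"age_group" %in% names(data) &&
      "age_years" %in% names(data))
    data$age_group <- age_group(data$age_years)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("variable(s) not in data: ", paste(miss, collapse = ", "))
  data
}

#' Fit CPT parameters for a given DAG
#'
#' Each CPT entry is `(count + alpha) / (row_total + alpha * card(child))`;
#' with `alpha = 0`, parent configurations with no observations get a uniform
#' row.
#'
#' @param dag a [bn_dag()].
#' @param data data frame with a factor column per node (character columns are
#'   coerced using the study schema where the name matches, otherwise their
#'   sorted unique values).
#' @param alpha Laplace pseudo-count, `>= 0`.
#' @return a `discrete_bn` object.
#' @export
fit_bn <- function(dag, data, alpha = 0) {
  stopifnot(inherits(dag, "bn_dag"), alpha >= 0)
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("empty cohort")
  data <- coerce_states(data, dag$nodes)
  if (anyNA(data[dag$nodes])) stop("missing values in model variables")
  cpts <- setNames(lapply(dag$nodes, function(n)
    estimate_cpt(data, n, dag_parents(dag, n), alpha)), dag$nodes)
  schema <- setNames(lapply(dag$nodes, function(n) levels(data[[n]])), dag$nodes)
  structure(list(dag = dag, cpts = cpts, schema = schema, alpha = alpha,
                 nobs = nrow(data)), class = "discrete_bn")
}

coerce_states <- function(data, nodes) {
  known <- cohort_schema()
  for (n in nodes) {
    if (!is.factor(data[[n]])) {
      lev <- if (n %in% names(known)) known[[n]]$states else
        sort(unique(as.character(data[[n]])))
      bad <- setdiff(unique(as.character(data[[n]])), c(lev, NA))
      if (length(bad)) stop("unknown state label(s) for ", n, ": ",
                            paste(bad, collapse = ", "))
      data[[n]] <- factor(data[[n]], levels = lev)
    }
  }
  data
}

## CPT as array with the child dimension first, then parents in order
estimate_cpt <- function(data, child, parents, alpha) {
  counts <- table(data[, c(child, parents), drop = FALSE])
  card <- dim(counts)[1L]
  counts <- counts + alpha
  if (length(parents) == 0L) {
    tot <- sum(counts)
    p <- if (tot == 0) rep(1 / card, card) else as.vector(counts) / tot
    return(array(p, dim = card, dimnames = setNames(dimnames(counts)[1L], child)))
  }
  tot <- apply(counts, seq_along(dim(counts))[-1L], sum)
  p <- sweep(counts, seq_along(dim(counts))[-1L], tot, "/")
  ## alpha = 0 and an unobserved parent configuration: uniform fallback
  zero <- which(tot == 0)
  if (length(zero)) {
    p <- array(p, dim = dim(counts), dimnames = dimnames(counts))
    flat <- matrix(p, nrow = card)
    flat[, zero] <- 1 / card
    p <- array(flat, dim = dim(counts), dimnames = dimnames(counts))
  }
  dn <- dimnames(counts)
  names(dn) <- c(child, parents)
  array(as.vector(p), dim = unname(dim(counts)), dimnames = dn)
}

#' Build a discrete Bayesian network from explicit CPTs
#'
#' Used for fixture networks and for turning published conditional tables
#' into generative models. Every CPT row must sum to 1 within `1e-12`.
#'
#' @param dag a [bn_dag()].
#' @param cpts named list, one array per node: child dimension first (named by
#'   the node, with state dimnames), parent dimensions following in the DAG's
#'   parent order.
#' @return a `discrete_bn`.
#' @export
make_bn <- function(dag, cpts) {
  stopifnot(inherits(dag, "bn_dag"))
  miss <- setdiff(dag$nodes, names(cpts))
  if (length(miss)) stop("missing CPT(s) for: ", paste(miss, collapse = ", "))
  schema <- list()
  for (n in dag$nodes) {
    f <- cpts[[n]]
    pa <- dag_parents(dag, n)
    if (!setequal(factor_vars(f), c(n, pa)))
      stop("CPT scope for ", n, " must be (", paste(c(n, pa), collapse = ", "), ")")
    rows <- factor_marginalize(f, n)
    if (any(abs(rows - 1) > 1e-12) || any(f < 0) || any(f > 1))
      stop("CPT rows for ", n, " must be probabilities summing to 1")
    cpts[[n]] <- norm_cpt(f)
    schema[[n]] <- dimnames(f)[[n]]
  }
  structure(list(dag = dag, cpts = cpts[dag$nodes], schema = schema,
                 alpha = NA_real_, nobs = NA_integer_), class = "discrete_bn")
}

#' Joint probability of a complete assignment
#'
#' Product of the matching CPT entries, `prod_i P(x_i | parents(x_i))`.
#'
#' @param net a `discrete_bn`.
#' @param assignment named list/vector giving one state for every node.
#' @return probability in \[0, 1\].
#' @export
joint_probability <- function(net, assignment) {
  assignment <- unlist(assignment)
  miss <- setdiff(net$dag$nodes, names(assignment))
  if (length(miss)) stop("assignment must cover all nodes; missing: ",
                         paste(miss, collapse = ", "))
  prod(vapply(net$dag$nodes, function(n) {
    f <- net$cpts[[n]]
    vars <- factor_vars(f)
    idx <- lapply(vars, function(v) {
      s <- as.character(assignment[[v]])
      if (!s %in% dimnames(f)[[v]]) stop("unknown state ", s, " for ", v)
      s
    })
    as.numeric(do.call(`[`, c(list(f), idx)))
  }, 0))
}

#' Exact posterior by variable elimination
#'
#' Computes `P(target | evidence)` by sum-product variable elimination with a
#' min-degree elimination order. Exact for any network this package builds;
#' the elimination order affects only speed.
#'
#' @param net a `discrete_bn`.
#' @param target variable to query (must not appear in the evidence).
#' @param evidence named list of observed states (possibly empty).
#' @return named probability vector over the target's states (sums to 1).
#' @examples
#' net <- make_bn(bn_dag("x"), list(x = array(c(.3, .7), 2,
#'   dimnames = list(x = c("a", "b")))))
#' query_posterior(net, "x", list())
#' @export
query_posterior <- function(net, target, evidence = list()) {
  if (!target %in% net$dag$nodes) stop("unknown target: ", target)
  evidence <- as.list(evidence)
  if (target %in% names(evidence)) stop("target cannot be part of the evidence")
  for (v in names(evidence)) {
    if (!v %in% net$dag$nodes) stop("unknown evidence variable: ", v)
    if (!as.character(evidence[[v]]) %in% net$schema[[v]])
      stop("unknown state ", evidence[[v]], " for ", v)
  }
  factors <- unname(net$cpts)
  const <- 1
  for (v in names(evidence)) {
    factors <- lapply(factors, factor_reduce, var = v,
                      value = as.character(evidence[[v]]))
  }
  scal <- vapply(factors, function(f) !is.array(f), TRUE)
  const <- prod(unlist(factors[scal]), 1)
  factors <- factors[!scal]
  elim <- setdiff(net$dag$nodes, c(target, names(evidence)))
  while (length(elim)) {
    ## min-degree: eliminate the variable involving the fewest other variables
    deg <- vapply(elim, function(v) {
      sc <- unique(unlist(lapply(factors, function(f)
        if (v %in% factor_vars(f)) factor_vars(f) else NULL)))
      length(setdiff(sc, v))
    }, 0L)
    v <- elim[order(deg, elim)][1L]
    elim <- setdiff(elim, v)
    inv <- vapply(factors, function(f) v %in% factor_vars(f), TRUE)
    if (!any(inv)) next
    prodf <- Reduce(factor_product, factors[inv])
    newf <- factor_marginalize(prodf, v)
    factors <- c(factors[!inv], if (is.array(newf)) list(newf))
    if (!is.array(newf)) const <- const * newf
  }
  res <- if (length(factors)) Reduce(factor_product, factors) else
    stop("internal error: no factor over the target remains")
  res <- const * res
  z <- sum(res)
  if (z <= 0) stop("impossible evidence: observed configuration has probability 0")
  p <- as.vector(res) / z
  setNames(p, dimnames(res)[[target]])[net$schema[[target]]]
}
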