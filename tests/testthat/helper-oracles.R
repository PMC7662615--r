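## Independent oracles and fixture builders shared across the suite.

## brute-force posterior: enumerate every complete assignment, take the
## product of CPT entries via joint_probability(), sum and normalize.
## Deliberately avoids the variable-elimination code path.
brute_posterior <- function(net, target, evidence = list()) {
  grid <- expand.grid(net$schema, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence))
    keep <- keep & grid[[v]] == as.character(evidence[[v]])
  p <- vapply(which(keep), function(i)
    joint_probability(net, as.list(grid[i, , drop = FALSE])), 0)
  tapply_states <- vapply(net$schema[[target]], function(s)
    sum(p[grid[[target]][keep] == s]), 0)
  tapply_states / sum(tapply_states)
}

## all-pairs AUC oracle: mean over positive-negative pairs, ties count 1/2
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

## random discrete network: random DAG over nvars variables with 2-5 states,
## Dirichlet(1) CPT rows; reproducible through the caller's RNG state
random_net <- function(nvars, max_states = 5L, edge_prob = 0.4) {
  vars <- paste0("v", seq_len(nvars))
  cards <- sample(2:max_states, nvars, replace = TRUE)
  states <- setNames(lapply(seq_len(nvars), function(i)
    paste0("s", seq_len(cards[i]))), vars)
  edges <- NULL
  for (i in seq_len(nvars - 1L)) for (j in (i + 1L):nvars)
    if (runif(1) < edge_prob) edges <- rbind(edges, c(vars[i], vars[j]))
  dag <- bn_dag(vars, edges)
  cpts <- setNames(lapply(vars, function(v) {
    pa <- hearbn:::dag_parents(dag, v)
    dn <- c(states[v], states[pa])
    dims <- lengths(dn)
    nrows <- prod(dims[-1L], 1)
    vals <- vapply(seq_len(nrows), function(r) {
      x <- -log(runif(dims[1L]))   # Dirichlet(1) row
      x / sum(x)
    }, numeric(dims[1L]))
    array(as.vector(vals), dim = dims, dimnames = dn)
  }), vars)
  make_bn(dag, cpts)
}

## skeleton + v-structures, for Markov-equivalence comparison of two DAGs
dag_class <- function(dag) {
  und <- apply(dag$edges, 1L, function(e) paste(sort(e), collapse = "~"))
  vs <- character(0)
  for (n in dag$nodes) {
    pa <- sort(hearbn:::dag_parents(dag, n))
    if (length(pa) >= 2L) {
      for (i in seq_len(length(pa) - 1L)) for (j in (i + 1L):length(pa)) {
        adj <- paste(sort(c(pa[i], pa[j])), collapse = "~") %in% und
        if (!adj) vs <- c(vs, paste(pa[i], pa[j], "->", n))
      }
    }
  }
  list(skeleton = sort(und), v_structures = sort(vs))
}

markov_equivalent <- function(d1, d2) {
  identical(dag_class(d1), dag_class(d2))
}

## canonical-structure network with clearly detectable conditional effects,
## used for structure-recovery tests (synthetic: effect sizes are chosen for
## identifiability — interaction-rich loss rows so that no smaller
## factorization approximates the joint — not taken from any cohort)
strong_effect_net <- function() {
  lt <- expand.grid(family_history = c("No", "Yes"),
                    gender = c("Women", "Men"),
                    age_group = c("<29", "29-34", "35-39", "40-48", ">=49"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  probs <- local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(20240101)
    t(vapply(seq_len(nrow(lt)), function(i) {
      x <- -log(runif(5)) * c(8, 4, 2, 1, 0.5)  # distinct, interaction-rich rows
      x / sum(x)
    }, numeric(5)))
  })
  colnames(probs) <- c("I", "II", "III", "IV", "V")
  as_bn(generating_model(c(0.4, 0.6), rep(0.2, 5), c(0.7, 0.3),
                         cbind(lt, as.data.frame(probs))))
}

## small cohort data.frame fixture used by I/O tests
tiny_cohort_df <- function() {
  data.frame(
    id = c("a1", "a2", "a3"),
    gender = c("Women", "Men", "Men"),
    age_years = c(24, 38, 55),
    family_history = c("No", "No", "Yes"),
    binaural_loss_pct = c(0, 12.5, 33.4),
    loss_group = c("I", "II", "IV"),
    stringsAsFactors = FALSE)
}
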