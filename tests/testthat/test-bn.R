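test_that("parameter counting matches hand counts and the joint baseline", {
  d4 <- bn_dag(letters[1:4])
  card2 <- setNames(rep(2L, 4), letters[1:4])
  expect_equal(parameter_count(d4, card2), 4)        # four independent binaries
  expect_equal(prod(card2) - 1, 15)                  # unfactorized joint
  study <- canonical_dag()
  cards <- c(gender = 2L, age_group = 5L, family_history = 2L, loss_group = 5L)
  expect_equal(parameter_count(study, cards), 1 + 4 + 1 + 4 * 20)  # 86
  expect_error(parameter_count(study, cards[-1]), "cardinality")
})

test_that("joint probability is the product of CPT entries", {
  one <- make_bn(bn_dag("x"), list(x = array(c(0.3, 0.7), 2,
    dimnames = list(x = c("a", "b")))))
  expect_equal(joint_probability(one, list(x = "a")), 0.3)
  two <- make_bn(bn_dag(c("x", "y")), list(
    x = array(c(0.5, 0.5), 2, dimnames = list(x = c("a", "b"))),
    y = array(c(0.5, 0.5), 2, dimnames = list(y = c("a", "b")))))
  for (sx in c("a", "b")) for (sy in c("a", "b"))
    expect_equal(joint_probability(two, list(x = sx, y = sy)), 0.25)
  expect_error(joint_probability(two, list(x = "a")), "missing")
  ## random nets: joint sums to 1 by enumeration
  set.seed(21)
  for (rep in 1:5) {
    net <- random_net(sample(2:5, 1))
    grid <- expand.grid(net$schema, stringsAsFactors = FALSE)
    tot <- sum(vapply(seq_len(nrow(grid)), function(i)
      joint_probability(net, as.list(grid[i, ])), 0))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("maximum-likelihood fitting recovers relative frequencies", {
  df <- data.frame(g = factor(rep(c("A", "B"), c(3, 7))))
  fit <- fit_bn(bn_dag("g"), df, alpha = 0)
  expect_equal(as.vector(coef(fit)$g), c(0.3, 0.7))
  ## Laplace smoothing
  fit1 <- fit_bn(bn_dag("g"), df, alpha = 1)
  expect_equal(as.vector(coef(fit1)$g), c(4, 8) / 12)
  expect_error(fit_bn(bn_dag("g"), df[0, , drop = FALSE]), "empty")
})

test_that("unobserved parent configurations fall back to uniform under alpha = 0", {
  df <- data.frame(p = factor(c("u", "u", "u"), levels = c("u", "v")),
                   c = factor(c("x", "x", "y"), levels = c("x", "y")))
  fit <- fit_bn(bn_dag(c("p", "c"), rbind(c("p", "c"))), df, alpha = 0)
  cpt <- coef(fit)$c
  expect_equal(as.vector(cpt[, "u"]), c(2 / 3, 1 / 3))
  expect_equal(as.vector(cpt[, "v"]), c(0.5, 0.5))
})

test_that("variable elimination agrees with brute-force enumeration", {
  ## canonical-structure fixture with full evidence returns the CPT row
  net <- as_bn(default_generating_model())
  ev <- list(gender = "Women", age_group = "<29", family_history = "No")
  post <- query_posterior(net, "loss_group", ev)
  row <- coef(net)$loss_group[, "No", "Women", "<29"]
  expect_equal(unname(post), unname(row), tolerance = 1e-12)
  ## empty evidence on a root returns its prior
  expect_equal(unname(query_posterior(net, "gender", list())),
               c(0.1305, 0.8695), tolerance = 1e-12)
  ## partial evidence equals enumeration of the joint
  post2 <- query_posterior(net, "loss_group", list(gender = "Men"))
  expect_equal(post2, brute_posterior(net, "loss_group", list(gender = "Men")),
               tolerance = 1e-12)
  ## random small nets, random targets and evidence
  set.seed(22)
  for (rep in 1:25) {
    rnet <- random_net(sample(3:6, 1))
    vars <- rnet$dag$nodes
    target <- sample(vars, 1)
    nev <- sample(0:(length(vars) - 1L), 1)
    evars <- setdiff(sample(vars), target)[seq_len(nev)]
    ev <- lapply(rnet$schema[evars], function(s) sample(s, 1))
    post <- query_posterior(rnet, target, ev)
    expect_equal(sum(post), 1, tolerance = 1e-12)
    expect_equal(post, brute_posterior(rnet, target, ev), tolerance = 1e-12)
  }
})

test_that("impossible evidence raises a distinct error", {
  net <- make_bn(bn_dag(c("x", "y"), rbind(c("x", "y"))), list(
    x = array(c(1, 0), 2, dimnames = list(x = c("a", "b"))),
    y = array(c(1, 0, 0, 1), c(2, 2), dimnames = list(y = c("u", "v"),
                                                      x = c("a", "b")))))
  expect_error(query_posterior(net, "y", list(x = "b")), "impossible evidence")
  expect_error(query_posterior(net, "x", list(x = "a")), "target")
  expect_error(query_posterior(net, "x", list(z = "a")), "unknown evidence")
})

test_that("ancestral sampling is seeded, deterministic and degenerate-safe", {
  pm <- make_bn(bn_dag("x"), list(x = array(c(1, 0), 2,
    dimnames = list(x = c("a", "b")))))
  s <- simulate(pm, 100, seed = 5)
  expect_true(all(s$x == "a"))
  net <- as_bn(default_generating_model())
  s1 <- simulate(net, 500, seed = 7)
  s2 <- simulate(net, 500, seed = 7)
  expect_identical(s1, s2)
  expect_false(identical(simulate(net, 500, seed = 8), s1))
  ## simulate() leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate(net, 10, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("sampling converges to the model joint and parameters are recovered", {
  net <- strong_effect_net()
  big <- simulate(net, 200000, seed = 31)
  refit <- fit_bn(net$dag, big, alpha = 0)
  ## every CPT entry within 4 binomial standard errors of truth
  for (n in net$dag$nodes) {
    truth <- coef(net)[[n]]
    est <- coef(refit)[[n]]
    pa <- setdiff(hearbn:::factor_vars(truth), n)
    ## row totals = observed parent-configuration counts
    cnt <- if (length(pa)) table(big[pa]) else length(big[[n]])
    err <- abs(est - truth)
    se <- sqrt(pmax(truth * (1 - truth), 1e-12) /
                 rep(as.vector(cnt) + 1, each = dim(truth)[1L]))
    expect_true(all(err <= 4 * se + 1e-3),
                label = paste("CPT recovery for", n))
  }
  ## empirical joint of a smaller state space vs joint_probability
  set.seed(32)
  small <- random_net(3, max_states = 3)
  draws <- simulate(small, 500000, seed = 33)
  grid <- expand.grid(small$schema, stringsAsFactors = FALSE)
  key <- do.call(paste, grid)
  emp <- table(factor(do.call(paste, draws), levels = key)) / nrow(draws)
  for (i in seq_len(nrow(grid))) {
    p <- joint_probability(small, as.list(grid[i, ]))
    se <- sqrt(p * (1 - p) / nrow(draws))
    expect_lt(abs(emp[[key[i]]] - p), 4 * se + 1e-6)
  }
})

test_that("network JSON serialization round-trips bit-exactly", {
  set.seed(23)
  net <- random_net(4)
  path <- withr::local_tempfile(fileext = ".json")
  write_bn(net, path)
  back <- read_bn(path)
  expect_identical(back$dag$nodes, net$dag$nodes)
  expect_identical(back$dag$edges, net$dag$edges)
  for (n in net$dag$nodes)
    expect_identical(back$cpts[[n]], net$cpts[[n]])  # bit-exact doubles
  fit <- fit_bn(canonical_dag(),
                sample_cohort(default_generating_model(), 500, seed = 2),
                alpha = 1)
  write_bn(fit, path)
  back <- read_bn(path)
  expect_identical(back$cpts, fit$cpts)
  expect_equal(back$nobs, 500)
})

test_that("the formula interface builds the canonical structure and methods work", {
  co <- sample_cohort(default_generating_model(), 3000, seed = 9)
  fit <- hearing_bn(loss_group ~ gender + age_group + family_history, co)
  expect_true(markov_equivalent(fit$dag, canonical_dag()))
  expect_equal(fit$nobs, 3000)
  ## logLik: closed form for a root node
  df <- data.frame(g = factor(rep(c("A", "B"), each = 50)))
  f1 <- fit_bn(bn_dag("g"), df)
  ll <- logLik(f1, df)
  expect_equal(as.numeric(ll), 100 * log(0.5))
  expect_equal(attr(ll, "df"), 1)
  ## predict returns per-record posteriors consistent with query_posterior
  p <- predict(fit, co[1:5, ])
  expect_equal(dim(p), c(5L, 5L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  q <- query_posterior(fit, "loss_group",
                       list(gender = as.character(co$gender[1]),
                            age_group = as.character(co$age_group[1]),
                            family_history = as.character(co$family_history[1])))
  expect_equal(p[1, ], q, tolerance = 1e-12)
  cls <- predict(fit, co[1:5, ], type = "class")
  expect_s3_class(cls, "factor")
  s <- summary(fit)
  expect_equal(sum(s$marginals$loss_group), 1, tolerance = 1e-12)
})
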