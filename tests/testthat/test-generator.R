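test_that("the default generating model matches the published marginals and rows", {
  m <- default_generating_model()
  expect_equal(unname(m$gender_prior), c(0.1305, 0.8695))
  expect_equal(unname(m$age_prior), c(0.19, 0.20, 0.19, 0.21, 0.21))
  expect_equal(unname(m$fh_prior), c(1239, 179) / 1418)
  expect_equal(nrow(m$loss_table), 20L)
  expect_equal(unname(rowSums(m$loss_table[c("I", "II", "III", "IV", "V")])),
               rep(1, 20), tolerance = 1e-12)
  row <- m$loss_table[m$loss_table$family_history == "No" &
                        m$loss_table$gender == "Women" &
                        m$loss_table$age_group == "<29", ]
  expect_equal(as.numeric(row[c("I", "II", "III", "IV", "V")]),
               c(0.9804, 0.0196, 0, 0, 0), tolerance = 1e-4)
})

test_that("sampled cohorts reproduce the priors and are seed-deterministic", {
  m <- default_generating_model()
  co <- sample_cohort(m, 1418, seed = 101)
  counts <- table(co$gender)
  se <- sqrt(1418 * 0.1305 * 0.8695)
  expect_lt(abs(counts[["Women"]] - 185), 4 * se)
  expect_lt(abs(counts[["Men"]] - 1233), 4 * se)
  expect_identical(sample_cohort(m, 1418, seed = 101), co)
  expect_false(identical(sample_cohort(m, 1418, seed = 102), co))
  ## ages stay inside their group's band
  rng <- tapply(co$age_years, co$age_group, range)
  expect_true(all(rng[["<29"]] >= 17 & rng[["<29"]] <= 28))
  expect_true(all(rng[[">=49"]] >= 49 & rng[[">=49"]] <= 66))
  expect_equal(as.character(age_group(co$age_years)),
               as.character(co$age_group))
})

test_that("conditional loss rows are recovered from large samples", {
  m <- default_generating_model()
  co <- sample_cohort(m, 500000, seed = 103)
  cfg <- co$family_history == "No" & co$gender == "Men" & co$age_group == ">=49"
  phat <- mean(co$loss_group[cfg] == "I")
  truth <- m$loss_table[m$loss_table$family_history == "No" &
                          m$loss_table$gender == "Men" &
                          m$loss_table$age_group == ">=49", "I"]
  se <- sqrt(truth * (1 - truth) / sum(cfg))
  expect_lt(abs(phat - truth), 4 * se)
})

test_that("scenario cells fix the predictors and hit the requested row", {
  m <- default_generating_model()
  cell <- sample_cell(m, list(gender = "Women", age_group = "<29",
                              family_history = "No"), 100000, seed = 104)
  expect_true(all(cell$gender == "Women"))
  expect_true(all(cell$age_group == "<29"))
  p1 <- mean(cell$loss_group == "I")
  se <- sqrt(0.9804 * 0.0196 / 100000)
  expect_lt(abs(p1 - 0.9804), 4 * se + 1e-4)
  ## zero entries are never sampled (groups III-V have probability 0 here)
  expect_equal(sum(cell$loss_group %in% c("III", "IV", "V")), 0L)
  single <- sample_cell(m, list(gender = "Men", age_group = ">=49",
                                family_history = "Yes"), 1, seed = 1)
  expect_equal(nrow(single), 1L)
  expect_equal(as.character(single$gender), "Men")
  expect_error(sample_cell(m, list(gender = "Men"), 10, seed = 1), "config")
})

test_that("conditional recovery is insensitive to the predictor joint", {
  ## deliberately correlated predictor sampler: older workers made mostly men
  m <- default_generating_model()
  set.seed(105)
  n <- 200000
  ag <- sample(levels(age_group(20)), n, TRUE, c(0.1, 0.1, 0.1, 0.2, 0.5))
  gender <- ifelse(ag == ">=49",
                   sample(c("Women", "Men"), n, TRUE, c(0.02, 0.98)),
                   sample(c("Women", "Men"), n, TRUE, c(0.3, 0.7)))
  df <- data.frame(gender = factor(gender, levels = c("Women", "Men")),
                   age_group = factor(ag, levels = levels(age_group(20))),
                   family_history = factor(sample(c("No", "Yes"), n, TRUE,
                                                  c(0.5, 0.5)),
                                           levels = c("No", "Yes")))
  df$loss_group <- hearbn:::draw_loss(hearbn:::loss_rows(m, df))
  fit <- fit_bn(canonical_dag(), df, alpha = 0)
  post <- query_posterior(fit, "loss_group",
                          list(gender = "Men", age_group = ">=49",
                               family_history = "Yes"))
  truth <- as.numeric(m$loss_table[m$loss_table$family_history == "Yes" &
                                     m$loss_table$gender == "Men" &
                                     m$loss_table$age_group == ">=49",
                                   c("I", "II", "III", "IV", "V")])
  ncfg <- sum(df$gender == "Men" & df$age_group == ">=49" &
                df$family_history == "Yes")
  expect_true(all(abs(post - truth) <=
                    4 * sqrt(pmax(truth * (1 - truth), 1e-9) / ncfg) + 1e-4))
})

test_that("audiogram inversion round-trips loss percentages exactly", {
  expect_equal(unlist(audiogram_for_loss(0)), rep(25, 8), ignore_attr = TRUE)
  ag15 <- audiogram_for_loss(15)
  expect_equal(unlist(ag15), rep(35, 8), ignore_attr = TRUE)
  expect_equal(audiogram_loss(ag15)$binaural, 15)
  set.seed(106)
  pct <- c(0, 100, runif(500, 0, 100))
  back <- audiogram_loss(audiogram_for_loss(pct))$binaural
  expect_true(all(abs(back - pct) < 1e-9))
  expect_error(audiogram_for_loss(101), "\\[0, 100\\]")
})

test_that("group-interval percentages rediscretize to the sampled groups", {
  ## loss group -> uniform percentage in the group interval -> audiogram ->
  ## recomputed binaural loss -> discretized group: identity across modules
  co <- sample_cohort(default_generating_model(), 5000, seed = 107,
                      audiograms = TRUE)
  rebuilt <- loss_group(audiogram_loss(co)$binaural)
  expect_equal(as.character(rebuilt), as.character(co$loss_group))
  expect_true(all(co$binaural_loss_pct[co$loss_group == "I"] == 0))
  expect_true(all(co$binaural_loss_pct[co$loss_group == "V"] <= 67))
})

test_that("a generating model converts to an equivalent Bayesian network", {
  m <- default_generating_model()
  net <- as_bn(m)
  expect_true(markov_equivalent(net$dag, canonical_dag()))
  post <- query_posterior(net, "loss_group",
                          list(family_history = "Yes", gender = "Men",
                               age_group = ">=49"))
  expect_equal(unname(post[1]), 0.7229, tolerance = 1e-3)
})
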