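#' Published summary tables of the reference occupational cohort
#'
#' Loads the packaged JSON copy of the published summary tables for the
#' 1418-worker reference cohort: marginal counts for loss group, gender, age
#' group and family history, and the conditional loss-group distributions (in
#' percent) for every reported combination of predictors.
#'
#' @return named list of tables.
#' @export
ref_tables <- function() {
  path <- system.file("extdata", "reference_cohort_tables.json",
                      package = "hearbn", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

## turn one "loss_by_*" entry of ref_tables() into a conditional-table
## data.frame: conditioning columns + prob columns I..V (rows renormalized,
## the printed percentages carry rounding noise of up to ~0.01)
ref_loss_table <- function(entry) {
  by <- unlist(entry$by)
  rows <- lapply(entry$rows, function(r) {
    p <- unlist(r$pct)
    cbind(as.data.frame(r[by], stringsAsFactors = FALSE),
          as.data.frame(as.list(setNames(p / sum(p), .LOSS_STATES))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct a synthetic-cohort generating model
#'
#' A generating model holds independent priors over the three predictors and
#' one conditional loss-group table `P(loss_group | conditioning vars)`, where
#' the conditioning variables are any subset of
#' `gender, age_group, family_history`. Probability rows are renormalized to
#' sum exactly to 1.
#'
#' @param gender_prior,age_prior,fh_prior probability vectors over
#'   (Women, Men), the five age groups, and (No, Yes).
#' @param loss_table data frame with the conditioning columns followed by five
#'   probability columns `I ... V`, one row per conditioning configuration.
#' @return an object of class `generating_model`.
#' @seealso [default_generating_model()], [sample_cohort()]
#' @export
generating_model <- function(gender_prior, age_prior, fh_prior, loss_table) {
  norm <- function(p, k, what) {
    if (length(p) != k || any(p < 0) || sum(p) <= 0)
      stop("invalid prior for ", what)
    p / sum(p)
  }
  gender_prior <- norm(gender_prior, 2L, "gender")
  age_prior <- norm(age_prior, 5L, "age group")
  fh_prior <- norm(fh_prior, 2L, "family history")
  by <- setdiff(names(loss_table), .LOSS_STATES)
  if (!all(by %in% c("gender", "age_group", "family_history")) ||
      !all(.LOSS_STATES %in% names(loss_table)))
    stop("loss_table must have conditioning columns plus columns I..V")
  states <- list(gender = .GENDER_STATES, age_group = .AGE_STATES,
                 family_history = .FH_STATES)
  need <- prod(lengths(states[by]))
  if (nrow(loss_table) != need)
    stop("loss_table must have one row per configuration (", need, " expected)")
  p <- as.matrix(loss_table[.LOSS_STATES])
  if (any(p < 0)) stop("negative probabilities in loss_table")
  loss_table[.LOSS_STATES] <- p / rowSums(p)
  structure(list(gender_prior = setNames(gender_prior, .GENDER_STATES),
                 age_prior = setNames(age_prior, .AGE_STATES),
                 fh_prior = setNames(fh_prior, .FH_STATES),
                 by = by, loss_table = loss_table),
            class = "generating_model")
}

#' The default generating model calibrated to the reference cohort
#'
#' Predictor priors are the published marginals — gender (13.05 % women,
#' 86.95 % men), age quintiles (19/20/19/21/21 %), family history (87.38 % No,
#' 12.62 % Yes) — and the loss-group table is the published conditional
#' distribution given all three predictors (20 rows, renormalized).
#'
#' @return a `generating_model`.
#' @export
default_generating_model <- function() {
  tb <- ref_tables()
  generating_model(
    gender_prior = c(0.1305, 0.8695),
    age_prior = unlist(tb$age_groups$freq_pct) / 100,
    fh_prior = unlist(tb$family_history$counts) / sum(unlist(tb$family_history$counts)),
    loss_table = ref_loss_table(tb$loss_by_family_history_gender_age))
}

#' @export
print.generating_model <- function(x, ...) {
  cat("synthetic-cohort generating model\n")
  cat("  gender prior:        ", paste(sprintf("%s %.4f", names(x$gender_prior),
                                               x$gender_prior), collapse = ", "), "\n")
  cat("  age-group prior:     ", paste(sprintf("%.3f", x$age_prior), collapse = ", "), "\n")
  cat("  family-history prior:", paste(sprintf("%s %.4f", names(x$fh_prior),
                                               x$fh_prior), collapse = ", "), "\n")
  cat("  loss table: P(loss_group | ", paste(x$by, collapse = ", "), "), ",
      nrow(x$loss_table), " rows\n", sep = "")
  invisible(x)
}

## look up the loss-group probability rows matching each record's predictors
loss_rows <- function(model, df) {
  key <- do.call(paste, c(lapply(model$loss_table[model$by], as.character),
                          sep = "\r"))
  rec <- do.call(paste, c(lapply(df[model$by], as.character), sep = "\r"))
  idx <- match(rec, key)
  if (anyNA(idx)) stop("predictor configuration not covered by loss_table")
  as.matrix(model$loss_table[.LOSS_STATES])[idx, , drop = FALSE]
}

#' Sample a synthetic worker cohort
#'
#' Predictors are drawn independently from the model's priors; the loss group
#' is drawn from the conditional table given the drawn predictors; integer
#' `age_years` is uniform within the drawn age band (17-28, 29-34, 35-39,
#' 40-48, 49-66). With `audiograms = TRUE`, a binaural loss percentage is
#' drawn uniformly from the loss group's interval (group I: exactly 0; group V
#' capped at the reference maximum of 67 %) and converted into flat per-ear
#' thresholds via [audiogram_for_loss()], so the audiometric stage can be
#' exercised end to end.
#'
#' @param model a [generating_model()].
#' @param n number of records.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param audiograms also generate loss percentages and audiograms.
#' @return an `hl_cohort` data frame.
#' @export
sample_cohort <- function(model, n, seed = NULL, audiograms = FALSE) {
  stopifnot(inherits(model, "generating_model"), n >= 1)
  with_seed(seed, {
    df <- data.frame(
      id = sprintf("w%06d", seq_len(n)),
      gender = sample(.GENDER_STATES, n, TRUE, model$gender_prior),
      family_history = sample(.FH_STATES, n, TRUE, model$fh_prior),
      stringsAsFactors = FALSE)
    ag_idx <- sample.int(5L, n, TRUE, model$age_prior)
    df$age_years <- .AGE_LOWER[ag_idx] +
      floor(runif(n) * (.AGE_UPPER[ag_idx] - .AGE_LOWER[ag_idx] + 1L))
    df$age_group <- factor(.AGE_STATES[ag_idx], levels = .AGE_STATES)
    df$gender <- factor(df$gender, levels = .GENDER_STATES)
    df$family_history <- factor(df$family_history, levels = .FH_STATES)
    df$loss_group <- draw_loss(loss_rows(model, df))
    if (audiograms) {
      df$binaural_loss_pct <- loss_pct_for_group(df$loss_group)
      df <- cbind(df, audiogram_for_loss(df$binaural_loss_pct))
    }
    class(df) <- c("hl_cohort", "data.frame")
    df
  })
}

## vectorized categorical draw: one row of probabilities per record
draw_loss <- function(p) {
  cum <- t(apply(p, 1L, cumsum))
  u <- runif(nrow(p)) * cum[, 5L]
  idx <- 1L + rowSums(u > cum[, -5L, drop = FALSE] + 0)
  factor(.LOSS_STATES[idx], levels = .LOSS_STATES)
}

#' Sample one scenario cell
#'
#' All `n` records share the predictor configuration `config` (which must fix
#' gender, age group and family history); only the loss group is random, drawn
#' from the conditional-table row matching the configuration.
#'
#' @param model a [generating_model()].
#' @param config named list with `gender`, `age_group` and `family_history`.
#' @param n number of records.
#' @param seed integer seed.
#' @return an `hl_cohort` data frame.
#' @export
sample_cell <- function(model, config, n, seed = NULL) {
  stopifnot(inherits(model, "generating_model"), n >= 1)
  need <- c("gender", "age_group", "family_history")
  if (!all(need %in% names(config)))
    stop("config must fix all of: ", paste(need, collapse = ", "))
  with_seed(seed, {
    df <- data.frame(
      id = sprintf("w%06d", seq_len(n)),
      gender = factor(rep(config$gender, n), levels = .GENDER_STATES),
      age_group = factor(rep(config$age_group, n), levels = .AGE_STATES),
      family_history = factor(rep(config$family_history, n), levels = .FH_STATES),
      stringsAsFactors = FALSE)
    if (anyNA(df[1, c("gender", "age_group", "family_history")]))
      stop("config states outside the variable domains")
    ai <- match(config$age_group, .AGE_STATES)
    df$age_years <- .AGE_LOWER[ai] +
      floor(runif(n) * (.AGE_UPPER[ai] - .AGE_LOWER[ai] + 1L))
    df$loss_group <- draw_loss(loss_rows(model, df))
    class(df) <- c("hl_cohort", "data.frame")
    df
  })
}

## uniform loss percentage within each group's interval; group I is exactly 0,
## group V is capped at the reference cohort's observed maximum of 67 %
loss_pct_for_group <- function(group) {
  lo <- c(0, 0, 15, 30, 45)
  hi <- c(0, 15, 30, 45, 67)
  g <- as.integer(group)
  ifelse(g == 1L, 0, lo[g] + runif(length(g)) * (hi[g] - lo[g]))
}

#' Flat audiogram reproducing a given binaural loss percentage
#'
#' Algebraic inverse of the loss indices: both ears are given identical flat
#' thresholds `25 + pct / 1.5` dB HL at all four frequencies, so each monaural
#' loss — and hence the binaural loss — equals `pct` exactly.
#'
#' @param binaural_pct percentage(s) in \[0, 100\].
#' @return data frame with the eight threshold columns `l500 ... r3000`.
#' @examples
#' audiogram_loss(audiogram_for_loss(15))$binaural  # 15
#' @export
audiogram_for_loss <- function(binaural_pct) {
  if (any(!is.finite(binaural_pct)) || any(binaural_pct < 0 | binaural_pct > 100))
    stop("binaural_pct must be in [0, 100]")
  thr <- 25 + binaural_pct / 1.5
  out <- as.data.frame(matrix(rep(thr, 8L), ncol = 8L))
  names(out) <- audiogram_cols()
  out
}

#' Turn a generating model into a discrete Bayesian network
#'
#' Builds the equivalent `discrete_bn`: predictor priors as parentless CPTs
#' and the conditional loss table as the loss-group CPT (parents = the model's
#' conditioning variables). Useful as ground truth in recovery tests.
#'
#' @param model a [generating_model()].
#' @return a `discrete_bn`.
#' @export
as_bn <- function(model) {
  states <- list(gender = .GENDER_STATES, age_group = .AGE_STATES,
                 family_history = .FH_STATES, loss_group = .LOSS_STATES)
  nodes <- c("gender", "age_group", "family_history", "loss_group")
  dag <- bn_dag(nodes, if (length(model$by)) cbind(model$by, "loss_group"))
  pri <- list(gender = model$gender_prior, age_group = model$age_prior,
              family_history = model$fh_prior)
  cpts <- lapply(names(pri), function(n)
    array(unname(pri[[n]]), dim = length(states[[n]]),
          dimnames = setNames(list(states[[n]]), n)))
  names(cpts) <- names(pri)
  by <- model$by
  dims <- c(5L, lengths(states[by]))
  dn <- c(list(loss_group = .LOSS_STATES), states[by])
  arr <- array(NA_real_, dim = dims, dimnames = dn)
  grid <- model$loss_table[by]
  for (i in seq_len(nrow(grid))) {
    idx <- c(list(seq_len(5L)), lapply(by, function(v)
      match(as.character(grid[i, v]), states[[v]])))
    arr <- do.call(`[<-`, c(list(arr), idx,
                            list(as.numeric(model$loss_table[i, .LOSS_STATES]))))
  }
  cpts$loss_group <- arr
  make_bn(dag, cpts)
}
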