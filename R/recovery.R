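#' Sampling-and-refit recovery of a conditional loss-group distribution
#'
#' End-to-end check of the generative and inferential machinery against a
#' known conditional table: draw a seeded synthetic sample from a
#' [generating_model()], re-estimate the network by maximum likelihood
#' ([fit_bn()] with `alpha = 0` on a DAG whose loss-group parents are the
#' model's conditioning variables), and query the loss-group posterior for
#' one predictor configuration by variable elimination. As the sample grows,
#' the result converges to the generating table's row — the basis of the
#' package's recovery tests.
#'
#' @param model a [generating_model()].
#' @param condition named list of predictor states to condition on; must
#'   cover the model's conditioning variables (`model$by`).
#' @param n sample size.
#' @param seed integer seed.
#' @param method `"cohort"` draws full records with predictors from the
#'   model's priors ([sample_cohort()]); `"cell"` fixes all predictors at
#'   `condition` (completed with first states for variables the model does
#'   not condition on) and only draws loss groups ([sample_cell()]).
#' @return named posterior probability vector over the five loss groups.
#' @examples
#' m <- default_generating_model()
#' recover_conditional(m, list(family_history = "No", gender = "Women",
#'                             age_group = "<29"), 5000, seed = 1,
#'                     method = "cell")
#' @export
recover_conditional <- function(model, condition, n, seed,
                                method = c("cohort", "cell")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "generating_model"))
  condition <- lapply(condition, as.character)
  miss <- setdiff(model$by, names(condition))
  if (length(miss))
    stop("condition must cover the model's conditioning variable(s): ",
         paste(miss, collapse = ", "))
  if (method == "cohort") {
    co <- sample_cohort(model, n, seed = seed)
  } else {
    defaults <- list(gender = .GENDER_STATES[1L], age_group = .AGE_STATES[1L],
                     family_history = .FH_STATES[1L])
    config <- modifyList(defaults, condition)
    co <- sample_cell(model, config, n, seed = seed)
  }
  dag <- bn_dag(c(model$by, "loss_group"),
                if (length(model$by)) cbind(model$by, "loss_group"))
  fit <- fit_bn(dag, co[c(model$by, "loss_group")], alpha = 0)
  query_posterior(fit, "loss_group", condition[model$by])
}
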