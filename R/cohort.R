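#' Variable schema of a worker cohort
#'
#' Describes the four discrete study variables: `gender` (Women/Men),
#' `age_group` (five quintile bands), `family_history` (No/Yes) and
#' `loss_group` (I-V binaural-loss bands). Each entry is a `VariableSpec`
#' list with the variable name, its ordered state labels, and whether the
#' variable is ordinal.
#'
#' @return named list of variable specifications.
#' @export
cohort_schema <- function() {
  spec <- function(name, states, ordinal) {
    stopifnot(length(states) >= 2L, !anyDuplicated(states))
    list(name = name, states = states, ordinal = ordinal)
  }
  list(
    gender         = spec("gender", .GENDER_STATES, FALSE),
    age_group      = spec("age_group", .AGE_STATES, TRUE),
    family_history = spec("family_history", .FH_STATES, FALSE),
    loss_group     = spec("loss_group", .LOSS_STATES, TRUE)
  )
}

## normalize the two accepted loss-group notations ("I".."V", "Group 1".."Group 5",
## or bare digits) onto the canonical Roman labels
canonical_loss_label <- function(x) {
  x <- trimws(as.character(x))
  num <- sub("^[Gg]roup\\s*", "", x)
  idx <- ifelse(x %in% .LOSS_STATES, match(x, .LOSS_STATES),
                ifelse(num %in% as.character(1:5), as.integer(num), NA_integer_))
  out <- .LOSS_STATES[idx]
  out[is.na(x) | x == ""] <- NA
  out
}

#' Read a worker cohort from CSV
#'
#' Expects a header row and (a subset of) the columns `id`, `gender`,
#' `age_years`, `family_history`, the eight audiogram threshold columns
#' `l500 ... r3000`, `binaural_loss_pct` and `loss_group`. Each record must
#' carry at least one of audiogram / loss percentage / loss group. Empty
#' strings are missing values. Loss groups may be written either as Roman
#' numerals `I`-`V` or as `Group 1`-`Group 5`.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` of class `hl_cohort` with factor-coded categorical
#'   columns and a derived `age_group` column when `age_years` is present.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    read.csv(path, colClasses = "character", check.names = TRUE),
    error = function(e) stop("cannot parse CSV ", path, ": ", conditionMessage(e)))
  if (nrow(raw) == 0L && ncol(raw) <= 1L)
    stop("empty cohort file (no header / no columns): ", path)
  mandatory <- c("gender", "age_years", "family_history")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  as_cohort(raw, source = path)
}

## coerce a character data.frame into a typed, validated-by-construction cohort;
## row-level parse failures are reported with their (1-based) data row numbers
as_cohort <- function(raw, source = "cohort") {
  n <- nrow(raw)
  num_field <- function(col, what) {
    if (!col %in% names(raw)) return(NULL)
    x <- trimws(raw[[col]])
    x[x == ""] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop(sprintf("%s: non-numeric %s %s on row(s) %s", source, what, col,
                   paste(head(bad, 5L), collapse = ", ")))
    out
  }
  fct_field <- function(col, states) {
    if (!col %in% names(raw)) return(NULL)
    x <- trimws(raw[[col]])
    x[x == ""] <- NA
    bad <- which(!is.na(x) & !x %in% states)
    if (length(bad))
      stop(sprintf("%s: invalid %s value on row(s) %s (allowed: %s)", source,
                   col, paste(head(bad, 5L), collapse = ", "),
                   paste(states, collapse = "/")))
    factor(x, levels = states)
  }
  out <- data.frame(
    id = if ("id" %in% names(raw)) as.character(raw$id) else
      sprintf("w%04d", seq_len(n)),
    stringsAsFactors = FALSE)
  out$gender <- fct_field("gender", .GENDER_STATES)
  out$age_years <- num_field("age_years", "age")
  out$family_history <- fct_field("family_history", .FH_STATES)
  for (col in audiogram_cols()) {
    v <- num_field(col, "threshold")
    if (!is.null(v)) out[[col]] <- v
  }
  out$binaural_loss_pct <- num_field("binaural_loss_pct", "percentage")
  if ("loss_group" %in% names(raw)) {
    x <- canonical_loss_label(raw$loss_group)
    bad <- which(!is.na(trimws(raw$loss_group)) & trimws(raw$loss_group) != "" & is.na(x))
    if (length(bad))
      stop(sprintf("%s: invalid loss_group value on row(s) %s", source,
                   paste(head(bad, 5L), collapse = ", ")))
    out$loss_group <- factor(x, levels = .LOSS_STATES)
  }
  if (!is.null(out$age_years)) {
    ## invalid ages become NA groups here; validate_cohort() reports them
    ok <- !is.na(out$age_years) & out$age_years >= 0 & is.finite(out$age_years)
    out$age_group <- factor(rep(NA_character_, n), levels = .AGE_STATES)
    out$age_group[ok] <- age_group(out$age_years[ok])
  }
  out <- out[, !vapply(out, is.null, TRUE), drop = FALSE]
  class(out) <- c("hl_cohort", "data.frame")
  out
}

#' Write a worker cohort to CSV
#'
#' Inverse of [read_cohort()]: categorical states are stored as their printed
#' labels, missing values as empty strings, and percentages with full
#' precision, so that a read/write round trip reproduces the cohort.
#'
#' @param cohort a cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  keep <- intersect(c("id", "gender", "age_years", "family_history",
                      audiogram_cols(), "binaural_loss_pct", "loss_group"),
                    names(cohort))
  out <- as.data.frame(cohort)[, keep, drop = FALSE]
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Validate a cohort against the study schema
#'
#' Checks every record and reports violations as data rather than raising
#' errors: duplicate ids, negative ages, out-of-range percentages or
#' thresholds, records carrying none of audiogram / loss percentage / loss
#' group, and records whose stored `loss_group` disagrees with the group
#' recomputed from `binaural_loss_pct` (or from the audiogram).
#'
#' @param cohort a cohort data frame.
#' @return a `validation_report`: data frame with columns `id`, `field`,
#'   `problem`; zero rows iff the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  v <- list()
  note <- function(id, field, problem)
    v[[length(v) + 1L]] <<- data.frame(id = id, field = field, problem = problem)
  ids <- as.character(cohort$id)
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) note(d, "id", "duplicate id")
  has <- function(col) col %in% names(cohort)
  for (i in seq_len(nrow(cohort))) {
    r <- cohort[i, ]
    if (has("age_years") && !is.na(r$age_years) && r$age_years < 0)
      note(ids[i], "age_years", "negative age")
    ag <- if (all(audiogram_cols() %in% names(cohort)))
      unlist(r[audiogram_cols()]) else NULL
    has_ag <- !is.null(ag) && all(!is.na(ag))
    if (has_ag && any(ag < -10 | ag > 120))
      note(ids[i], "audiogram", "threshold outside [-10, 120] dB HL")
    pct <- if (has("binaural_loss_pct")) r$binaural_loss_pct else NA
    grp <- if (has("loss_group")) r$loss_group else NA
    if (!has_ag && is.na(pct) && is.na(grp))
      note(ids[i], "loss", "no audiogram, loss percentage or loss group")
    if (!is.na(pct) && (pct < 0 || pct > 100))
      note(ids[i], "binaural_loss_pct", "percentage outside [0, 100]")
    if (!is.na(pct) && !is.na(grp) && pct >= 0 && pct <= 100 &&
        loss_group(pct) != grp)
      note(ids[i], "loss_group",
           sprintf("loss_group %s inconsistent with binaural_loss_pct %.4g (expect %s)",
                   grp, pct, loss_group(pct)))
    if (has_ag && !is.na(pct) &&
        abs(audiogram_loss(r[audiogram_cols()])$binaural - pct) > 1e-6)
      note(ids[i], "binaural_loss_pct",
           "percentage inconsistent with audiogram")
  }
  rep <- if (length(v)) do.call(rbind, v) else
    data.frame(id = character(), field = character(), problem = character())
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("cohort valid: no violations\n")
  else {
    cat(nrow(x), "violation(s):\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Export a validation report as JSON
#'
#' @param report a [validate_cohort()] report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  jsonlite::write_json(
    list(valid = nrow(report) == 0L, n_violations = nrow(report),
         violations = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.hl_cohort <- function(x, ...) {
  cat("worker cohort:", nrow(x), "records\n")
  for (col in intersect(c("gender", "age_group", "family_history", "loss_group"),
                        names(x))) {
    tb <- table(x[[col]], useNA = "no")
    cat(sprintf("  %-15s %s\n", col,
                paste(sprintf("%s=%d", names(tb), tb), collapse = " ")))
  }
  invisible(x)
}
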