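#' Monaural hearing-loss percentage from pure-tone thresholds
#'
#' Computes the "social" monaural hearing-loss index for one ear from the
#' air-conduction thresholds at 500, 1000, 2000 and 3000 Hz: the four-frequency
#' threshold average, minus the 25 dB HL low fence, times 1.5, clamped to
#' \[0, 100\]. Thresholds at or below an average of 25 dB HL therefore count as
#' no loss, and averages of 91.67 dB HL or more as total (100 %) loss.
#'
#' @param thresholds numeric vector of four thresholds in dB HL, in frequency
#'   order (500, 1000, 2000, 3000) Hz, or a matrix/data frame with four columns
#'   (one row per ear).
#' @return numeric vector of loss percentages in \[0, 100\].
#' @examples
#' monaural_loss(c(30, 30, 30, 30))  # (30 - 25) * 1.5 = 7.5
#' monaural_loss(c(25, 25, 25, 25))  # exactly at the fence: 0
#' @seealso [binaural_loss()], [audiogram_loss()]
#' @export
monaural_loss <- function(thresholds) {
  if (is.data.frame(thresholds)) thresholds <- as.matrix(thresholds)
  if (is.matrix(thresholds)) {
    if (ncol(thresholds) != 4L)
      stop("`thresholds` must have four columns (500, 1000, 2000, 3000 Hz)")
    if (!all(is.finite(thresholds))) stop("thresholds must all be finite")
    m <- rowMeans(thresholds)
  } else {
    if (length(thresholds) != 4L)
      stop("`thresholds` must be four values (500, 1000, 2000, 3000 Hz)")
    if (!all(is.finite(thresholds))) stop("thresholds must all be finite")
    m <- mean(thresholds)
  }
  pmin(pmax((m - 25) * 1.5, 0), 100)
}

#' Binaural hearing-loss percentage from two monaural losses
#'
#' Weighted combination of the per-ear loss percentages: the better (smaller)
#' ear counts five times, the worse ear once, and the sum is divided by six.
#' The result always lies between the better and the worse monaural loss and
#' is symmetric in its arguments.
#'
#' @param loss_a,loss_b monaural loss percentages in \[0, 100\] (vectorized).
#' @return numeric vector of binaural loss percentages.
#' @examples
#' binaural_loss(10, 40)  # (5*10 + 40) / 6 = 15
#' @export
binaural_loss <- function(loss_a, loss_b) {
  if (any(!is.finite(loss_a)) || any(!is.finite(loss_b)) ||
      any(loss_a < 0 | loss_a > 100) || any(loss_b < 0 | loss_b > 100))
    stop("monaural losses must be finite percentages in [0, 100]")
  better <- pmin(loss_a, loss_b)
  worse  <- pmax(loss_a, loss_b)
  (5 * better + worse) / 6
}

#' Monaural and binaural loss percentages from a full audiogram
#'
#' @param audiogram a data frame (or list) with per-ear thresholds in dB HL in
#'   columns `l500, l1000, l2000, l3000, r500, r1000, r2000, r3000`, or a
#'   numeric vector of those eight values in that order.
#' @return a data frame with columns `monaural_left`, `monaural_right` and
#'   `binaural`, one row per audiogram.
#' @examples
#' audiogram_loss(c(30, 30, 30, 30, 25, 25, 25, 25))  # binaural (5*0 + 7.5)/6
#' @export
audiogram_loss <- function(audiogram) {
  cols <- audiogram_cols()
  if (is.numeric(audiogram) && is.null(dim(audiogram))) {
    if (length(audiogram) != 8L) stop("audiogram vector must have 8 thresholds")
    audiogram <- as.data.frame(as.list(setNames(audiogram, cols)))
  }
  if (!all(cols %in% colnames(audiogram)))
    stop("audiogram must contain columns ", paste(cols, collapse = ", "))
  left  <- monaural_loss(as.matrix(audiogram[, cols[1:4], drop = FALSE]))
  right <- monaural_loss(as.matrix(audiogram[, cols[5:8], drop = FALSE]))
  data.frame(monaural_left = left, monaural_right = right,
             binaural = binaural_loss(left, right))
}

audiogram_cols <- function() {
  c(paste0("l", .FREQS), paste0("r", .FREQS))
}

#' Discretize binaural loss percentages into groups I-V
#'
#' Group I is exactly 0 % loss; groups II-V partition (0, 100\] into
#' lower-exclusive / upper-inclusive intervals with cut points at 15, 30 and
#' 45 %. Labels are the Roman numerals I-V; the integer codes of the returned
#' factor are the equivalent "Group 1"-"Group 5" numbering.
#'
#' @param pct numeric vector of binaural loss percentages in \[0, 100\].
#' @return factor with levels `I, II, III, IV, V`.
#' @examples
#' loss_group(c(0, 15, 15.0001, 67))
#' @export
loss_group <- function(pct) {
  if (any(!is.finite(pct)) || any(pct < 0 | pct > 100))
    stop("loss percentages must be finite and in [0, 100]")
  idx <- ifelse(pct == 0, 1L, 1L + pmin(ceiling(pct / 15), 4L))
  factor(.LOSS_STATES[idx], levels = .LOSS_STATES)
}

#' Discretize age in years into the five study age groups
#'
#' Quintile-based bands with lower-inclusive / upper-exclusive edges at
#' 29, 35, 40 and 49 years: `<29`, `29-34`, `35-39`, `40-48`, `>=49`.
#'
#' @param age_years numeric vector of non-negative ages in whole years.
#' @return factor with the five age-group levels.
#' @examples
#' age_group(c(17, 38, 49, 66))
#' @export
age_group <- function(age_years) {
  if (any(!is.finite(age_years)) || any(age_years < 0))
    stop("ages must be finite and non-negative")
  cut(age_years, breaks = c(-Inf, 29, 35, 40, 49, Inf),
      labels = .AGE_STATES, right = FALSE)
}
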