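# Thresholded two-channel 5mC immunofluorescence statistic.

#' Two-channel image
#'
#' @param r Matrix of 5mC-channel pixel intensities (>= 0).
#' @param b Matrix of nuclear (DAPI) channel intensities, same shape.
#' @param t Background threshold (same units, >= 0). Pixels equal to `t`
#'   are background (strict inequalities throughout).
#' @return Object of class `two_channel_image`.
#' @export
two_channel_image <- function(r, b, t) {
  r <- as.matrix(r); b <- as.matrix(b)
  if (!identical(dim(r), dim(b))) stop("channel shapes differ")
  if (any(r < 0) || any(b < 0)) stop("negative pixel intensity")
  if (t < 0) stop("threshold must be >= 0")
  structure(list(r = r, b = b, t = t), class = "two_channel_image")
}

#' Per-image 5mC score
#'
#' Background-subtracted 5mC signal per nuclear pixel:
#' `sum over i of 1[b_i > t] * 1[r_i > t] * (r_i - t)` divided by
#' `sum over i of 1[b_i > t]`. Pixels whose nuclear channel does not exceed
#' the threshold contribute nothing regardless of their 5mC value.
#'
#' @param img A [two_channel_image()], or the `r` matrix when `b` and `t`
#'   are supplied.
#' @param b,t Optional nuclear channel and threshold (see
#'   [two_channel_image()]).
#' @return The score (intensity units, >= 0).
#' @export
#' @examples
#' mc5_score(rbind(c(5, 1), c(9, 9)), rbind(c(10, 10), c(0, 0)), 2)  # 1.5
mc5_score <- function(img, b = NULL, t = NULL) {
  if (!inherits(img, "two_channel_image")) {
    img <- two_channel_image(img, b, t)
  }
  nuclear <- img$b > img$t
  n <- sum(nuclear)
  if (n == 0) stop("no pixel exceeds the nuclear threshold: score undefined")
  signal <- nuclear & (img$r > img$t)
  sum((img$r[signal] - img$t)) / n
}

#' Otsu-style automatic threshold (optional, never the default)
#'
#' Maximizes between-class variance over a 256-level quantization of the
#' channel. Provided for exploratory use; the score itself always takes an
#' explicit threshold.
#'
#' @param x Intensity matrix or vector.
#' @return Threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  lv <- seq(rng[1], rng[2], length.out = 256)
  counts <- tabulate(findInterval(x, lv, rightmost.closed = TRUE), 256)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * lv)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  lv[which.max(sigma_b)]
}

#' Per-condition means and percent of control
#'
#' @param scores Data frame with columns `image`, `score`, `condition`
#'   (one row per field of view).
#' @param control Condition label of the control.
#' @return Data frame with `condition`, `n_fields`, `mean_score`,
#'   `percent_of_control`. A warning is emitted for any condition with
#'   fewer than 4 fields of view.
#' @export
percent_of_control <- function(scores, control) {
  need <- c("image", "score", "condition")
  if (!all(need %in% names(scores))) {
    stop("scores must have columns ", paste(need, collapse = ", "))
  }
  if (any(scores$score < 0)) stop("negative score")
  if (!control %in% scores$condition) {
    stop("control condition '", control, "' not present")
  }
  agg <- stats::aggregate(score ~ condition, data = scores,
                          FUN = function(s) c(n = length(s), m = mean(s)))
  out <- data.frame(condition = agg$condition,
                    n_fields = as.integer(agg$score[, "n"]),
                    mean_score = agg$score[, "m"],
                    stringsAsFactors = FALSE)
  ctrl_mean <- out$mean_score[out$condition == control]
  if (ctrl_mean == 0) stop("control mean score is zero")
  out$percent_of_control <- 100 * out$mean_score / ctrl_mean
  few <- out$condition[out$n_fields < 4]
  if (length(few) > 0) {
    warning("fewer than 4 fields of view for condition(s): ",
            paste(few, collapse = ", "))
  }
  out
}

#' Read a numeric-matrix CSV as an image channel
#'
#' Plain CSV of pixel intensities, no header.
#'
#' @param path CSV path.
#' @return Numeric matrix.
#' @export
read_channel_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' Write a numeric matrix as a channel CSV
#'
#' @param m Matrix.
#' @param path Output path.
#' @export
write_channel_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
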