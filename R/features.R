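# Index tables for the 84-term expansion: 7 base channels, 7 inverses,
# 7 squares, 21 products over unordered pairs i<j, 42 quotients over
# ordered pairs i != j (both in lexicographic order).
.expansion_index <- function() {
  ch <- flow_channels()
  pairs <- which(upper.tri(matrix(0, 7, 7)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  ord <- do.call(rbind, lapply(1:7, function(i) {
    cbind(i, setdiff(1:7, i))
  }))
  list(
    class = rep(c("base", "inverse", "square", "product", "quotient"),
                c(7L, 7L, 7L, 21L, 42L)),
    label = c(ch,
              paste0("1/", ch),
              paste0(ch, "^2"),
              paste0(ch[pairs[, 1]], "*", ch[pairs[, 2]]),
              paste0(ch[ord[, 1]], "/", ch[ord[, 2]])),
    prod_i = pairs[, 1], prod_j = pairs[, 2],
    quot_i = ord[, 1], quot_j = ord[, 2]
  )
}

#' Describe the 84 engineered per-event features
#'
#' @return A `data.frame` with columns `label` and `class`
#'   (`base`, `inverse`, `square`, `product`, `quotient`), one row per
#'   expanded feature, in the fixed column order of [expand_features()].
#' @export
expanded_feature_info <- function() {
  idx <- .expansion_index()
  data.frame(label = idx$label, class = idx$class,
             stringsAsFactors = FALSE)
}

#' Expand 7 channels into 84 engineered per-event features
#'
#' The linear projection and 1-d distribution comparison downstream cannot
#' represent interactions between channels, so the channel set is expanded
#' with all inverses (7), squares (7), pairwise products (21, unordered
#' pairs) and pairwise quotients (42, ordered pairs), raising the
#' dimensionality from 7 to 84.
#'
#' Any divisor `d` with `|d| < eps` is replaced by `sign(d) * eps` (with
#' `sign(0)` taken as +1) before inversion or division, so all outputs are
#' finite even when a log-scaled channel hits zero.
#'
#' @param m An [event_matrix()] (events x 7).
#' @param eps Positive clamp for small divisors, default `1e-6`.
#' @return An events x 84 matrix; column names are the expanded feature
#'   labels and the attribute `"feature_class"` gives each column's class.
#' @export
expand_features <- function(m, eps = 1e-6) {
  if (ncol(m) != 7L) {
    stop("expand_features() expects a 7-channel event matrix, got ",
         ncol(m), " columns", call. = FALSE)
  }
  stopifnot(eps > 0)
  m <- as.matrix(m)
  idx <- .expansion_index()
  # sign-preserving clamp with sign(0) = +1
  clamped <- m
  small <- abs(clamped) < eps
  if (any(small)) {
    s <- sign(clamped[small])
    s[s == 0] <- 1
    clamped[small] <- s * eps
  }
  out <- cbind(
    m,
    1 / clamped,
    m^2,
    m[, idx$prod_i, drop = FALSE] * m[, idx$prod_j, drop = FALSE],
    m[, idx$quot_i, drop = FALSE] / clamped[, idx$quot_j, drop = FALSE]
  )
  colnames(out) <- idx$label
  attr(out, "feature_class") <- idx$class
  out
}

.require_tubes <- function(p, min_events = 1L) {
  missing <- setdiff(as.character(1:7), names(p$tubes))
  if (length(missing)) {
    stop("patient ", p$patient_id, " is missing tube(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  small <- names(which(vapply(p$tubes, nrow, integer(1)) < min_events))
  if (length(small)) {
    stop("patient ", p$patient_id, " has fewer than ", min_events,
         " events in tube(s) ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-patient mean-intensity features (49)
#'
#' One feature per tube and channel: the arithmetic mean of the channel
#' over the tube's events.  CD45 and the scatter channels are kept as
#' separate features per tube rather than pooled across tubes; pooling
#' was found to hurt validation performance.
#'
#' @param p A [patient_sample()] with all 7 tubes.
#' @return Named numeric vector of length 49; names are
#'   `"<marker>_<tube>"`.
#' @export
mean_features <- function(p) {
  .require_tubes(p)
  vals <- unlist(lapply(1:7, function(t) {
    colMeans(p$tubes[[as.character(t)]])
  }))
  names(vals) <- unlist(lapply(1:7, function(t) {
    vapply(flow_channels(), function(ch) .marker_label(t, ch),
           character(1))
  }))
  vals
}

# Moments with the conventions used throughout: sample sd (n-1), skewness
# and kurtosis as third/fourth standardized central moments (normal
# kurtosis = 3, not excess), IQR with linear-interpolation quantiles.
# Degenerate (constant) channels map to sd = skew = kurt = IQR = 0.
.six_moments <- function(x) {
  n <- length(x)
  mu <- mean(x)
  cx <- x - mu
  m2 <- mean(cx^2)
  if (m2 == 0) {
    return(c(mean = mu, sd = 0, skew = 0, kurt = 0,
             median = mu, iqr = 0))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(mean = mu,
    sd = sqrt(sum(cx^2) / (n - 1)),
    skew = mean(cx^3) / m2^1.5,
    kurt = mean(cx^4) / m2^2,
    median = q[2],
    iqr = q[3] - q[1])
}

#' Per-patient moment features (294)
#'
#' Six distribution summaries per channel and tube: mean, standard
#' deviation, skewness, kurtosis, median, and interquartile range --
#' 6 x 7 channels x 7 tubes = 294 features.  These are the engineered
#' inputs of the moment-feature reference classifier.
#'
#' @param p A [patient_sample()] with all 7 tubes, each with at least 4
#'   events.
#' @return Named numeric vector of length 294; names are
#'   `"<stat>_<marker>_<tube>"`.
#' @export
moment_features <- function(p) {
  .require_tubes(p, min_events = 4L)
  stats_names <- c("mean", "sd", "skew", "kurt", "median", "iqr")
  out <- numeric(0)
  for (t in 1:7) {
    m <- p$tubes[[as.character(t)]]
    for (ch_i in 1:7) {
      v <- .six_moments(m[, ch_i])
      names(v) <- paste0(stats_names, "_",
                         .marker_label(t, flow_channels()[ch_i]))
      out <- c(out, v)
    }
  }
  out
}

#' Fit a z-score feature normalizer on training vectors
#'
#' Similarity scores and intensity features are put on a common scale
#' before the penalized fit so that coefficient magnitudes are comparable
#' across features.  The scale is the population standard deviation
#' (denominator `n`), matching the standardization convention of the
#' penalized fitter.  Features with zero training variance keep scale 1
#' (centering only) and are flagged.
#'
#' @param x Matrix of training feature vectors, one row per patient.
#' @return An object of class `feature_normalizer` with fields `center`,
#'   `scale`, `constant` (logical flags).
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop("need at least 2 training vectors to fit a normalizer",
         call. = FALSE)
  }
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2L, center)^2))
  constant <- scale == 0
  scale[constant] <- 1
  structure(list(center = center, scale = scale, constant = constant,
                 labels = colnames(x)),
            class = "feature_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param norm A [fit_normalizer()] object.
#' @param x Feature vector or matrix (rows = patients).
#' @return The z-scored vector/matrix.
#' @export
apply_normalizer <- function(norm, x) {
  stopifnot(inherits(norm, "feature_normalizer"))
  if (is.matrix(x)) {
    sweep(sweep(x, 2L, norm$center), 2L, norm$scale, `/`)
  } else {
    (x - norm$center) / norm$scale
  }
}
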