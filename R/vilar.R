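# Channel indices of the four 4-d sub-histograms of one tube: each keeps
# one of FL1/FL2/FL4/FL5 together with CD45 (FL3) and both scatters.
.vilar_subhist_channels <- function() {
  ch <- flow_channels()   # FS SS FL1 FL2 FL3 FL4 FL5
  lapply(c("FL1", "FL2", "FL4", "FL5"), function(fl) {
    match(c(fl, "FL3", "FS", "SS"), ch)
  })
}

#' Histogram specification for the KL reference method
#'
#' Per tube, the 7-d event density is approximated by four 4-d
#' histograms (one per non-CD45 fluorescence channel, always joined with
#' CD45, forward and side scatter), with `bins_per_dim` bins per
#' dimension.  Bin edges are uniform on the chosen scale between each
#' channel's `(low, high)` range; events outside the range of any of a
#' sub-histogram's dimensions are treated as outliers and discarded
#' before normalization.  The method is sensitive to the ranges, so they
#' are explicit configuration; [vilar_spec_from_cohort()] derives them
#' from training data.
#'
#' @param ranges List of 7 per-tube 7x2 matrices (`low`, `high` per
#'   channel, canonical order).
#' @param bins_per_dim Bins per dimension, default 9.
#' @param spacing `"linear"` (default: the pipeline consumes data whose
#'   scatter/fluorescence channels are already log-transformed, so
#'   linear spacing here corresponds to log-spaced bins in raw
#'   intensity) or `"log"` (requires positive `low`).
#' @return An object of class `vilar_spec`.
#' @export
vilar_spec <- function(ranges, bins_per_dim = 9L,
                       spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  stopifnot(bins_per_dim >= 2L, length(ranges) == 7L)
  for (t in 1:7) {
    r <- ranges[[t]]
    stopifnot(is.matrix(r), nrow(r) == 7L, ncol(r) == 2L)
    if (any(r[, 1] >= r[, 2])) {
      stop("invalid histogram range in tube ", t, ": low >= high",
           call. = FALSE)
    }
    if (spacing == "log" && any(r[, 1] <= 0)) {
      stop("log spacing requires positive range lows (tube ", t, ")",
           call. = FALSE)
    }
  }
  structure(list(ranges = ranges, bins_per_dim = as.integer(bins_per_dim),
                 spacing = spacing),
            class = "vilar_spec")
}

#' Derive a histogram spec from training data
#'
#' Ranges default to central quantiles of the pooled training events per
#' tube and channel, so a small fraction of extreme events is discarded
#' as outliers.
#'
#' @param cohort An `aml_cohort`.
#' @param probs Lower/upper quantile for the range, default
#'   `c(0.005, 0.995)`.
#' @param ... Passed to [vilar_spec()].
#' @return A `vilar_spec`.
#' @export
vilar_spec_from_cohort <- function(cohort, probs = c(0.005, 0.995), ...) {
  ranges <- lapply(1:7, function(t) {
    pooled <- do.call(rbind, lapply(cohort$patients, function(p) {
      p$tubes[[as.character(t)]]
    }))
    t(apply(pooled, 2L, stats::quantile, probs = probs, names = FALSE))
  })
  vilar_spec(ranges, ...)
}

.bin_edges <- function(low, high, bins, spacing) {
  if (spacing == "log") {
    exp(seq(log(low), log(high), length.out = bins + 1L))
  } else {
    seq(low, high, length.out = bins + 1L)
  }
}

#' Build the four 4-d histogram densities of one tube
#'
#' Events outside the range of any dimension of a sub-histogram are
#' discarded from that sub-histogram; the remaining events are binned
#' into half-open bins (last bin closed) and counts are normalized to
#' probabilities.
#'
#' @param m An [event_matrix()].
#' @param spec A [vilar_spec()].
#' @param tube_id Tube whose ranges apply, in 1..7.
#' @return Object of class `vilar_histogram`: `probs` (list of 4
#'   probability vectors over `bins^4` cells), `n_used`, `n_discarded`
#'   (per sub-histogram).
#' @export
build_histogram <- function(m, spec, tube_id) {
  stopifnot(inherits(spec, "vilar_spec"), tube_id %in% 1:7)
  m <- as.matrix(m)
  b <- spec$bins_per_dim
  rng <- spec$ranges[[tube_id]]
  subs <- .vilar_subhist_channels()
  probs <- vector("list", 4L)
  n_used <- integer(4L)
  n_disc <- integer(4L)
  for (s in seq_along(subs)) {
    dims <- subs[[s]]
    keep <- rep(TRUE, nrow(m))
    for (d in dims) {
      keep <- keep & m[, d] >= rng[d, 1] & m[, d] <= rng[d, 2]
    }
    x <- m[keep, dims, drop = FALSE]
    n_used[s] <- nrow(x)
    n_disc[s] <- nrow(m) - nrow(x)
    if (nrow(x) == 0L) {
      stop("empty histogram: all events of tube ", tube_id,
           " are out of range for sub-histogram ", s, call. = FALSE)
    }
    cell <- rep(1L, nrow(x))
    mult <- 1L
    for (q in seq_along(dims)) {
      edges <- .bin_edges(rng[dims[q], 1], rng[dims[q], 2], b,
                          spec$spacing)
      idx <- findInterval(x[, q], edges, rightmost.closed = TRUE)
      cell <- cell + (idx - 1L) * mult
      mult <- mult * b
    }
    counts <- tabulate(cell, nbins = b^4L)
    probs[[s]] <- counts / n_used[s]
  }
  structure(list(probs = probs, n_used = n_used, n_discarded = n_disc,
                 tube_id = tube_id),
            class = "vilar_histogram")
}

#' Kullback-Leibler divergence between two smoothed histograms
#'
#' Both probability vectors are smoothed by adding `alpha` to every cell
#' and renormalizing, then `sum(p * log(p / q))` is returned; by Gibbs'
#' inequality the result is nonnegative and zero iff the smoothed
#' distributions coincide.
#'
#' @param p,q Probability vectors of equal length.
#' @param alpha Additive smoothing, default `1e-6`.
#' @return Nonnegative scalar divergence `KL(p || q)`.
#' @export
kl_divergence <- function(p, q, alpha = 1e-6) {
  if (length(p) != length(q)) {
    stop("histogram shape mismatch: ", length(p), " vs ", length(q),
         call. = FALSE)
  }
  stopifnot(alpha > 0)
  pt <- (p + alpha) / sum(p + alpha)
  qt <- (q + alpha) / sum(q + alpha)
  sum(pt * log(pt / qt))
}

#' Train the KL-histogram reference classifier
#'
#' Class reference histograms are built per tube from the pooled events
#' of all training patients of the class.
#'
#' @param cohort An `aml_cohort` with labeled patients of both classes.
#' @param spec A [vilar_spec()]; derived from the training cohort when
#'   `NULL`.
#' @param alpha KL smoothing used at scoring time.
#' @param gain Logistic gain applied to the total divergence statistic.
#' @return Object of class `vilar_model`.
#' @export
vilar_train <- function(cohort, spec = NULL, alpha = 1e-6, gain = 1) {
  labels <- cohort_labels(cohort)
  if (sum(labels == 1, na.rm = TRUE) < 1 ||
      sum(labels == 0, na.rm = TRUE) < 1) {
    stop("training needs labeled patients of both classes",
         call. = FALSE)
  }
  if (is.null(spec)) {
    spec <- vilar_spec_from_cohort(cohort)
  }
  pool_class <- function(class_label, t) {
    do.call(rbind, lapply(
      cohort$patients[which(labels == class_label)],
      function(p) p$tubes[[as.character(t)]]))
  }
  refs <- lapply(1:7, function(t) {
    list(healthy = build_histogram(pool_class(0, t), spec, t),
         aml = build_histogram(pool_class(1, t), spec, t))
  })
  structure(list(spec = spec, refs = refs, alpha = alpha, gain = gain),
            class = "vilar_model")
}

#' Score a patient with the KL-histogram classifier
#'
#' The total statistic sums, over tubes and sub-histograms, the relative
#' entropy of the test histogram against the healthy reference minus
#' that against the AML reference; proximity to the AML reference thus
#' raises the statistic.  The AML confidence is the logistic map
#' `plogis(gain * T)`.
#'
#' @param p A [patient_sample()] with all 7 tubes.
#' @param model A [vilar_train()] fit.
#' @return Confidence in (0, 1); the attribute `"statistic"` carries the
#'   raw total divergence difference.
#' @export
vilar_score <- function(p, model) {
  stopifnot(inherits(model, "vilar_model"))
  .require_tubes(p)
  total <- 0
  for (t in 1:7) {
    h <- build_histogram(p$tubes[[as.character(t)]], model$spec, t)
    ref <- model$refs[[t]]
    for (s in 1:4) {
      total <- total +
        kl_divergence(h$probs[[s]], ref$healthy$probs[[s]],
                      model$alpha) -
        kl_divergence(h$probs[[s]], ref$aml$probs[[s]], model$alpha)
    }
  }
  structure(stats::plogis(model$gain * total), statistic = total)
}
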