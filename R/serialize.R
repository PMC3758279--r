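# JSON serialization of trained models and reports.  Numbers are written
# at full double precision so a save/load round trip is exact to text
# precision.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Save a trained model or report as JSON
#'
#' Supported: `tube_models` (per tube: grid, reference EDF values, LDA
#' weights and ridge), `l1_logreg` (labels, intercept, sparse
#' coefficients, penalty, standardization), `vilar_model` (spec, ranges,
#' flattened reference probabilities) and `evaluation_report`.
#'
#' @param x The object to save.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(x, path) {
  obj <- if (inherits(x, "tube_models")) {
    list(type = "tube_models", K = x$K, eps = x$eps,
         reference = x$reference,
         tubes = lapply(x$tubes, function(tm) {
           list(tube_id = tm$direction$tube_id,
                w = tm$direction$w, ridge = tm$direction$ridge,
                grid = unclass(tm$grid),
                ref_healthy = tm$ref_healthy, ref_aml = tm$ref_aml)
         }))
  } else if (inherits(x, "l1_logreg")) {
    nz <- which(x$beta != 0)
    list(type = "l1_logreg", lambda = x$lambda, beta0 = x$beta0,
         labels = x$labels,
         support = as.list(stats::setNames(x$beta[nz], x$labels[nz])),
         center = x$center, scale = x$scale)
  } else if (inherits(x, "vilar_model")) {
    list(type = "vilar_model", alpha = x$alpha, gain = x$gain,
         bins_per_dim = x$spec$bins_per_dim, spacing = x$spec$spacing,
         ranges = lapply(x$spec$ranges, function(r) {
           list(low = r[, 1], high = r[, 2])
         }),
         refs = lapply(x$refs, function(rf) {
           list(healthy = rf$healthy$probs, aml = rf$aml$probs)
         }))
  } else if (inherits(x, "evaluation_report")) {
    list(type = "evaluation_report", method = x$method,
         auc_roc = x$auc_roc, auc_pr = x$auc_pr,
         challenge_score = x$challenge_score,
         threshold = x$threshold,
         confusion = as.list(unclass(x$confusion)),
         scores = x$scores, labels = x$labels,
         failed_folds = x$failed_folds,
         k = x$k, repeats = x$repeats, seed = x$seed)
  } else {
    stop("don't know how to serialize objects of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  .write_json(obj, path)
}

#' Load a model saved by [write_model()]
#'
#' @param path JSON file path.
#' @return The reconstructed object (same class as saved).  Evaluation
#'   reports are returned as plain lists.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  switch(obj$type,
    tube_models = structure(
      list(tubes = lapply(obj$tubes, function(tm) {
        list(direction = structure(
               list(w = tm$w, ridge = tm$ridge,
                    tube_id = tm$tube_id),
               class = "lda_direction"),
             grid = structure(tm$grid[c("x1", "delta", "K")],
                              class = "edf_grid"),
             ref_healthy = tm$ref_healthy, ref_aml = tm$ref_aml)
      }),
      K = obj$K, eps = obj$eps, reference = obj$reference),
      class = "tube_models"),
    l1_logreg = {
      beta <- stats::setNames(numeric(length(obj$labels)), obj$labels)
      beta[names(obj$support)] <- unlist(obj$support)
      structure(
        list(beta0 = obj$beta0, beta = beta,
             beta_std = beta * obj$scale,
             lambda = obj$lambda, labels = obj$labels,
             center = stats::setNames(obj$center, obj$labels),
             scale = stats::setNames(obj$scale, obj$labels)),
        class = "l1_logreg")
    },
    vilar_model = {
      ranges <- lapply(obj$ranges, function(r) {
        cbind(r$low, r$high)
      })
      spec <- vilar_spec(ranges, bins_per_dim = obj$bins_per_dim,
                         spacing = obj$spacing)
      refs <- lapply(seq_len(7), function(t) {
        rf <- obj$refs[[t]]
        mk <- function(pl) {
          structure(list(probs = pl, tube_id = t),
                    class = "vilar_histogram")
        }
        list(healthy = mk(rf$healthy), aml = mk(rf$aml))
      })
      structure(list(spec = spec, refs = refs, alpha = obj$alpha,
                     gain = obj$gain),
                class = "vilar_model")
    },
    evaluation_report = obj,
    stop("unknown serialized type: ", obj$type, call. = FALSE))
}
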