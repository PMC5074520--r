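# Model persistence: a single JSON document embedding the feature list,
# normalization statistics, regression parameters (or SVR dual
# representation), PWM matrices with their background, the decision
# threshold and provenance. JSON keeps the artifact diff-able.

#' Write a trained model to JSON
#'
#' @param model A `tis_model` (typically `run_experiment(...)$best_model`).
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  doc <- list(
    format = "tiscall-model", version = 1L,
    kind = model$kind,
    feature_names = model$feature_names,
    center = as.list(model$center),
    scale = as.list(model$scale),
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    svr = if (!is.null(model$svr)) list(
      kernel = model$svr$kernel, cost = model$svr$cost,
      epsilon = model$svr$epsilon, gamma = model$svr$gamma,
      degree = model$svr$degree, coef0 = model$svr$coef0,
      rho = model$svr$rho, dual_coefs = model$svr$dual_coefs,
      support_vectors = model$svr$support_vectors
    ),
    pwm = if (!is.null(model$pwm)) list(
      width = model$pwm$width, pseudocount = model$pwm$pseudocount,
      bg = as.list(model$pwm$bg),
      pfm_pos = model$pwm$pfm_pos, pfm_neg = model$pwm$pfm_neg
    ),
    threshold = model$threshold,
    confidence_bounds = list(very_high = 0.9, high = 0.8, moderate = 0.7),
    window = model$window,
    seed = model$seed
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a trained model from JSON
#'
#' Reconstructs a `tis_model` written by [write_model()]; PWMs are rebuilt
#' from the stored frequency matrices and background.
#'
#' @param path Path to a model JSON file.
#' @return A `tis_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "tiscall-model")) {
    stop("not a tiscall model file: ", path)
  }
  m <- list(kind = doc$kind, feature_names = doc$feature_names,
            center = unlist(doc$center), scale = unlist(doc$scale),
            threshold = doc$threshold, window = doc$window, seed = doc$seed)
  if (!is.null(doc$intercept)) {
    m$intercept <- doc$intercept
    m$coefficients <- unlist(doc$coefficients)
  }
  if (!is.null(doc$svr)) {
    m$svr <- doc$svr
    m$svr$support_vectors <- as.matrix(doc$svr$support_vectors)
  }
  if (!is.null(doc$pwm)) {
    bg <- unlist(doc$pwm$bg)[NT]
    pfm_pos <- as.matrix(doc$pwm$pfm_pos)
    pfm_neg <- as.matrix(doc$pwm$pfm_neg)
    rownames(pfm_pos) <- rownames(pfm_neg) <- NT
    m$pwm <- structure(
      list(pfm_pos = pfm_pos, pfm_neg = pfm_neg, bg = bg,
           pwm_pos = log(pfm_pos / bg), pwm_neg = log(pfm_neg / bg),
           pwm_ratio = log(pfm_pos / pfm_neg),
           width = doc$pwm$width, pseudocount = doc$pwm$pseudocount),
      class = "tis_pwm"
    )
  }
  structure(m, class = "tis_model")
}
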