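#' Serialize a trained model to JSON
#'
#' Writes a plain-text JSON record of the model's defining quantities —
#' kernel, penalty, tube width, dual coefficients, bias, support
#' indices, and (linear models) the explicit weight vector — at full
#' double precision.  [read_model()] reconstructs a predictor from it;
#' training data are stored alongside the coefficients because kernel
#' models need them for prediction.
#'
#' @param model A `binary_svm`, `svr_model`, or `multiclass_svm`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rec <- if (inherits(model, "binary_svm")) {
    list(type = "binary_svm", kernel = model$kernel$kind,
         sigma = model$kernel$sigma, C = model$C, alpha = model$alpha,
         b = model$b, support = model$support, w = model$w,
         X = model$X, y = model$y)
  } else if (inherits(model, "svr_model")) {
    list(type = "svr_model", kernel = model$kernel$kind,
         sigma = model$kernel$sigma, C = model$C,
         epsilon = model$epsilon, alpha = model$alpha,
         alpha_star = model$alpha_star, b = model$b,
         support = model$support, w = model$w, X = model$X, y = model$y)
  } else if (inherits(model, "multiclass_svm")) {
    list(type = "multiclass_svm", C = model$C, levels = model$levels,
         W = model$W, b = model$b, objective = model$objective)
  } else {
    abort("unsupported model class: ", paste(class(model), collapse = "/"))
  }
  jsonlite::write_json(rec[!vapply(rec, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @param path Path to a JSON file written by [write_model()].
#' @return `read_model()` returns the reconstructed model object.
#' @export
read_model <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m) if (is.matrix(m)) m else as.matrix(m)
  if (rec$type == "binary_svm") {
    kern <- kernel_spec(rec$kernel, if (rec$kernel == "rbf") rec$sigma else 2)
    m <- structure(list(alpha = rec$alpha, b = rec$b, C = rec$C,
                        kernel = kern, support = as.integer(rec$support),
                        X = as_mat(rec$X), y = rec$y,
                        w = rec$w, objective = NA_real_),
                   class = "binary_svm")
  } else if (rec$type == "svr_model") {
    kern <- kernel_spec(rec$kernel, if (rec$kernel == "rbf") rec$sigma else 2)
    m <- structure(list(beta = rec$alpha - rec$alpha_star,
                        alpha = rec$alpha, alpha_star = rec$alpha_star,
                        b = rec$b, C = rec$C, epsilon = rec$epsilon,
                        kernel = kern, support = as.integer(rec$support),
                        X = as_mat(rec$X), y = rec$y, w = rec$w,
                        objective = NA_real_),
                   class = "svr_model")
  } else if (rec$type == "multiclass_svm") {
    m <- structure(list(W = as_mat(rec$W), b = rec$b, C = rec$C,
                        levels = rec$levels, objective = rec$objective),
                   class = "multiclass_svm")
  } else {
    abort("unknown model type in ", path)
  }
  m
}
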