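#' Base learner specification
#'
#' A base learner is the binary classifier fitted for every ordered class
#' pair. The default, [svm_learner()], is a linear soft-margin support vector
#' machine with cost 1 (LIBSVM via \pkg{e1071}), no feature scaling and no
#' class weighting; its decision threshold at exactly 0 predicts the second
#' class, i.e. the sample is passed on.
#'
#' A learner is a list with a \code{fit(features, labels)} function returning
#' a fitted model, a \code{predict(model, features)} function returning labels
#' from the fitted pair, and a \code{name} used in provenance records.
#'
#' @param cost soft-margin cost parameter C (default 1).
#' @param ... further arguments passed to [e1071::svm()].
#' @return An object of class \code{base_learner}.
#' @export
svm_learner <- function(cost = 1, ...) {
  extra <- list(...)
  base_learner(
    fit = function(features, labels) {
      do.call(e1071::svm,
              c(list(x = features, y = factor(labels),
                     kernel = "linear", cost = cost, scale = FALSE),
                extra))
    },
    predict = function(model, features) {
      as.character(stats::predict(model, features))
    },
    name = sprintf("linear-svm(cost=%g)", cost),
    hyperparameters = c(list(cost = cost), extra)
  )
}

#' @rdname svm_learner
#' @param fit function \code{(features, labels) -> model}.
#' @param predict function \code{(model, features) -> labels}.
#' @param name short description used in provenance.
#' @param hyperparameters opaque key-value settings, recorded only.
#' @export
base_learner <- function(fit, predict, name = "custom",
                         hyperparameters = list()) {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(fit = fit, predict = predict, name = name,
                 hyperparameters = hyperparameters),
            class = "base_learner")
}
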