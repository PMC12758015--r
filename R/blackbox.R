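#' Wrap a victim model as an opaque score interface
#'
#' Enforces the black-box contract: downstream code can obtain scores for
#' patches in the victim's expected format, and nothing else — no
#' parameters, gradients, architecture or training data are reachable
#' through the interface. A query counter records how much the interface
#' has been exercised.
#'
#' Any scoring function can be wrapped, not just a [build_classifier()]
#' model; the migration engine is thereby provably independent of the
#' victim's implementation.
#'
#' @param model A `qus_classifier`, or a function mapping an
#'   n x h x w patch array to n scores in `[0, 1]`.
#' @param input_shape Expected patch `c(height, width)`; defaults to the
#'   model's own input shape when wrapping a classifier.
#' @param hard_labels If `TRUE` the interface returns thresholded 0/1
#'   labels instead of continuous scores (a stricter threat model).
#' @return An object of class `victim_interface`.
#' @export
victim_interface <- function(model, input_shape = NULL,
                             hard_labels = FALSE) {
  if (inherits(model, "qus_classifier")) {
    score_fun <- local({
      frozen <- model
      function(X) predict_scores(frozen, X)
    })
    if (is.null(input_shape)) input_shape <- model$spec$input_shape
  } else if (is.function(model)) {
    score_fun <- model
    if (is.null(input_shape)) {
      stop("input_shape is required when wrapping a plain function",
           call. = FALSE)
    }
  } else {
    stop("'model' must be a qus_classifier or a function", call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$counter <- 0L
  iface <- list(
    query = function(X) {
      if (!identical(as.integer(dim(X)[2:3]), as.integer(input_shape))) {
        stop("patch shape rejected by the victim interface", call. = FALSE)
      }
      env$counter <- env$counter + dim(X)[1]
      s <- score_fun(X)
      if (hard_labels) as.numeric(s >= 0.5) else s
    },
    input_shape = as.integer(input_shape),
    counter_env = env)
  class(iface) <- "victim_interface"
  iface
}

#' Query the victim interface
#'
#' @param iface A [victim_interface()].
#' @param patches A `patch_set` or n x h x w array, standardized and at
#'   the victim sampling rate.
#' @return One score per patch; the interface's query counter advances by
#'   the patch count.
#' @export
query <- function(iface, patches) {
  if (!inherits(iface, "victim_interface")) {
    stop("'iface' must be a victim_interface", call. = FALSE)
  }
  iface$query(patch_array(patches))
}

#' @rdname query
#' @export
query_count <- function(iface) {
  iface$counter_env$counter
}

#' @export
print.victim_interface <- function(x, ...) {
  cat(sprintf("<victim_interface> expects %d x %d patches; %d patches queried\n",
              x$input_shape[1], x$input_shape[2], query_count(x)))
  invisible(x)
}
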