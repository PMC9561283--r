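# Multiple-instance building blocks: gated attention pooling, Noisy-OR read
# aggregation, and sliding-window instance extraction.

#' Create gated-attention pooling parameters
#'
#' @param d Feature dimension of the bag members.
#' @param a Attention hidden dimension (default 64).
#' @param seed Integer seed for the random initialization.
#' @return Parameter list (`V`, `U`, `w`) for [attention_pool()].
#' @export
attention_params <- function(d, a = 64L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  attn_params(d, a)
}

#' Gated attention pooling over a bag of feature vectors
#'
#' Computes a per-member gated query `tanh(h V) * sigmoid(h U)`, scores each
#' member against a learned context vector `w`, normalizes the scores with a
#' softmax, and returns the weighted average of the members. Weights are
#' non-negative and sum to one over the bag.
#'
#' @param features Numeric matrix, one row per bag member.
#' @param params Parameters from [attention_params()].
#' @return List with `pooled` (length-`d` vector) and `weights` (one per
#'   member, summing to 1).
#' @export
attention_pool <- function(features, params) {
  features <- as.matrix(features)
  if (nrow(features) < 1L) stop("bag must have at least one member")
  if (ncol(features) < 1L) stop("zero-dimensional features")
  fw <- attn_forward(params, features)
  list(pooled = fw$pooled, weights = fw$weights)
}

#' Noisy-OR aggregation of read-level probabilities
#'
#' The probability that a site is modified given independent per-read
#' modification probabilities: `1 - prod(1 - p_i)`. Padding members (from
#' fixed-size read bags) are excluded via `real`.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param real Optional logical mask; only `p[real]` enter the product.
#' @return Site-level probability.
#' @export
noisy_or <- function(p, real = NULL) {
  if (!is.null(real)) p <- p[real]
  if (length(p) == 0L) stop("noisy_or needs at least one probability")
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  1 - prod(1 - p)
}

#' Split a sequence into fixed-length instances with a sliding window
#'
#' Windows of `length` nucleotides are taken at offsets 0, `stride`,
#' 2 `stride`, ...; a final partial window is dropped, giving
#' `floor((L - length) / stride) + 1` instances.
#'
#' @param x A character scalar (sequence) or a matrix with one row per
#'   nucleotide (e.g. a one-hot sequence matrix).
#' @param length Instance length (default 50).
#' @param stride Offset between instance starts (default 10).
#' @return For a string: character vector of instances. For a matrix: a list
#'   of row-slices.
#' @export
make_instances <- function(x, length = 50L, stride = 10L) {
  L <- if (is.character(x)) nchar(x) else nrow(x)
  if (L < length)
    stop("sequence length ", L, " is shorter than the instance length ",
         length, "; pad the input first")
  starts <- seq.int(1L, L - length + 1L, by = stride)
  if (is.character(x))
    return(vapply(starts, function(s) substr(x, s, s + length - 1L), character(1)))
  lapply(starts, function(s) x[s:(s + length - 1L), , drop = FALSE])
}
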