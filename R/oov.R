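# Out-of-vocabulary embedding projection: a weighted least-squares linear map
# from a word-embedding space (e.g. 300-D Word2Vec) into the sentence-encoder
# embedding space, so unseen domain words can be represented.

#' Fit the OOV least-squares projection
#'
#' Solves `min_M sum_i w_i || s_i M - t_i ||^2` over paired rows of `source`
#' and `target`. Weights default to uniform. Underdetermined systems (fewer
#' pairs than source dimensions) resolve to the minimum-norm solution via the
#' pseudoinverse, which reproduces the training targets exactly.
#'
#' @param source numeric matrix, `n x d_source` (word vectors).
#' @param target numeric matrix, `n x d_target` (sentence-space vectors).
#' @param weights optional nonnegative length-`n` regression weights.
#' @return a `vqa_oov_projection`: list with `map` (`d_source x d_target`),
#'   `residual` (root weighted sum of squared fit errors), `weights`.
#' @export
fit_oov_projection <- function(source, target, weights = NULL) {
  source <- as.matrix(source); target <- as.matrix(target)
  ovqa_assert(nrow(source) == nrow(target),
              "`source` and `target` must have the same number of rows")
  ovqa_assert(ncol(source) >= 1, "`source` must have at least one column")
  n <- nrow(source)
  w <- weights %||% rep(1, n)
  ovqa_assert(length(w) == n && all(w >= 0), "`weights` must be nonnegative, length n")
  sw <- sqrt(w)
  s <- source * sw
  t <- target * sw
  sv <- svd(s)
  tol <- max(dim(s)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  dinv <- ifelse(pos, 1 / sv$d, 0)
  map <- sv$v %*% (dinv * (t(sv$u) %*% t))   # minimum-norm weighted LS solution
  resid <- sqrt(sum(((source %*% map - target)^2) * w))
  structure(list(map = map, residual = resid, weights = w),
            class = "vqa_oov_projection")
}

#' Apply an OOV projection
#'
#' @param projection a [fit_oov_projection()] result.
#' @param vectors matrix (or vector) of source-space embeddings.
#' @return projected embeddings in the target space.
#' @export
apply_oov_projection <- function(projection, vectors) {
  v <- if (is.matrix(vectors)) vectors else matrix(vectors, nrow = 1)
  ovqa_assert(ncol(v) == nrow(projection$map), "source dimension mismatch")
  v %*% projection$map
}
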