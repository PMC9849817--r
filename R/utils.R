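# Internal helpers shared across modules.

#' Signal a classed package error
#'
#' All validation failures raised by the package carry a subclass of
#' `orchardvqa_error` so callers can branch on the failure kind
#' (e.g. `orchardvqa_invalid_input`, `orchardvqa_contract_violation`).
#'
#' @param message error message.
#' @param class error subclass (character scalar, without package prefix).
#' @param ... additional condition fields.
#' @keywords internal
#' @noRd
ovqa_stop <- function(message, class = "invalid_input", ...) {
  cond <- structure(
    class = c(paste0("orchardvqa_", class), "orchardvqa_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

ovqa_assert <- function(ok, message, class = "invalid_input") {
  if (!isTRUE(ok)) ovqa_stop(message, class = class)
  invisible(TRUE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls do not perturb the
#' caller's RNG stream. All randomness in the package flows through explicit
#' integer seeds passed to this helper.
#'
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  ovqa_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "`seed` must be a single finite integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result in the 32-bit signed integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.double(seed) * 48271 + h) %% .Machine$integer.max)
}

# ---- parameter-tree utilities -----------------------------------------------
# Model parameters are nested named lists whose leaves are numeric vectors or
# matrices; gradients share the same shape.

tree_map <- function(f, tree) {
  if (is.list(tree)) return(lapply(tree, function(x) tree_map(f, x)))
  f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    ovqa_assert(is.list(b) && length(a) == length(b), "parameter trees differ in shape")
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    return(out)
  }
  f(a, b)
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

#' Count the scalar parameters in a parameter tree
#'
#' @param params a nested list of numeric leaves (model parameters).
#' @return integer count of scalar entries.
#' @export
count_params <- function(params) {
  if (is.list(params)) return(sum(vapply(params, count_params, numeric(1))))
  length(params)
}

# Flatten / unflatten a parameter tree to a numeric vector (finite-difference
# gradient checks and optimizer state bookkeeping).
tree_flatten <- function(tree) {
  if (is.list(tree)) return(unlist(lapply(tree, tree_flatten), use.names = FALSE))
  as.numeric(tree)
}

tree_unflatten <- function(tree, values) {
  pos <- 0L
  rebuild <- function(node) {
    if (is.list(node)) return(lapply(node, rebuild))
    n <- length(node)
    out <- values[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(node)) dim(out) <- dim(node)
    out
  }
  out <- rebuild(tree)
  ovqa_assert(pos == length(values), "flattened length mismatch")
  out
}

# Numerically stable row-wise softmax; rows with no finite entry become zero.
row_softmax <- function(m) {
  mx <- apply(m, 1L, max)
  dead <- !is.finite(mx)
  mx[dead] <- 0
  e <- exp(m - mx)
  e[!is.finite(e)] <- 0
  s <- rowSums(e)
  out <- e / ifelse(s > 0, s, 1)
  out[dead, ] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
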