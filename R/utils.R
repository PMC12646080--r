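## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(
    class = c("pleionet_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_config(...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == round(x)
}

## Symmetric positive-definite check via Cholesky.
is_spd <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > 1e-8) return(FALSE)
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  ok
}

## Derive a stream-specific 32-bit seed from a master seed so that stages
## consuming randomness independently stay reproducible.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

## Area under the ROC curve via the rank (Mann-Whitney) statistic.
auc_rank <- function(score, label) {
  stopifnot(length(score) == length(label))
  pos <- label > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Adjusted Rand index between two labelings (used for module recovery).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
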