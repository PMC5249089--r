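`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical unordered gene-pair index
#'
#' Pairs are enumerated in column-major upper-triangle order:
#' (1,2), (1,3), (2,3), (1,4), ... with i < j.  All per-pair parameter
#' vectors in a `control_model` follow this order.
#'
#' @param n_genes number of genes in the panel.
#' @return list with integer vectors `i` and `j` (i < j) of length
#'   `n_genes * (n_genes - 1) / 2`.
#' @export
pair_indices <- function(n_genes) {
  stopifnot(n_genes >= 2)
  idx <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
  list(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
}

## run code under a temporary RNG state so library functions stay
## referentially transparent for the caller
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## deterministic sub-seed derivation; stays far below .Machine$integer.max
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.integer(seed) %% 1000003L
  for (o in offs) s <- (s * 31L + as.integer(o) %% 997L) %% 1000003L
  s + 7L
}

fmt_num <- function(x) sprintf("%.12g", x)

stop_pn <- function(...) stop(..., call. = FALSE)
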