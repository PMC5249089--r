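## Control models: per-gene-pair reference parameters fitted on the control
## group.  Pairs follow the canonical order of pair_indices(); the regression
## kernel always uses the lower-indexed gene of a pair as predictor, recorded
## in the model so weights are reproducible.

MODEL_FORMAT <- "parenclitic_control_model"
MODEL_VERSION <- 1L

control_values <- function(x) {
  if (inherits(x, "methylation_matrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop_pn("controls must be a methylation_matrix or a numeric matrix")
}

new_control_model <- function(kernel, gene_ids, control_ids, pairs, params,
                              degenerate, extra = list()) {
  params <- lapply(params, unname)
  degenerate <- unname(degenerate)
  m <- structure(c(list(kernel = kernel, gene_ids = gene_ids,
                        control_ids = control_ids,
                        pair_i = pairs$i, pair_j = pairs$j,
                        params = params, degenerate = degenerate,
                        orientation = "predictor = lower-indexed gene",
                        version = MODEL_VERSION), extra),
                 class = "control_model")
  m
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf("<control_model> kernel=%s, %d genes, %d pairs (%d degenerate), %d control samples\n",
              x$kernel, length(x$gene_ids), length(x$pair_i),
              sum(x$degenerate), length(x$control_ids)))
  invisible(x)
}

#' Fit per-pair linear-regression control models
#'
#' For every unordered gene pair (i < j), fits an ordinary-least-squares
#' regression of gene j's methylation level on gene i's over the control
#' samples, m_j = alpha + beta * m_i, and records the residual standard
#' deviation sigma (divisor n - 1).  A pair whose predictor gene is constant
#' across controls, or whose residual variance is numerically zero relative
#' to the response variance, is flagged degenerate; degenerate pairs are
#' dropped from networks by default (see [build_network()]).
#'
#' @param controls a [methylation_matrix()] (all of its samples are used as
#'   the control group) or a plain genes-by-samples numeric matrix.
#' @return a `control_model` with kernel `"regression"`, holding vectors
#'   `alpha`, `beta`, `sigma` over the canonical pair order of
#'   [pair_indices()].
#' @export
fit_regression <- function(controls) {
  X <- control_values(controls)
  n <- ncol(X)
  if (n < 3) stop_pn("need at least 3 control samples")
  G <- nrow(X)
  C <- cov(t(X))
  m <- rowMeans(X)
  p <- pair_indices(G)
  vx <- diag(C)[p$i]
  vy <- diag(C)[p$j]
  cxy <- C[cbind(p$i, p$j)]

  const_pred <- vx <= 0
  beta <- ifelse(const_pred, NA_real_, cxy / vx)
  alpha <- ifelse(const_pred, NA_real_, m[p$j] - beta * m[p$i])
  s2 <- vy - beta * cxy          # residual SS / (n - 1)
  ## numerically-zero residual variance (exact linear relation) snaps to 0
  zero_resid <- !const_pred & (s2 <= 1e-12 * pmax(vy, .Machine$double.eps))
  s2[zero_resid] <- 0
  s2[!const_pred & s2 < 0] <- 0
  sigma <- sqrt(s2)
  degenerate <- const_pred | zero_resid
  if (any(degenerate))
    warning(sum(degenerate), " degenerate pair(s) (constant predictor or ",
            "zero residual variance); they will be dropped from networks",
            call. = FALSE)
  new_control_model("regression", rownames(X), colnames(X), p,
                    list(alpha = alpha, beta = beta, sigma = sigma),
                    degenerate)
}

#' Fit per-pair Mahalanobis control models
#'
#' For every unordered gene pair, stores the control-group mean 2-vector and
#' the 2x2 sample covariance matrix (divisor n - 1).  Pairs whose covariance
#' is numerically singular get `ridge` added to the diagonal, which keeps the
#' squared-Mahalanobis edge weight well defined; with `ridge = 0` such pairs
#' are flagged degenerate instead and dropped at network-building time.
#'
#' @inheritParams fit_regression
#' @param ridge nonnegative diagonal loading applied to singular pair
#'   covariances; default `1e-8`.
#' @return a `control_model` with kernel `"mahalanobis"`, holding `mu` (per
#'   gene) and per-pair covariance entries `s11`, `s12`, `s22`.
#' @export
fit_mahalanobis <- function(controls, ridge = 1e-8) {
  X <- control_values(controls)
  n <- ncol(X)
  if (n < 3) stop_pn("need at least 3 control samples")
  if (ridge < 0) stop_pn("`ridge` must be nonnegative")
  G <- nrow(X)
  C <- cov(t(X))
  mu <- rowMeans(X)
  p <- pair_indices(G)
  s11 <- diag(C)[p$i]
  s22 <- diag(C)[p$j]
  s12 <- C[cbind(p$i, p$j)]
  det0 <- s11 * s22 - s12^2
  singular <- det0 <= 1e-12 * pmax(s11 * s22, .Machine$double.eps)
  ridged <- singular & ridge > 0
  s11[ridged] <- s11[ridged] + ridge
  s22[ridged] <- s22[ridged] + ridge
  degenerate <- singular & ridge == 0
  if (any(degenerate))
    warning(sum(degenerate), " pair(s) with singular covariance and ridge=0; ",
            "they will be dropped from networks", call. = FALSE)
  new_control_model("mahalanobis", rownames(X), colnames(X), p,
                    list(mu = mu, s11 = s11, s12 = s12, s22 = s22),
                    degenerate, extra = list(ridge = ridge, ridged = ridged))
}

#' Per-pair parameters of a control model
#'
#' @param model a `control_model`.
#' @param gene_i,gene_j gene ids (order irrelevant; the canonical record for
#'   the unordered pair is returned).
#' @return for the regression kernel a list `alpha`, `beta`, `sigma`,
#'   `predictor`, `response`; for the Mahalanobis kernel a list `mu`
#'   (2-vector) and `S` (2x2 matrix).
#' @export
pair_params <- function(model, gene_i, gene_j) {
  gi <- match(gene_i, model$gene_ids)
  gj <- match(gene_j, model$gene_ids)
  if (is.na(gi) || is.na(gj) || gi == gj)
    stop_pn("gene pair not in model panel: ", gene_i, ", ", gene_j)
  i <- min(gi, gj); j <- max(gi, gj)
  k <- which(model$pair_i == i & model$pair_j == j)
  if (model$kernel == "regression") {
    list(alpha = model$params$alpha[k], beta = model$params$beta[k],
         sigma = model$params$sigma[k],
         predictor = model$gene_ids[i], response = model$gene_ids[j],
         degenerate = model$degenerate[k])
  } else {
    list(mu = c(model$params$mu[i], model$params$mu[j]),
         S = matrix(c(model$params$s11[k], model$params$s12[k],
                      model$params$s12[k], model$params$s22[k]), 2, 2),
         degenerate = model$degenerate[k])
  }
}

num_to_chr <- function(x) sprintf("%.17g", x)
chr_to_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[x == "nan" | x == "NA"] <- NA_real_
  out
}

#' Save / load a control model
#'
#' The model file is JSON with a small header (format tag, version, kernel,
#' gene panel, control ids) and per-pair parameter vectors stored as decimal
#' strings with 17 significant digits, so the round trip is lossless:
#' `load_model(save_model(m, p))` equals `m` field by field.
#'
#' @param model a `control_model`.
#' @param path file path.
#' @return `load_model` returns the restored `control_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "control_model"))
  doc <- list(format = MODEL_FORMAT, version = model$version,
              kernel = model$kernel,
              gene_ids = model$gene_ids, control_ids = model$control_ids,
              orientation = model$orientation,
              pair_i = model$pair_i, pair_j = model$pair_j,
              degenerate = model$degenerate,
              params = lapply(model$params, num_to_chr))
  if (model$kernel == "mahalanobis") {
    doc$ridge <- num_to_chr(model$ridge)
    doc$ridged <- model$ridged
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_pn("corrupted or unreadable model file: ", path,
                            " (", conditionMessage(e), ")"))
  if (!identical(doc$format, MODEL_FORMAT))
    stop_pn("not a parenclitic control-model file: ", path)
  if (!identical(as.integer(doc$version), MODEL_VERSION))
    stop_pn("model file version mismatch: found ", doc$version,
            ", supported ", MODEL_VERSION)
  params <- lapply(doc$params, chr_to_num)
  extra <- if (identical(doc$kernel, "mahalanobis"))
    list(ridge = chr_to_num(doc$ridge), ridged = as.logical(doc$ridged))
  else list()
  new_control_model(doc$kernel, doc$gene_ids, doc$control_ids,
                    list(i = as.integer(doc$pair_i), j = as.integer(doc$pair_j)),
                    params, as.logical(doc$degenerate), extra = extra)
}

#' Export a control model as a flat pair table
#'
#' One row per gene pair with the kernel's parameters in plain columns;
#' intended for inspection, not for lossless round trips (use
#' [save_model()] for that).
#'
#' @inheritParams save_model
#' @export
export_model_tsv <- function(model, path) {
  base <- data.frame(gene_i = model$gene_ids[model$pair_i],
                     gene_j = model$gene_ids[model$pair_j],
                     degenerate = model$degenerate)
  pars <- if (model$kernel == "regression")
    data.frame(alpha = model$params$alpha, beta = model$params$beta,
               sigma = model$params$sigma)
  else
    data.frame(mu_i = model$params$mu[model$pair_i],
               mu_j = model$params$mu[model$pair_j],
               s11 = model$params$s11, s12 = model$params$s12,
               s22 = model$params$s22)
  write.table(cbind(base, pars), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
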