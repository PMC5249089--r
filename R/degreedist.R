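#' Complementary cumulative degree distribution
#'
#' For each distinct degree value x, the fraction of nodes whose degree
#' strictly exceeds x: `P(deg > x) = #{v : deg(v) > x} / |V|`.
#'
#' @param degrees nonnegative numeric vector (e.g. [weighted_degrees()]), or
#'   a `parenclitic_network`.
#' @param group optional group label carried in the result.
#' @return an object of class `degree_distribution`: list with `degree`
#'   (sorted distinct values), `ccdf` (non-increasing, in \[0, 1\]), `group`,
#'   and the raw `degrees`.
#' @export
degree_ccdf <- function(degrees, group = NULL) {
  if (inherits(degrees, "parenclitic_network"))
    degrees <- weighted_degrees(degrees)
  degrees <- as.numeric(degrees)
  if (any(degrees < 0)) stop_pn("degrees must be nonnegative")
  x <- sort(unique(degrees))
  p <- vapply(x, function(v) mean(degrees > v), numeric(1))
  structure(list(degree = x, ccdf = p, group = group, degrees = degrees),
            class = "degree_distribution")
}

#' Assemble a degree distribution from explicit values
#'
#' Mainly useful for fitting analytically known CCDFs; [degree_ccdf()] is
#' the empirical constructor.
#'
#' @param degree sorted distinct degree values.
#' @param ccdf matching non-increasing tail probabilities in \[0, 1\].
#' @param group optional label.
#' @param degrees optional raw degree sample (enables MLE fitting).
#' @return a `degree_distribution`.
#' @export
degree_distribution <- function(degree, ccdf, group = NULL, degrees = NULL) {
  stopifnot(length(degree) == length(ccdf))
  if (is.unsorted(degree)) stop_pn("`degree` must be sorted increasingly")
  if (any(diff(ccdf) > 1e-12)) stop_pn("`ccdf` must be non-increasing")
  if (any(ccdf < 0 | ccdf > 1)) stop_pn("`ccdf` must lie in [0,1]")
  structure(list(degree = degree, ccdf = ccdf, group = group,
                 degrees = degrees),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("<degree_distribution>%s %d support points, degree range [%.4g, %.4g]\n",
              if (is.null(x$group)) "" else paste0(" group=", x$group),
              length(x$degree), min(x$degree), max(x$degree)))
  invisible(x)
}

eval_ccdf <- function(degrees, at) {
  vapply(at, function(v) mean(degrees > v), numeric(1))
}

#' Group-average degree distribution
#'
#' Evaluates each network's empirical CCDF on a shared log-spaced degree
#' grid and averages pointwise (`mode = "average"`, the default), or pools
#' all degrees into one empirical CCDF (`mode = "pooled"`).
#'
#' @param nets a list of `parenclitic_network` objects or of degree vectors.
#' @param group group label for the result.
#' @param n_grid grid size for the averaged mode; default 50.
#' @param mode `"average"` or `"pooled"`.
#' @return a `degree_distribution`; in averaged mode `degree` is the shared
#'   grid and `degrees` is `NULL`.
#' @export
average_ccdf <- function(nets, group = NULL, n_grid = 50,
                         mode = c("average", "pooled")) {
  mode <- match.arg(mode)
  if (length(nets) == 0) stop_pn("empty network group")
  degs <- lapply(nets, function(x)
    if (inherits(x, "parenclitic_network")) weighted_degrees(x) else as.numeric(x))
  if (mode == "pooled") return(degree_ccdf(unlist(degs), group = group))
  all_deg <- unlist(degs)
  pos <- all_deg[all_deg > 0]
  if (!length(pos)) stop_pn("all degrees are zero; no distribution to average")
  lo <- min(pos); hi <- max(all_deg)
  grid <- if (hi > lo) exp(seq(log(lo), log(hi), length.out = n_grid)) else lo
  ## evaluate strictly below each grid point's value so the smallest grid
  ## point keeps ccdf < 1 information; strict ">" as in degree_ccdf
  avg <- rowMeans(vapply(degs, eval_ccdf, numeric(length(grid)), at = grid))
  structure(list(degree = grid, ccdf = avg, group = group, degrees = NULL),
            class = "degree_distribution")
}

#' Power-law fit to a degree distribution tail
#'
#' The default (`method = "ols"`) fits a least-squares line to
#' (log degree, log ccdf) over points at or above `x_min` with positive
#' ccdf; the reported `exponent` is minus the slope, i.e. the tail exponent
#' a in `P(deg > x) ~ x^(-a)` (the corresponding density exponent is
#' `alpha = a + 1`).  `method = "mle"` applies the continuous maximum-
#' likelihood estimator `alpha = 1 + n / sum(log(x / x_min))` to the raw
#' degree sample (available when the distribution retains raw degrees).
#' Goodness is reported as the R-squared of the log-log line and the
#' Kolmogorov-Smirnov distance between the empirical and fitted CCDF over
#' the fit range.
#'
#' @param dist a `degree_distribution`.
#' @param x_min lower end of the fit range; default: smallest positive
#'   degree with positive ccdf.
#' @param method `"ols"` (log-log least squares on the CCDF) or `"mle"`.
#' @return an object of class `power_law_fit`: list with `exponent`,
#'   `alpha`, `x_min`, `r_squared`, `ks`, `n_points`, `method`.
#' @export
fit_power_law <- function(dist, x_min = NULL, method = c("ols", "mle")) {
  stopifnot(inherits(dist, "degree_distribution"))
  method <- match.arg(method)
  keep <- dist$degree > 0 & dist$ccdf > 0
  if (!is.null(x_min)) keep <- keep & dist$degree >= x_min
  x <- dist$degree[keep]; p <- dist$ccdf[keep]
  if (length(x) < 5)
    stop_pn("need at least 5 points with positive degree and ccdf above x_min")
  if (is.null(x_min)) x_min <- min(x)
  lx <- log(x); lp <- log(p)

  if (method == "ols") {
    slope <- cov(lx, lp) / var(lx)
    intercept <- mean(lp) - slope * mean(lx)
    exponent <- -slope
    alpha <- exponent + 1
  } else {
    d <- dist$degrees
    if (is.null(d))
      stop_pn("mle fitting needs the raw degree sample (not available for averaged ccdfs)")
    tail <- d[d >= x_min]
    if (length(tail) < 5) stop_pn("too few observations above x_min for mle")
    alpha <- 1 + length(tail) / sum(log(tail / x_min))
    exponent <- alpha - 1
    slope <- -exponent
    intercept <- mean(lp) - slope * mean(lx)
  }
  fitted <- exp(intercept + slope * lx)
  ss_res <- sum((lp - (intercept + slope * lx))^2)
  ss_tot <- sum((lp - mean(lp))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  ks <- max(abs(p - fitted))
  structure(list(exponent = exponent, alpha = alpha, x_min = x_min,
                 r_squared = r2, ks = ks, n_points = length(x),
                 method = method),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> P(deg > x) ~ x^-%.3f (alpha = %.3f), x_min = %.4g, R2 = %.4f, KS = %.4f [%s, %d points]\n",
              x$exponent, x$alpha, x$x_min, x$r_squared, x$ks, x$method,
              x$n_points))
  invisible(x)
}

#' Write a degree distribution as a two-column table
#'
#' @param dist a `degree_distribution`.
#' @param path output TSV (`degree`, `ccdf`).
#' @export
write_ccdf <- function(dist, path) {
  write.table(data.frame(degree = fmt_num(dist$degree),
                         ccdf = fmt_num(dist$ccdf)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
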