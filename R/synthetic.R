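#' Specification of a synthetic methylation cohort
#'
#' The generator emulates the bivariate gene-pair structure the parenclitic
#' method assumes.  Linked gene pairs are drawn from a correlated bivariate
#' normal on the logit scale and squashed into (0, 1) with the logistic
#' function (a logit-normal keeps beta-like values bounded while preserving
#' correlation structure near the boundaries).  Control and healthy-test
#' samples share one distribution; disease samples are perturbed on the
#' linked pairs according to one of two geometries:
#' \describe{
#'   \item{`off_line`}{the response gene is displaced off the pair's
#'     regression line by `delta_perp` control residual standard deviations
#'     (random sign per sample), so regression residuals separate the
#'     classes;}
#'   \item{`along_line`}{the disease cluster is displaced along the
#'     regression direction by `delta_par` marginal standard deviations, so
#'     residuals do not separate the classes but the Mahalanobis distance
#'     does;}
#' }
#' `mixed` alternates the two geometries over the linked pairs.
#'
#' @param n_genes gene-panel size.
#' @param n_control,n_healthy,n_disease sample counts for the three label
#'   groups (`control`, `healthy_test`, `disease`).
#' @param pair_correlation latent correlation rho of linked pairs, in
#'   (-1, 1).
#' @param fraction_linked_pairs fraction of the `floor(n_genes / 2)`
#'   disjoint gene pairs that are linked (and perturbed in disease).
#' @param geometry `"off_line"`, `"along_line"` or `"mixed"`.
#' @param delta_perp off-line displacement in control residual-sigma units.
#' @param delta_par along-line displacement in marginal-sigma units.
#' @param noise_sd standard deviation of the latent logit-scale levels.
#' @param seed integer seed; identical specs generate byte-identical cohorts.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 50, n_control = 60, n_healthy = 60,
                           n_disease = 120, pair_correlation = 0.7,
                           fraction_linked_pairs = 0.5,
                           geometry = c("off_line", "along_line", "mixed"),
                           delta_perp = 5, delta_par = 4,
                           noise_sd = 0.5, seed = 1L) {
  geometry <- match.arg(geometry)
  if (!(pair_correlation > -1 && pair_correlation < 1))
    stop_pn("`pair_correlation` must lie strictly inside (-1, 1)")
  if (any(c(n_genes, n_control, n_healthy, n_disease) < 0))
    stop_pn("counts must be nonnegative")
  if (n_genes < 2) stop_pn("need at least 2 genes")
  if (delta_perp < 0 || delta_par < 0 || noise_sd <= 0)
    stop_pn("magnitudes must be nonnegative and noise_sd positive")
  if (!(fraction_linked_pairs >= 0 && fraction_linked_pairs <= 1))
    stop_pn("`fraction_linked_pairs` must lie in [0, 1]")
  structure(list(n_genes = n_genes, n_control = n_control,
                 n_healthy = n_healthy, n_disease = n_disease,
                 pair_correlation = pair_correlation,
                 fraction_linked_pairs = fraction_linked_pairs,
                 geometry = geometry, delta_perp = delta_perp,
                 delta_par = delta_par, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic methylation cohort
#'
#' Draws a seeded cohort per the [synthetic_spec()] and returns a labelled
#' [methylation_matrix()]; the `ground_truth` attribute records which gene
#' pairs were linked and how disease samples were perturbed (pair table with
#' geometry and displacement, latent means, rho, noise and residual sigmas),
#' so downstream tests can target parameter recovery directly.
#'
#' @param spec a `synthetic_spec`.
#' @return a `methylation_matrix` with labels `control` / `healthy_test` /
#'   `disease` and attribute `ground_truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  N <- spec$n_control + spec$n_healthy + spec$n_disease
  genes <- sprintf("g%04d", seq_len(G))
  samples <- c(sprintf("C%04d", seq_len(spec$n_control)),
               sprintf("H%04d", seq_len(spec$n_healthy)),
               sprintf("D%04d", seq_len(spec$n_disease)))
  labels <- c(rep("control", spec$n_control),
              rep("healthy_test", spec$n_healthy),
              rep("disease", spec$n_disease))
  is_disease <- labels == "disease"
  rho <- spec$pair_correlation
  s <- spec$noise_sd
  mu <- runif(G, -1.5, 1.5)

  n_linked <- round(spec$fraction_linked_pairs * floor(G / 2))
  shuffled <- sample(G)
  pred <- shuffled[seq_len(n_linked) * 2 - 1]
  resp <- shuffled[seq_len(n_linked) * 2]
  linked <- sort(c(pred, resp))
  geo <- if (n_linked == 0) character() else switch(
    spec$geometry,
    off_line = rep("off_line", n_linked),
    along_line = rep("along_line", n_linked),
    mixed = rep(c("off_line", "along_line"), length.out = n_linked))

  Z <- matrix(NA_real_, G, N, dimnames = list(genes, samples))
  free <- setdiff(seq_len(G), linked)
  if (length(free))
    Z[free, ] <- mu[free] + s * matrix(rnorm(length(free) * N), length(free), N)

  sigma_resid <- s * sqrt(1 - rho^2)
  for (k in seq_len(n_linked)) {
    e1 <- rnorm(N); e2 <- rnorm(N)
    zp <- mu[pred[k]] + s * e1
    zr <- mu[resp[k]] + s * (rho * e1 + sqrt(1 - rho^2) * e2)
    if (any(is_disease)) {
      if (geo[k] == "off_line" && spec$delta_perp > 0) {
        sign <- sample(c(-1, 1), sum(is_disease), replace = TRUE)
        zr[is_disease] <- zr[is_disease] + sign * spec$delta_perp * sigma_resid
      } else if (geo[k] == "along_line" && spec$delta_par > 0) {
        zp[is_disease] <- zp[is_disease] + spec$delta_par * s
        zr[is_disease] <- zr[is_disease] + spec$delta_par * s * rho
      }
    }
    Z[pred[k], ] <- zp
    Z[resp[k], ] <- zr
  }

  m <- methylation_matrix(plogis(Z), labels = setNames(labels, samples))
  truth <- list(
    linked_pairs = data.frame(
      predictor = genes[pred], response = genes[resp],
      geometry = geo,
      delta = if (n_linked) ifelse(geo == "off_line", spec$delta_perp,
                                   spec$delta_par) else numeric(),
      stringsAsFactors = FALSE),
    latent_means = setNames(mu, genes),
    pair_correlation = rho, noise_sd = s, sigma_resid = sigma_resid,
    spec = unclass(spec))
  attr(m, "ground_truth") <- truth
  m
}

#' Generate probe-level data for a synthetic cohort
#'
#' Expands each gene of a [generate_cohort()] matrix into `probes_per_gene`
#' probes (gene value plus independent Gaussian probe noise, clipped to
#' \[0, 1\]), then overlays seeded missingness and detection-failure masks,
#' exercising the full preprocessing stage.
#'
#' @param spec a `synthetic_spec`.
#' @param probes_per_gene probes per gene (>= 1); default 3.
#' @param missing_rate fraction of probe entries set to `NA`.
#' @param detp_fail_rate fraction of probe entries whose detection p-value
#'   exceeds 0.05 (values drawn in (0.06, 1); passing entries in (0, 0.04)).
#' @param probe_noise probe-level noise standard deviation; default 0.01.
#' @return list with `probe_matrix`, `map` (probe-to-gene data.frame) and
#'   `gene_truth` (the underlying gene-level `methylation_matrix`).
#' @export
generate_probe_level <- function(spec, probes_per_gene = 3,
                                 missing_rate = 0, detp_fail_rate = 0,
                                 probe_noise = 0.01) {
  if (probes_per_gene < 1) stop_pn("`probes_per_gene` must be >= 1")
  if (missing_rate < 0 || missing_rate > 1 ||
      detp_fail_rate < 0 || detp_fail_rate > 1)
    stop_pn("rates must lie in [0, 1]")
  gm <- generate_cohort(spec)   # reseeds; subsequent draws continue the stream
  gv <- gm$values
  G <- nrow(gv); N <- ncol(gv); P <- G * probes_per_gene
  probe_ids <- paste0(rep(rownames(gv), each = probes_per_gene), "_p",
                      rep(seq_len(probes_per_gene), G))
  v <- gv[rep(seq_len(G), each = probes_per_gene), , drop = FALSE] +
    matrix(rnorm(P * N, sd = probe_noise), P, N)
  v <- pmin(pmax(v, 0), 1)
  rownames(v) <- probe_ids

  detp <- matrix(runif(P * N, 0, 0.04), P, N, dimnames = dimnames(v))
  if (detp_fail_rate > 0) {
    fail <- matrix(runif(P * N) < detp_fail_rate, P, N)
    detp[fail] <- runif(sum(fail), 0.06, 1)
  }
  if (missing_rate > 0) {
    miss <- matrix(runif(P * N) < missing_rate, P, N)
    v[miss] <- NA_real_
  }
  list(probe_matrix = probe_matrix(v, detp),
       map = data.frame(probe_id = probe_ids,
                        gene_id = rep(rownames(gv), each = probes_per_gene),
                        stringsAsFactors = FALSE),
       gene_truth = gm)
}
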