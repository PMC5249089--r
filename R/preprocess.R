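#' Probe-level methylation matrix
#'
#' Raw array data before gene-level aggregation: a probes-by-samples value
#' matrix (expected in \[0, 1\], missing entries allowed) with an optional
#' parallel matrix of detection p-values of identical shape and index order.
#'
#' @param values numeric matrix with probe rownames and sample colnames;
#'   `NA` marks missing observations.
#' @param detection_p optional numeric matrix of detection p-values in
#'   \[0, 1\], same dimnames as `values`.
#' @return an object of class `probe_matrix`.
#' @export
probe_matrix <- function(values, detection_p = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_pn("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_pn("`values` must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_pn("duplicate probe ids")
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(values)) ||
        !identical(dimnames(detection_p), dimnames(values)))
      stop_pn("`detection_p` must match `values` in shape and index order")
    if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE))
      stop_pn("detection p-values must lie in [0,1]")
  }
  structure(list(values = values, detection_p = detection_p),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat(sprintf("<probe_matrix> %d probes x %d samples (%d missing entries%s)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              if (is.null(x$detection_p)) ", no detection p" else ""))
  invisible(x)
}

#' Read a probe matrix and probe-to-gene map from delimited files
#'
#' @param values_path probe value table (probes as rows, header of sample ids).
#' @param detp_path optional detection p-value table of identical shape.
#' @return [probe_matrix()] for `read_probe_matrix`; a data.frame with
#'   columns `probe_id`, `gene_id` for `read_probe_gene_map`.
#' @export
read_probe_matrix <- function(values_path, detp_path = NULL) {
  v <- df_to_numeric_matrix(read_table_checked(values_path, "probe matrix"),
                            "probe matrix")
  p <- if (!is.null(detp_path))
    df_to_numeric_matrix(read_table_checked(detp_path, "detection p"),
                         "detection p")
  if (!is.null(p)) p <- p[rownames(v), colnames(v), drop = FALSE]
  probe_matrix(v, p)
}

#' @param path two-column delimited file (probe_id, gene_id).
#' @rdname read_probe_matrix
#' @export
read_probe_gene_map <- function(path) {
  df <- read_table_checked(path, "probe-gene map")
  map <- data.frame(probe_id = as.character(df[[1L]]),
                    gene_id = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  map <- unique(map)
  if (any(!nzchar(map$gene_id))) stop_pn("empty gene_id in probe-gene map")
  if (anyDuplicated(map$probe_id))
    stop_pn("probe mapped to more than one gene: ",
            paste(head(unique(map$probe_id[duplicated(map$probe_id)]), 5),
                  collapse = ", "))
  map
}

#' Filter probes by blacklist, annotation and coverage
#'
#' Keeps probes that (a) are not blacklisted, (b) have a gene annotation in
#' `map`, and (c) are observed (non-missing) in at least `coverage_min` of
#' samples.  Sample order is preserved.  The blacklist is caller-supplied
#' (e.g. SNP-overlapping, multi-mapping or sex-chromosome probes); the
#' package embeds no platform annotation.
#'
#' @param pm a [probe_matrix()].
#' @param map probe-to-gene map data.frame (`probe_id`, `gene_id`).
#' @param coverage_min minimum fraction of samples with observed values,
#'   in (0, 1]; default 0.95.
#' @param blacklist character vector of probe ids to drop.
#' @return the filtered [probe_matrix()].
#' @export
filter_probes <- function(pm, map, coverage_min = 0.95,
                          blacklist = character()) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (!(coverage_min > 0 && coverage_min <= 1))
    stop_pn("`coverage_min` must lie in (0, 1]")
  probes <- rownames(pm$values)
  keep_bl <- !(probes %in% blacklist)
  keep_map <- probes %in% map$probe_id
  coverage <- rowMeans(!is.na(pm$values))
  keep_cov <- coverage >= coverage_min
  keep <- keep_bl & keep_map & keep_cov
  if (!any(keep)) {
    constraint <-
      if (!any(keep_bl)) "every probe is blacklisted"
      else if (!any(keep_bl & keep_map)) "no non-blacklisted probe has a gene annotation"
      else sprintf("no annotated probe reaches %.0f%% coverage", 100 * coverage_min)
    stop_pn("no probe survives filtering: ", constraint)
  }
  probe_matrix(pm$values[keep, , drop = FALSE],
               if (!is.null(pm$detection_p))
                 pm$detection_p[keep, , drop = FALSE])
}

#' Impute detection failures (and residual missing values) by k-NN
#'
#' Entries whose detection p-value exceeds `p_max`, plus any remaining `NA`
#' entries, are replaced by the unweighted mean of the values of the `k`
#' nearest probe rows at the same sample.  Distance between two probe rows is
#' the root-mean-square difference over samples observed in both rows
#' (detection-flagged values still participate in distances; only missing
#' values are excluded).  Neighbours must have an observed value at the
#' target sample.  All other entries are returned unchanged, and imputed
#' entries are no longer flagged in the output.
#'
#' @param pm a [probe_matrix()] with `detection_p` present (unless only `NA`
#'   imputation is needed).
#' @param p_max detection p-value threshold; default 0.05.
#' @param k number of nearest neighbour probes; default 5.
#' @return a dense [probe_matrix()] with no flagged or missing entries.
#' @export
impute_detection_failures <- function(pm, p_max = 0.05, k = 5) {
  stopifnot(inherits(pm, "probe_matrix"))
  v <- pm$values
  n_probes <- nrow(v)
  if (!(k >= 1 && k <= n_probes - 1))
    stop_pn("`k` must satisfy 1 <= k <= n_probes - 1")
  flagged <- if (!is.null(pm$detection_p)) {
    f <- pm$detection_p > p_max
    f[is.na(f)] <- FALSE
    f
  } else matrix(FALSE, n_probes, ncol(v), dimnames = dimnames(v))
  target <- flagged | is.na(v)
  if (!any(target)) return(pm)

  obs <- !is.na(v)
  out <- v
  rows_needed <- which(rowSums(target) > 0)
  for (i in rows_needed) {
    ## RMS distance to every other probe row over mutually observed samples
    shared <- obs & rep(obs[i, ], each = n_probes)
    nsh <- rowSums(shared)
    diff2 <- (sweep(v, 2, v[i, ]))^2
    diff2[!shared] <- 0
    d <- sqrt(rowSums(diff2) / pmax(nsh, 1L))
    d[nsh == 0] <- Inf
    d[i] <- Inf
    for (s in which(target[i, ])) {
      cand <- which(is.finite(d) & obs[, s])
      if (length(cand) < k)
        stop_pn("probe ", rownames(v)[i],
                " has too few valid co-observations to find ", k, " neighbours")
      nb <- cand[order(d[cand], cand)][seq_len(k)]
      out[i, s] <- mean(v[nb, s])
    }
  }
  detp <- pm$detection_p
  if (!is.null(detp)) detp[target] <- 0
  res <- probe_matrix(out, detp)
  attr(res, "imputed") <- which(target, arr.ind = TRUE)
  res
}

#' Aggregate probes to gene-level methylation
#'
#' Each gene is characterised by the arithmetic mean of its probes' values
#' per sample, and the resulting matrix is rescaled into \[0, 1\].  Gene order
#' is lexicographic.  Rescaling modes: `"auto"` (values already in range pass
#' through; otherwise a global min-max rescale), `"global"`, `"per_gene"`,
#' `"none"`.  The global default preserves relative differences between
#' genes.  The applied mode is recorded in the `rescale` attribute.
#'
#' @param pm a filtered, dense [probe_matrix()].
#' @param map probe-to-gene map covering every probe in `pm`.
#' @param rescale rescaling mode, see above.
#' @return a [methylation_matrix()] (labels unset).
#' @export
aggregate_to_genes <- function(pm, map,
                               rescale = c("auto", "global", "per_gene", "none")) {
  stopifnot(inherits(pm, "probe_matrix"))
  rescale <- match.arg(rescale)
  v <- pm$values
  if (anyNA(v))
    stop_pn("probe matrix still has missing values; impute before aggregating")
  miss <- setdiff(rownames(v), map$probe_id)
  if (length(miss))
    stop_pn("probes without gene annotation: ", paste(head(miss, 5), collapse = ", "))
  gene_of <- setNames(map$gene_id, map$probe_id)[rownames(v)]
  sums <- rowsum(v, group = gene_of)        # rows sorted lexicographically
  counts <- as.vector(table(gene_of))       # same lexicographic order
  g <- sums / counts

  applied <- "none"
  rng <- range(g)
  if (rescale == "global" ||
      (rescale == "auto" && (rng[1] < 0 || rng[2] > 1))) {
    span <- rng[2] - rng[1]
    g <- if (span > 0) (g - rng[1]) / span else g * 0
    applied <- "global"
  } else if (rescale == "per_gene") {
    g <- t(apply(g, 1, function(r) {
      sp <- max(r) - min(r)
      if (sp > 0) (r - min(r)) / sp else r * 0
    }))
    applied <- "per_gene"
  }
  res <- methylation_matrix(g)
  attr(res, "rescale") <- list(requested = rescale, applied = applied)
  res
}
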