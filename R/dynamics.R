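## align a lognorm matrix to the cells covered by a SeverityAxis
axis_lognorm <- function(mat, axis) {
  if (is.null(mat$lognorm)) stop("lognorm layer missing; run normalize_expression()")
  cells <- intersect(mat$cell_ids, names(axis$pseudo_severity))
  if (!length(cells)) stop("no overlap between matrix cells and axis cells")
  list(Y = mat$lognorm[, cells, drop = FALSE],
       t = unname(axis$pseudo_severity[cells]))
}

#' Test each gene for differential expression along the severity axis
#'
#' Per gene, a likelihood-ratio test (Gaussian errors on lognorm) of a
#' natural cubic spline in pseudo-severity (3 degrees of freedom) against an
#' intercept-only model, with BH q-values across genes. Constant genes get
#' p = 1 by convention.
#'
#' @param mat normalized ExpressionMatrix.
#' @param axis a `SeverityAxis` covering (a subset of) the matrix cells.
#' @param q_threshold significance cut (default 0.01).
#' @return data.frame: gene_id, p_value, q_value, significant.
#' @export
axis_differential_test <- function(mat, axis, q_threshold = 0.01) {
  al <- axis_lognorm(mat, axis)
  Y <- al$Y; t_ <- al$t
  n <- length(t_)
  if (n < 50L) stop("need >= 50 cells for the axis differential test")
  X <- cbind(1, splines::ns(t_, df = 3))
  Q <- qr.Q(qr(X))
  tot <- rowSums(Y^2)
  rss0 <- tot - rowSums(Y)^2 / n
  rss1 <- tot - rowSums((Y %*% Q)^2)
  rss1 <- pmax(rss1, 0)
  lrt <- n * log(pmax(rss0, .Machine$double.eps) /
                 pmax(rss1, .Machine$double.eps))
  p <- stats::pchisq(lrt, df = 3, lower.tail = FALSE)
  const <- rss0 <= 1e-12 * pmax(tot, 1)
  p[const] <- 1
  q <- bh_adjust(p)
  data.frame(gene_id = rownames(Y), p_value = p, q_value = q,
             significant = q < q_threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Smooth gene profiles along the axis and cluster them into modules
#'
#' Per gene, a LOESS fit of lognorm on pseudo-severity evaluated on a
#' 100-point grid; profiles are z-scored per gene and clustered by
#' hierarchical clustering (Ward linkage on 1 - Pearson correlation), cut at
#' `k`. Modules are renumbered so module 1 has the highest mean profile at
#' low severity (first tenth of the grid), a deterministic function of the
#' profiles.
#'
#' @param mat normalized ExpressionMatrix.
#' @param axis a `SeverityAxis`.
#' @param genes genes to smooth and cluster (e.g. axis-significant genes).
#' @param k number of modules (default 4).
#' @param loess_span LOESS span (default 0.5).
#' @param grid_n grid length (default 100).
#' @return list with `modules` (data.frame gene_id, module), `profiles`
#'   (genes x grid z-scored matrix) and `grid`.
#' @export
smooth_and_cluster <- function(mat, axis, genes, k = 4L, loess_span = 0.5,
                               grid_n = 100L) {
  genes <- intersect(genes, mat$gene_ids)
  if (length(genes) < k) stop("fewer significant genes than modules requested")
  al <- axis_lognorm(mat, axis)
  grid <- seq(0, 1, length.out = grid_n)
  prof <- t(vapply(genes, function(g) {
    fit <- stats::loess(al$Y[g, ] ~ al$t, span = loess_span,
                        degree = 2, family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    stats::predict(fit, grid)
  }, numeric(grid_n)))
  mu <- rowMeans(prof)
  s <- apply(prof, 1L, stats::sd)
  s[s == 0] <- 1
  z <- (prof - mu) / s
  d <- stats::as.dist(1 - suppressWarnings(stats::cor(t(z))))
  d[is.na(d)] <- 2
  hc <- stats::hclust(d, method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  early <- vapply(seq_len(k), function(m)
    mean(z[cl == m, seq_len(max(1L, grid_n %/% 10L)), drop = FALSE]),
    numeric(1L))
  relabel <- match(seq_len(k), order(-early))
  modules <- data.frame(gene_id = genes, module = relabel[cl],
                        row.names = NULL, stringsAsFactors = FALSE)
  list(modules = modules, profiles = z, grid = grid)
}

#' Ordinary least-squares trend of one gene along the axis
#'
#' @param y numeric expression values (lognorm).
#' @param t pseudo-severity values, same length.
#' @return list with `slope` (S) and `p_value` (P, two-sided t-test on the
#'   slope).
#' @export
linear_trend <- function(y, t) {
  n <- length(y)
  stopifnot(length(t) == n, n >= 3L)
  vx <- sum((t - mean(t))^2)
  if (vx == 0) stop("zero variance in the axis values")
  beta <- sum((t - mean(t)) * (y - mean(y))) / vx
  res <- y - mean(y) - beta * (t - mean(t))
  s2 <- sum(res^2) / (n - 2L)
  se <- sqrt(s2 / vx)
  tt <- if (se == 0) sign(beta) * Inf else beta / se
  list(slope = beta, p_value = 2 * stats::pt(-abs(tt), df = n - 2L))
}

#' Locate a gene's switch-like activation/repression period
#'
#' The axis \[0,1\] is divided into `n_bins` equal-width half-open bins (the
#' last bin closed); bins with fewer than `min_cells_per_bin` cells are
#' skipped. Within each retained bin an OLS regression of expression on
#' pseudo-severity gives a local slope and p-value; bins with p < alpha are
#' the significant bins. The reported period is the interquartile range of
#' the significant bin centers, snapped outward to bin boundaries, and the
#' direction is the sign of the mean slope over significant bins.
#'
#' @param y expression values (lognorm).
#' @param t pseudo-severity values in \[0,1\], same length.
#' @param n_bins number of bins (default 50).
#' @param alpha per-bin significance level (default 0.05).
#' @param min_cells_per_bin minimum cells for a bin's regression (default 10).
#' @return a `SwitchPeriod` list: significant_bins (0-based), interval
#'   (c(start, end) or c(NA, NA)), direction ("up"/"down"/NA), bin table.
#' @export
switch_timing <- function(y, t, n_bins = 50L, alpha = 0.05,
                          min_cells_per_bin = 10L) {
  stopifnot(length(y) == length(t), all(t >= 0 & t <= 1))
  bin <- pmin(floor(t * n_bins), n_bins - 1L)     # 0-based bins
  counts <- tabulate(bin + 1L, nbins = n_bins)
  usable <- which(counts >= min_cells_per_bin) - 1L
  if (!length(usable)) stop("axis too sparse: no bin reaches min_cells_per_bin")
  rows <- lapply(usable, function(b) {
    sel <- bin == b
    tb <- t[sel]
    if (stats::sd(tb) == 0) return(NULL)   # no within-bin contrast
    lt <- linear_trend(y[sel], tb)
    data.frame(bin = b, center = (b + 0.5) / n_bins, n = sum(sel),
               slope = lt$slope, p_value = lt$p_value)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) stop("axis too sparse: no bin admits a regression")
  sig <- tab[tab$p_value < alpha, , drop = FALSE]
  if (!nrow(sig)) {
    out <- list(significant_bins = integer(0), interval = c(NA_real_, NA_real_),
                direction = NA_character_, bins = tab)
  } else {
    qs <- stats::quantile(sig$center, c(0.25, 0.75), names = FALSE, type = 7)
    interval <- c(floor(qs[1L] * n_bins) / n_bins,
                  ceiling(qs[2L] * n_bins) / n_bins)
    out <- list(significant_bins = sort(sig$bin), interval = interval,
                direction = if (mean(sig$slope) >= 0) "up" else "down",
                bins = tab)
  }
  class(out) <- "SwitchPeriod"
  out
}

#' @export
print.SwitchPeriod <- function(x, ...) {
  if (length(x$significant_bins))
    cat(sprintf("SwitchPeriod: %s in [%.2f, %.2f] (%d significant bins)\n",
                x$direction, x$interval[1L], x$interval[2L],
                length(x$significant_bins)))
  else cat("SwitchPeriod: no significant bins\n")
  invisible(x)
}

#' Core gene set: consensus DEGs shared by S and L groups, perturbed along
#' the axis
#'
#' Thin composition: consensus DEGs (vs both controls) computed for the
#' pooled S samples and for the pooled L samples, intersected with matching
#' direction, then intersected with the axis-significant genes at
#' `fdr` (default 0.05).
#'
#' @param mat normalized ExpressionMatrix.
#' @param ann annotation.
#' @param axis a `SeverityAxis`.
#' @param control_samples two control sample ids.
#' @param fdr axis-test FDR level (default 0.05).
#' @param alpha,min_log2fc consensus-DEG thresholds (defaults 0.05 / 0.5).
#' @return character vector of core gene ids.
#' @export
core_gene_set <- function(mat, ann, axis, control_samples, fdr = 0.05,
                          alpha = 0.05, min_log2fc = 0.5) {
  ann <- validate_annotation(ann, cell_ids = mat$cell_ids)
  s_samples <- unique(ann$sample_id[ann$group == "S"])
  l_samples <- unique(ann$sample_id[ann$group == "L"])
  if (!length(s_samples) || !length(l_samples))
    stop("core_gene_set needs both S and L samples")
  deg_s <- consensus_deg(mat, ann, s_samples, control_samples,
                         alpha = alpha, min_log2fc = min_log2fc)
  deg_l <- consensus_deg(mat, ann, l_samples, control_samples,
                         alpha = alpha, min_log2fc = min_log2fc)
  shared <- merge(deg_s[, c("gene_id", "direction")],
                  deg_l[, c("gene_id", "direction")], by = "gene_id")
  shared <- shared$gene_id[shared$direction.x == shared$direction.y]
  ax <- axis_differential_test(mat, axis, q_threshold = fdr)
  core <- intersect(shared, ax$gene_id[ax$significant])
  log_info("core_gene_set: %d shared S/L DEGs, %d axis-significant -> %d core genes",
           length(shared), sum(ax$significant), length(core))
  sort(core)
}
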