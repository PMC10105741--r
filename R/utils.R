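`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed for a pipeline stage
#'
#' A single global seed governs all random draws; each stage works on its own
#' sub-stream so that stages can be rerun independently with identical
#' results. The derived seed always stays below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  off <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 99991L
  as.integer((abs(as.numeric(seed)) * 48271 + off) %% 2147483647)
}

#' Benjamini-Hochberg adjusted p-values
#' @param p numeric vector of p-values (NA allowed).
#' @return q-values, same length.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

## Two-sided Wilcoxon rank-sum test for every row of a matrix, normal
## approximation with tie correction and continuity correction (the same
## approximation stats::wilcox.test uses for exact = FALSE). Vectorised
## because the consensus-DEG step runs it over thousands of genes.
rank_sum_rows <- function(M, ia, ib) {
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
  na <- length(ia); nb <- length(ib); n <- na + nb
  stopifnot(na >= 1L, nb >= 1L)
  sub <- M[, c(ia, ib), drop = FALSE]
  res <- apply(sub, 1L, function(v) {
    r <- rank(v)
    W <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    nt <- tabulate(match(v, unique(v)))
    tie <- sum(nt^3 - nt)
    s2 <- na * nb / 12 * ((n + 1) - tie / (n * (n - 1)))
    c(W, s2)
  })
  W <- res[1L, ]; s2 <- res[2L, ]
  mu <- na * nb / 2
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(s2)
  p <- 2 * stats::pnorm(-abs(z))
  p[s2 == 0] <- 1
  list(statistic = unname(W), p_value = unname(pmin(p, 1)))
}

#' Two-sided Wilcoxon rank-sum test between two numeric vectors
#'
#' Normal approximation with tie and continuity correction; the statistic is
#' the Mann-Whitney W of the first group.
#'
#' @param x,y numeric vectors.
#' @return list with `statistic` and `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  r <- rank_sum_rows(matrix(c(x, y), nrow = 1L),
                     seq_along(x), length(x) + seq_along(y))
  list(statistic = r$statistic, p_value = r$p_value)
}

## Spearman correlation of every row of M against vector y, with p-values
## from the t approximation. Rows with zero rank variance get r = NA, p = 1.
spearman_rows_vs <- function(M, y) {
  n <- length(y)
  stopifnot(ncol(M) == n, n >= 3L)
  ry <- rank(y)
  RM <- t(apply(M, 1L, rank))
  r <- suppressWarnings(as.vector(stats::cor(ry, t(RM))))
  p <- spearman_p(r, n)
  p[is.na(r)] <- 1
  list(r = r, p_value = p)
}

spearman_p <- function(r, n) {
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Spearman correlation between two vectors (pairwise-complete)
#' @param x,y numeric vectors of equal length; NA pairs dropped.
#' @return list with `r`, `n` and `p_value` (t approximation).
#' @export
spearman_cor <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) return(list(r = NA_real_, n = n, p_value = NA_real_))
  r <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  p <- if (is.na(r)) NA_real_ else spearman_p(r, n)
  list(r = r, n = n, p_value = p)
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted gene modules; label values themselves
#' do not matter, only the induced partitions.
#'
#' @param a,b vectors of equal length (any atomic type).
#' @return the adjusted Rand index in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

## INFO-level logging; no timestamps so pipeline outputs stay byte-stable.
log_info <- function(fmt, ..., logfile = NULL) {
  line <- sprintf(paste0("INFO ", fmt), ...)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", sep = "", file = logfile, append = TRUE)
  invisible(line)
}

## min-max rescale to [0, 1]; constant input is an error at call sites that
## require contrast, so guard there.
minmax01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("cannot rescale a constant vector to [0, 1]")
  (x - r[1]) / (r[2] - r[1])
}
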