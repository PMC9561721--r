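#' Rank-rank hypergeometric overlap grid
#'
#' Computes the RRHO heatmap grid for two signed signatures over their
#' shared genes. Both axes order genes by signed score descending (most
#' upregulated first, most downregulated last). For each pair of rank
#' thresholds `(i*step, j*step)` the cell holds a signed −log10
#' hypergeometric tail probability for the overlap `k` between the first
#' `i*step` genes of the y-signature and the first `j*step` genes of the
#' x-signature: positive (upper tail, `P(X >= k)`) when `k` strictly
#' exceeds its expectation `i*step * j*step / N`, otherwise negative
#' (lower tail, `P(X <= k)`). Strong positive values in the corner
#' quadrants of a disease-vs-treatment map are the reversal pattern.
#'
#' @param sig_x,sig_y `signed_scores` or `portrait` objects (x = columns,
#'   y = rows of the heatmap).
#' @param step Rank increment between thresholds (default 100); thresholds
#'   run `step, 2*step, ...` up to the shared-gene count.
#' @param p_floor Floor before −log10 (default 1e-320).
#' @return An `rrho_map` list: `values` (matrix, rows = y thresholds,
#'   columns = x thresholds), `thresholds_x`, `thresholds_y`, `step`,
#'   `genes_x`, `genes_y` (axis orderings), `N`.
#' @export
rrho_grid <- function(sig_x, sig_y, step = 100L, p_floor = 1e-320) {
  stopifnot(step >= 1)
  sx <- signature_scores(sig_x); sy <- signature_scores(sig_y)
  shared <- intersect(names(sx), names(sy))
  N <- length(shared)
  if (step > N) {
    stop("step (", step, ") exceeds the shared-gene count (", N, ")",
         call. = FALSE)
  }
  ord_x <- shared[order(-sx[shared], shared)]
  ord_y <- shared[order(-sy[shared], shared)]
  m <- N %/% step
  thr <- step * seq_len(m)

  # bin each gene by which threshold block its rank falls in on each axis,
  # then a 2-D cumulative sum gives every overlap count at once
  bx <- ceiling(match(shared, ord_x) / step)
  by <- ceiling(match(shared, ord_y) / step)
  counts <- matrix(0L, nrow = m, ncol = m)
  inside <- bx <= m & by <= m
  if (any(inside)) {
    tab <- table(factor(by[inside], levels = seq_len(m)),
                 factor(bx[inside], levels = seq_len(m)))
    counts <- apply(apply(unclass(tab), 2, cumsum), 1, cumsum)
    counts <- t(counts)
  }

  K <- matrix(thr, nrow = m, ncol = m)        # y-list size per row
  n2 <- matrix(thr, nrow = m, ncol = m, byrow = TRUE) # x-list size per col
  expected <- K * n2 / N
  p_up <- stats::phyper(counts - 1, K, N - K, n2, lower.tail = FALSE)
  p_lo <- stats::phyper(counts, K, N - K, n2, lower.tail = TRUE)
  values <- ifelse(counts > expected,
                   neg_log10(p_up, p_floor),
                   -neg_log10(p_lo, p_floor))
  dimnames(values) <- list(y = thr, x = thr)
  structure(list(values = values, thresholds_x = thr, thresholds_y = thr,
                 step = as.integer(step), genes_x = ord_x, genes_y = ord_y,
                 N = N),
            class = "rrho_map")
}

#' Render an RRHO map as a PNG heatmap
#'
#' Diverging palette centered at 0 (blue = under-enrichment, red =
#' over-enrichment), axes in rank thresholds with the most upregulated genes
#' at the origin. Deterministic for a fixed map and settings.
#'
#' @param map An `rrho_map`.
#' @param path Output PNG path.
#' @param width,height Image size in pixels (default 640).
#' @param palette_size Number of colour bins (default 101, odd so 0 sits on
#'   the middle colour).
#' @return `path`, invisibly.
#' @export
render_rrho <- function(map, path, width = 640L, height = 640L,
                        palette_size = 101L) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  v <- map$values
  lim <- max(abs(v), 1e-12)
  breaks <- seq(-lim, lim, length.out = palette_size + 1L)
  half <- (palette_size - 1L) %/% 2L
  cols <- c(grDevices::colorRampPalette(c("#2166AC", "#F7F7F7"))(half + 1L),
            grDevices::colorRampPalette(c("#F7F7F7", "#B2182B"))(half + 1L)[-1])
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::image(x = map$thresholds_x, y = map$thresholds_y,
                  z = t(v), col = cols, breaks = breaks,
                  xlab = "rank threshold (x signature)",
                  ylab = "rank threshold (y signature)",
                  main = "rank-rank hypergeometric overlap",
                  useRaster = TRUE)
  invisible(path)
}

#' Write an RRHO map's value matrix as TSV
#'
#' @param map An `rrho_map`.
#' @param path Output TSV path; rows = y thresholds, columns = x thresholds.
#' @return `path`, invisibly.
#' @export
write_rrho <- function(map, path) {
  df <- as.data.frame(map$values)
  names(df) <- map$thresholds_x
  df <- cbind(threshold_y = map$thresholds_y, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
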