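#' Summarise per-base depth into fixed windows
#'
#' Non-overlapping tiling of the chromosome into `window`-sized windows (the
#' last window may be short); per-window arithmetic mean of depth and of
#' mapping quality.
#'
#' @param depth Numeric per-base depth vector covering the chromosome.
#' @param mq Optional numeric per-base mapping quality vector (same length).
#' @param window Window width in bases (default 1000).
#' @param chrom Chromosome name.
#' @return A `window_depth_track` data frame (`chrom`, `start`, `end`,
#'   `depth`, `mq`).
#' @export
window_depth <- function(depth, mq = NULL, window = 1000L, chrom = "chrT") {
  if (window < 1) stop("window must be >= 1")
  n <- length(depth)
  if (n == 0L) stop("empty depth vector")
  idx <- rep(seq_len(ceiling(n / window)), each = window, length.out = n)
  starts <- (seq_len(max(idx)) - 1L) * window + 1L
  out <- data.frame(
    chrom = chrom, start = starts, end = pmin(starts + window - 1L, n),
    depth = as.numeric(tapply(depth, idx, mean)),
    mq = if (is.null(mq)) NA_real_ else as.numeric(tapply(mq, idx, mean)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("window_depth_track", "data.frame")
  out
}

#' Mapping-quality filter mask
#'
#' Flags windows whose mean mapping quality falls strictly below
#' `mean(MQ) - 3 SD(MQ)` computed over all windows — the rule whose value on
#' the real pools was the published MQ < 30 cut-off.
#'
#' @param track A `window_depth_track` with an `mq` column.
#' @return Logical mask of filtered (flagged) windows, with the threshold as
#'   attribute `threshold`.
#' @export
mq_filter <- function(track) {
  if (nrow(track) < 2L) stop("SD undefined: need >= 2 windows")
  thr <- mean(track$mq) - 3 * stats::sd(track$mq)
  mask <- track$mq < thr
  attr(mask, "threshold") <- thr
  mask
}

#' Log2 fold change of depth between two pools
#'
#' Each pool's window depths are normalized by that pool's genome-wide median
#' depth, then the per-window log2 ratio a/b is taken. Windows flagged by
#' either pool's MQ filter, or with zero depth in either pool, are excluded
#' (fold change `NA`, `filtered = TRUE`).
#'
#' @param track_a,track_b `window_depth_track`s on the same grid.
#' @param mask_a,mask_b Optional logical filter masks (default: [mq_filter()]
#'   of each track; pass `FALSE` to disable).
#' @return A `fold_change_track` data frame (`chrom`, `start`, `end`,
#'   `log2fc`, `filtered`).
#' @export
log2_fold_change <- function(track_a, track_b,
                             mask_a = mq_filter(track_a),
                             mask_b = mq_filter(track_b)) {
  if (nrow(track_a) != nrow(track_b) ||
      any(track_a$start != track_b$start) ||
      any(track_a$end != track_b$end)) {
    stop("window grids differ between pools")
  }
  med_a <- stats::median(track_a$depth)
  med_b <- stats::median(track_b$depth)
  if (med_a <= 0 || med_b <= 0) stop("zero median depth: cannot normalize")
  filtered <- (mask_a | mask_b) | track_a$depth <= 0 | track_b$depth <= 0
  fc <- ifelse(filtered, NA_real_,
               log2((track_a$depth / med_a) / (track_b$depth / med_b)))
  out <- data.frame(chrom = track_a$chrom, start = track_a$start,
                    end = track_a$end, log2fc = fc, filtered = filtered,
                    stringsAsFactors = FALSE)
  class(out) <- c("fold_change_track", "data.frame")
  out
}

#' Segment a fold-change track into CNV calls
#'
#' Maximal runs of windows whose |log2 fold change| meets the call threshold
#' (same sign), allowing up to `max_gap` intervening filtered or
#' sub-threshold windows, merged into calls. Deterministic; an empty call
#' list is a valid result.
#'
#' @param fc A `fold_change_track`.
#' @param min_abs_log2fc Per-window call threshold (default 0.58, ~log2 1.5).
#' @param min_windows Minimum qualifying windows per call (default 3).
#' @param max_gap Maximum run of non-qualifying windows bridged (default 1).
#' @return A `cnv_calls` data frame (`chrom`, `start`, `end`, `direction`,
#'   `mean_log2fc`, `n_windows`).
#' @export
segment_cnv <- function(fc, min_abs_log2fc = 0.58, min_windows = 3L,
                        max_gap = 1L) {
  calls <- list()
  for (dir in c("gain_a", "gain_b")) {
    q <- !fc$filtered & !is.na(fc$log2fc) &
      (if (dir == "gain_a") fc$log2fc >= min_abs_log2fc
       else fc$log2fc <= -min_abs_log2fc)
    idx <- which(q)
    if (length(idx) == 0L) next
    grp <- cumsum(c(1L, diff(idx) > max_gap + 1L))
    for (g in split(idx, grp)) {
      if (length(g) < min_windows) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = fc$chrom[g[1]], start = fc$start[g[1]],
        end = fc$end[g[length(g)]], direction = dir,
        mean_log2fc = mean(fc$log2fc[g]), n_windows = length(g),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               direction = character(0), mean_log2fc = numeric(0),
               n_windows = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat(sprintf("<cnv_calls> %d call(s)\n", nrow(x)))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s:%s-%s %s (mean log2FC %.2f, %d windows)\n",
                x$chrom[i], format(x$start[i], big.mark = ","),
                format(x$end[i], big.mark = ","), x$direction[i],
                x$mean_log2fc[i], x$n_windows[i]))
  }
  invisible(x)
}

#' Synthetic gene annotation of the duplicated region
#'
#' Reads the packaged synthetic gene fixture: a toy annotation whose overlap
#' pattern with the three duplicated segments reproduces the described gene
#' content (3' of PSMC5 and all of SMARCD2 in CNV1; HOXB7 and HOXB8 in CNV2;
#' 5' of CCR7, SMARCE1 and 3' of KRT222 in CNV3) plus flanking genes outside
#' the duplications. Coordinates are synthetic stand-ins, not real galGal4
#' annotation.
#'
#' @return Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
mb_gene_fixture <- function() {
  utils::read.delim(
    system.file("extdata", "gga27_genes_synthetic.tsv", package = "mbsv"),
    stringsAsFactors = FALSE
  )
}

#' Genes overlapping a set of intervals
#'
#' @param genes Data frame with `gene`, `chrom`, `start`, `end` (e.g.
#'   [mb_gene_fixture()]).
#' @param intervals Data frame with `chrom` (optional), `start`, `end` —
#'   e.g. CNV calls or [mb_breakpoints()].
#' @return Character vector of the distinct overlapping gene names, in
#'   positional order.
#' @export
genes_in_cnv <- function(genes, intervals) {
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end))
  chr <- if ("chrom" %in% names(intervals)) intervals$chrom else
    rep(genes$chrom[1], nrow(intervals))
  iv <- GenomicRanges::GRanges(chr,
                               IRanges::IRanges(intervals$start, intervals$end))
  hits <- GenomicRanges::findOverlaps(g, iv)
  idx <- sort(unique(S4Vectors::queryHits(hits)))
  genes$gene[idx[order(genes$start[idx])]]
}
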