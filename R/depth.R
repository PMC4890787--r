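#' Configure pooled read-depth simulation
#'
#' Defaults reproduce the published pool coverages (95x for the Mb-line pool
#' and 97x for the wild-type pool). Per-window depth is negative-binomial with
#' mean `mean_depth * copy_number / 2`; `overdispersion = 0` (the default) is
#' the Poisson limit, since only mean depths are reported for the real pools.
#'
#' @param window_size Window width in bases (default 1000).
#' @param mean_depth_pool_a,mean_depth_pool_b Genome-wide mean depths at copy
#'   number 2 (defaults 95 and 97).
#' @param overdispersion Negative-binomial overdispersion `phi >= 0`
#'   (variance `mu + phi * mu^2`); 0 gives Poisson.
#' @param mq_mean,mq_sd Mean and SD of per-window mapping quality.
#' @param low_mq_regions List of `c(start, end)` intervals whose windows get
#'   depressed mapping quality (`low_mq_mean`).
#' @param low_mq_mean Mean MQ inside `low_mq_regions`.
#' @param seed Integer seed.
#' @return An object of class `depth_sim_config`.
#' @export
depth_sim_config <- function(window_size = 1000L, mean_depth_pool_a = 95,
                             mean_depth_pool_b = 97, overdispersion = 0,
                             mq_mean = 50, mq_sd = 3,
                             low_mq_regions = list(), low_mq_mean = 10,
                             seed = 1L) {
  stopifnot(window_size >= 1, mean_depth_pool_a > 0, mean_depth_pool_b > 0,
            overdispersion >= 0, mq_sd >= 0)
  structure(list(window_size = as.integer(window_size),
                 mean_depth_pool_a = mean_depth_pool_a,
                 mean_depth_pool_b = mean_depth_pool_b,
                 overdispersion = overdispersion,
                 mq_mean = mq_mean, mq_sd = mq_sd,
                 low_mq_regions = low_mq_regions, low_mq_mean = low_mq_mean,
                 seed = as.integer(seed)),
            class = "depth_sim_config")
}

#' Build a per-window copy-number track
#'
#' Background copy number (2 for a diploid pool) with altered copy number
#' inside the given intervals. Windows tile `[1, genome_length]`; a window's
#' copy number is the base-weighted mean when an interval partially covers it.
#'
#' @param genome_length Chromosome length in bases.
#' @param window_size Window width.
#' @param intervals Data frame with `start`, `end` (1-based inclusive), or a
#'   list of `c(start, end)`.
#' @param cn_background Copy number outside intervals (default 2).
#' @param cn_interval Copy number inside intervals (default 4), recycled.
#' @param chrom Chromosome name.
#' @return Data frame with `chrom`, `start`, `end`, `copy_number`.
#' @export
copy_number_track <- function(genome_length, window_size = 1000L,
                              intervals = NULL, cn_background = 2,
                              cn_interval = 4, chrom = "chrT") {
  starts <- seq(1L, genome_length, by = window_size)
  ends <- pmin(starts + window_size - 1L, genome_length)
  cn <- rep(cn_background, length(starts))
  if (!is.null(intervals)) {
    if (is.list(intervals) && !is.data.frame(intervals)) {
      intervals <- data.frame(start = vapply(intervals, `[`, numeric(1), 1L),
                              end = vapply(intervals, `[`, numeric(1), 2L))
    }
    cn_interval <- rep_len(cn_interval, nrow(intervals))
    for (i in seq_len(nrow(intervals))) {
      ov <- pmin(ends, intervals$end[i]) - pmax(starts, intervals$start[i]) + 1
      ov <- pmax(ov, 0)
      cn <- cn + ov / (ends - starts + 1) * (cn_interval[i] - cn_background)
    }
  }
  data.frame(chrom = chrom, start = starts, end = ends, copy_number = cn,
             stringsAsFactors = FALSE)
}

.rdepth <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate pooled read-depth tracks for two pools
#'
#' @param copy_number_track_a,copy_number_track_b Tracks from
#'   [copy_number_track()] on the same window grid (values `>= 0`).
#' @param cfg A [depth_sim_config()].
#' @return List of two `window_depth_track` data frames (`pool_a`, `pool_b`)
#'   with columns `chrom`, `start`, `end`, `depth`, `mq`.
#' @export
simulate_pool_depth <- function(copy_number_track_a, copy_number_track_b,
                                cfg = depth_sim_config()) {
  stopifnot(inherits(cfg, "depth_sim_config"))
  a <- copy_number_track_a; b <- copy_number_track_b
  if (nrow(a) != nrow(b) || any(a$start != b$start) || any(a$end != b$end)) {
    stop("copy-number tracks are not on the same window grid")
  }
  stopifnot(all(a$copy_number >= 0), all(b$copy_number >= 0))
  set.seed(cfg$seed)
  n <- nrow(a)
  mk_mq <- function() {
    mq <- stats::rnorm(n, cfg$mq_mean, cfg$mq_sd)
    for (iv in cfg$low_mq_regions) {
      low <- a$start <= iv[2] & a$end >= iv[1]
      mq[low] <- stats::rnorm(sum(low), cfg$low_mq_mean, cfg$mq_sd)
    }
    pmin(pmax(mq, 0), 60)
  }
  track <- function(cn, mean_depth) {
    data.frame(chrom = a$chrom, start = a$start, end = a$end,
               depth = .rdepth(n, mean_depth * cn / 2, cfg$overdispersion),
               mq = mk_mq(), stringsAsFactors = FALSE)
  }
  out <- list(pool_a = track(a$copy_number, cfg$mean_depth_pool_a),
              pool_b = track(b$copy_number, cfg$mean_depth_pool_b))
  class(out$pool_a) <- c("window_depth_track", "data.frame")
  class(out$pool_b) <- c("window_depth_track", "data.frame")
  out
}

#' Write a window depth track as bedGraph
#'
#' Coordinates are converted to 0-based half-open at this boundary only; the
#' package works in 1-based inclusive coordinates internally.
#'
#' @param track A `window_depth_track` data frame.
#' @param path Output file.
#' @param value Column to write (`"depth"` or `"mq"`).
#' @return `path`, invisibly.
#' @export
write_depth_bedgraph <- function(track, path, value = c("depth", "mq")) {
  value <- match.arg(value)
  utils::write.table(
    data.frame(track$chrom, track$start - 1L, track$end, track[[value]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
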