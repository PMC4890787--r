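## 3-state transition matrix between positions d cM apart for an F2 genotype
## chain {HH, HL, LL} (two independent gametic chains, Haldane recombination)
.f2_transition <- function(d_cM) {
  r <- haldane_r(d_cM)
  matrix(c(
    (1 - r)^2,     2 * r * (1 - r),     r^2,
    r * (1 - r),   (1 - r)^2 + r^2,     r * (1 - r),
    r^2,           2 * r * (1 - r),     (1 - r)^2
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("HH", "HL", "LL"), c("HH", "HL", "LL")))
}

#' Infer line origin along the chromosome for each F2 individual
#'
#' Posterior probabilities of the founder-line origin classes
#' `{HH, HL, LL}` (both alleles from line H, one from each line, both from
#' line L) at every marker and every centiMorgan of a grid, from a 3-state
#' hidden Markov model: Haldane transition probabilities between positions,
#' emissions from the founder-line allele frequencies with a genotyping-error
#' parameter, prior `{1/4, 1/2, 1/4}`. With fully informative markers and
#' zero error the posteriors are 0/1 and equal the true transmission.
#'
#' @param gm A [genotype_matrix()] containing founders and F2s.
#' @param ped Pedigree with columns `id`, `generation`, `line` (`"HB"` /
#'   `"HQLA"` for founders).
#' @param map Genetic map data frame (`marker`, `chrom`, `bp`, `cM`).
#' @param error_rate Per-allele genotyping error (default 0.001).
#' @param grid_step_cM Grid spacing (default 1 cM).
#' @param individuals Ids to infer for; default all `generation == "F2"`.
#' @return An object of class `line_origin_tracks`: list with `prob` (array
#'   individuals x grid x 3), `grid_cM`, `grid_bp`, `individuals`, `map`.
#' @export
infer_line_origin <- function(gm, ped, map, error_rate = 0.001,
                              grid_step_cM = 1, individuals = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(individuals)) {
    if (!"generation" %in% names(ped)) {
      stop("pedigree has no 'generation' column; pass `individuals` explicitly")
    }
    individuals <- ped$id[ped$generation == "F2"]
  }
  missing_ped <- setdiff(individuals, ped$id)
  if (length(missing_ped) > 0L) {
    stop(sprintf("individual(s) absent from pedigree: %s",
                 paste(utils::head(missing_ped, 3), collapse = ", ")))
  }
  individuals <- intersect(individuals, rownames(gm$calls))
  use <- map$marker %in% colnames(gm$calls)
  map <- map[use, , drop = FALSE]
  if (nrow(map) == 0L) stop("no mapped markers present in the genotype matrix")
  map <- map[order(map$cM), , drop = FALSE]

  ## founder-line allele frequencies per marker
  h_ids <- ped$id[!is.na(ped$line) & ped$line == "HB"]
  l_ids <- ped$id[!is.na(ped$line) & ped$line == "HQLA"]
  h_ids <- intersect(h_ids, rownames(gm$calls))
  l_ids <- intersect(l_ids, rownames(gm$calls))
  if (length(h_ids) == 0L || length(l_ids) == 0L) {
    stop("founder genotypes for both lines are required")
  }
  p_h <- colMeans(gm$calls[h_ids, map$marker, drop = FALSE], na.rm = TRUE) / 2
  p_l <- colMeans(gm$calls[l_ids, map$marker, drop = FALSE], na.rm = TRUE) / 2
  p_h[is.nan(p_h)] <- 0.5
  p_l[is.nan(p_l)] <- 0.5
  q_h <- p_h * (1 - error_rate) + (1 - p_h) * error_rate
  q_l <- p_l * (1 - error_rate) + (1 - p_l) * error_rate

  grid_cM <- seq(floor(min(map$cM)), ceiling(max(map$cM)), by = grid_step_cM)
  pos_cM <- sort(unique(c(map$cM, grid_cM)))
  np <- length(pos_cM)
  marker_at <- match(map$cM, pos_cM)  # position index of each marker
  trans <- lapply(seq_len(np - 1L),
                  function(i) .f2_transition(pos_cM[i + 1L] - pos_cM[i]))
  prior <- c(HH = 0.25, HL = 0.5, LL = 0.25)

  ## per-position emission table: rows = positions, entries P(g | state)
  emit_for <- function(g) {
    ## returns np x 3 matrix of emission likelihoods for one individual
    e <- matrix(1, np, 3)
    for (k in seq_along(marker_at)) {
      gi <- g[k]
      if (is.na(gi)) next
      qh <- q_h[k]; ql <- q_l[k]
      lik <- c(
        HH = stats::dbinom(gi, 2, qh),
        HL = c((1 - qh) * (1 - ql),
               qh * (1 - ql) + ql * (1 - qh),
               qh * ql)[gi + 1L],
        LL = stats::dbinom(gi, 2, ql)
      )
      e[marker_at[k], ] <- e[marker_at[k], ] * lik
    }
    e
  }

  prob <- array(NA_real_,
                dim = c(length(individuals), length(grid_cM), 3L),
                dimnames = list(individuals, NULL, c("HH", "HL", "LL")))
  grid_at <- match(grid_cM, pos_cM)
  for (ii in seq_along(individuals)) {
    g <- gm$calls[individuals[ii], map$marker]
    e <- emit_for(g)
    ## forward
    fwd <- matrix(0, np, 3)
    f <- prior * e[1, ]
    fwd[1, ] <- f / sum(f)
    for (t in 2:np) {
      f <- drop(fwd[t - 1L, ] %*% trans[[t - 1L]]) * e[t, ]
      fwd[t, ] <- f / sum(f)
    }
    ## backward
    bwd <- matrix(0, np, 3)
    bwd[np, ] <- 1
    for (t in (np - 1L):1L) {
      b <- drop(trans[[t]] %*% (e[t + 1L, ] * bwd[t + 1L, ]))
      bwd[t, ] <- b / sum(b)
    }
    post <- fwd * bwd
    post <- post / rowSums(post)
    prob[ii, , ] <- post[grid_at, ]
  }
  grid_bp <- stats::approx(map$cM, map$bp, xout = grid_cM, rule = 2)$y
  structure(list(prob = prob, grid_cM = grid_cM, grid_bp = grid_bp,
                 individuals = individuals, map = map,
                 chrom = map$chrom[1]),
            class = "line_origin_tracks")
}

#' @export
print.line_origin_tracks <- function(x, ...) {
  cat(sprintf("<line_origin_tracks> %d individuals, %d grid points (%g-%g cM)\n",
              length(x$individuals), length(x$grid_cM),
              min(x$grid_cM), max(x$grid_cM)))
  invisible(x)
}

## F statistic of (additive, dominance) line-origin regressors given covariate
.f_at_point <- function(y, cov, a, d) {
  X0 <- cbind(1, cov)
  X1 <- cbind(X0, a, d)
  q1 <- qr(X1)
  df1 <- q1$rank - qr(X0)$rank
  if (df1 < 2L) {
    X1 <- cbind(X0, a)
    q1 <- qr(X1)
    df1 <- q1$rank - qr(X0)$rank
  }
  if (df1 < 1L) return(c(F = 0, df1 = 0))
  rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
  rss1 <- sum(qr.resid(q1, y)^2)
  df2 <- length(y) - q1$rank
  c(F = max(0, (rss0 - rss1) / df1 / (rss1 / df2)), df1 = df1)
}

#' Linkage F-scan over the line-origin grid
#'
#' At each grid position the phenotype is regressed on the additive
#' (`P(HH) - P(LL)`) and dominance (`P(HL)`) expectations of line origin plus
#' the covariate; the 2-df F statistic against the covariate-only model is
#' reported. If the dominance regressor is collinear (e.g. no LL individuals)
#' the test drops to 1 df with a notice.
#'
#' @param tracks A [infer_line_origin()] result.
#' @param ph Phenotype data frame (`id`, `mb_week10`, covariate).
#' @param covariate Covariate column name (default `"mb_at_birth"`).
#' @return An `fstat_profile` data frame (`grid_cM`, `grid_bp`, `F`, `df1`).
#' @export
linkage_scan <- function(tracks, ph, covariate = "mb_at_birth") {
  stopifnot(inherits(tracks, "line_origin_tracks"))
  ids <- intersect(tracks$individuals, ph$id)
  if (length(ids) < 10L) stop("too few phenotyped individuals on the tracks")
  y <- ph$mb_week10[match(ids, ph$id)]
  cov <- ph[[covariate]][match(ids, ph$id)]
  sel <- match(ids, tracks$individuals)
  res <- t(vapply(seq_along(tracks$grid_cM), function(k) {
    p <- tracks$prob[sel, k, , drop = FALSE]
    .f_at_point(y, cov, p[, 1, "HH"] - p[, 1, "LL"], p[, 1, "HL"])
  }, numeric(2)))
  if (any(res[, "df1"] == 1L)) {
    message("dominance regressor collinear at some positions; 1-df test used")
  }
  out <- data.frame(grid_cM = tracks$grid_cM, grid_bp = tracks$grid_bp,
                    F = res[, "F"], df1 = as.integer(res[, "df1"]))
  class(out) <- c("fstat_profile", "data.frame")
  out
}

#' Randomization-test threshold for the linkage scan
#'
#' Genome-wide (1 - alpha) quantile of the maximum F statistic over
#' phenotype permutations (phenotype and covariate rows are permuted
#' together, preserving their relationship).
#'
#' @inheritParams linkage_scan
#' @param n_perm Number of permutations (`>= 100`; the published analysis
#'   used 1000).
#' @param alpha Genome-wide error rate (default 0.05).
#' @param seed Integer seed.
#' @return The F threshold, with the permutation max-F distribution attached
#'   as attribute `max_f`.
#' @export
randomization_threshold <- function(tracks, ph, n_perm = 1000L, alpha = 0.05,
                                    covariate = "mb_at_birth", seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100 for a stable threshold")
  ids <- intersect(tracks$individuals, ph$id)
  y <- ph$mb_week10[match(ids, ph$id)]
  if (stats::var(y) == 0) stop("degenerate: constant phenotype")
  cov <- ph[[covariate]][match(ids, ph$id)]
  sel <- match(ids, tracks$individuals)
  A <- tracks$prob[sel, , "HH", drop = TRUE] - tracks$prob[sel, , "LL", drop = TRUE]
  D <- tracks$prob[sel, , "HL", drop = TRUE]
  set.seed(seed)
  maxf <- vapply(seq_len(n_perm), function(b) {
    o <- sample.int(length(y))
    max(vapply(seq_len(ncol(A)), function(k) {
      .f_at_point(y[o], cov[o], A[, k], D[, k])["F"]
    }, numeric(1)))
  }, numeric(1))
  thr <- unname(stats::quantile(maxf, 1 - alpha, type = 1))
  attr(thr, "max_f") <- maxf
  thr
}

#' Fine-map by shared identity-by-descent
#'
#' Hard-calls the line-origin posteriors (class with posterior
#' `> posterior_min`, otherwise unknown) and finds the grid positions where
#' every affected (Mb) individual carries at least one H-origin allele and
#' every unaffected individual carries none — the dominant-model shared-IBD
#' rule. Unknown calls cannot disqualify a position (conservative). The
#' longest qualifying run is returned as the minimal enclosing interval,
#' snapped outward to the nearest flanking markers, with the recombinant
#' individuals that define each boundary.
#'
#' @inheritParams linkage_scan
#' @param posterior_min Hard-call threshold (default 0.99).
#' @return An object of class `ibd_interval` (possibly empty).
#' @export
shared_ibd_interval <- function(tracks, ph, posterior_min = 0.99) {
  stopifnot(inherits(tracks, "line_origin_tracks"))
  ids <- intersect(tracks$individuals, ph$id)
  pheno <- ph$mb_week10[match(ids, ph$id)]
  mb <- ids[pheno == 1L]
  non <- ids[pheno == 0L]
  if (length(mb) == 0L) stop("definition error: no affected individuals")
  sel <- match(ids, tracks$individuals)
  p <- tracks$prob[sel, , , drop = FALSE]
  dimnames(p)[[1]] <- ids
  cls <- apply(p, c(1, 2), function(v) {
    k <- which.max(v)
    if (v[k] > posterior_min) k else NA_integer_
  })
  carrier <- cls <= 2L  # HH or HL; NA = unknown
  qual <- vapply(seq_len(ncol(carrier)), function(k) {
    !any(carrier[mb, k] == FALSE, na.rm = TRUE) &&
      !any(carrier[non, k] == TRUE, na.rm = TRUE)
  }, logical(1))
  empty <- structure(list(chrom = tracks$chrom, start_bp = NA_real_,
                          end_bp = NA_real_, flank_markers = character(0),
                          boundary_individuals = list(), n_positions = 0L,
                          empty = TRUE),
                     class = "ibd_interval")
  if (!any(qual)) {
    message("shared-IBD intersection is empty (phenocopy or misclassification)")
    return(empty)
  }
  runs <- rle(qual)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values)
  best <- ok[which.max(runs$lengths[ok])]
  i0 <- starts[best]; i1 <- ends[best]
  bp0 <- tracks$grid_bp[i0]; bp1 <- tracks$grid_bp[i1]
  ## snap outward to nearest flanking markers
  mleft <- tracks$map[tracks$map$bp <= bp0, , drop = FALSE]
  mright <- tracks$map[tracks$map$bp >= bp1, , drop = FALSE]
  flank <- c(if (nrow(mleft)) utils::tail(mleft$marker, 1) else NA_character_,
             if (nrow(mright)) mright$marker[1] else NA_character_)
  start_bp <- if (nrow(mleft)) utils::tail(mleft$bp, 1) else bp0
  end_bp <- if (nrow(mright)) mright$bp[1] else bp1
  boundary_ind <- function(k) {
    if (k < 1L || k > ncol(carrier)) return(character(0))
    c(mb[which(carrier[mb, k] == FALSE)], non[which(carrier[non, k] == TRUE)])
  }
  structure(list(chrom = tracks$chrom, start_bp = start_bp, end_bp = end_bp,
                 flank_markers = flank,
                 boundary_individuals = list(left = boundary_ind(i0 - 1L),
                                             right = boundary_ind(i1 + 1L)),
                 n_positions = i1 - i0 + 1L,
                 grid_cM = tracks$grid_cM[c(i0, i1)],
                 empty = FALSE),
            class = "ibd_interval")
}

#' @export
print.ibd_interval <- function(x, ...) {
  if (x$empty) {
    cat("<ibd_interval> empty\n")
  } else {
    cat(sprintf("<ibd_interval> %s:%s-%s (%.0f kb, %d grid positions)\n",
                x$chrom, format(x$start_bp, big.mark = ","),
                format(x$end_bp, big.mark = ","),
                (x$end_bp - x$start_bp) / 1e3, x$n_positions))
    cat(sprintf("  flanking markers: %s\n",
                paste(x$flank_markers, collapse = " - ")))
  }
  invisible(x)
}
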