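#' Genotype and individual quality control
#'
#' Applies, in order: removal of individuals with call rate `<= ind_call_rate`;
#' removal of SNPs with call rate `<= snp_call_rate`; removal of SNPs with
#' minor allele frequency below `maf_min`; pedigree-based Mendelian
#' consistency screening (individuals or SNPs with an error rate above
#' `mendel_max` are removed, remaining single inconsistent offspring calls are
#' set missing); removal of W-linked markers; and masking of heterozygous
#' Z-linked calls in females (the heterogametic sex in birds). Thresholds are
#' strict inequalities as stated.
#'
#' @param gm A [genotype_matrix()].
#' @param ped Pedigree data frame with columns `id`, `sire`, `dam`, `sex`.
#' @param ind_call_rate,snp_call_rate Minimum call rates (exclusive bounds).
#' @param maf_min Minimum minor allele frequency (calls below are removed).
#' @param mendel_max Maximum tolerated Mendelian error rate per entity.
#' @return A list of class `qc_result` with elements `genotypes` (filtered
#'   [genotype_matrix()]) and `report` (step-by-step counts).
#' @export
qc_filter <- function(gm, ped, ind_call_rate = 0.9, snp_call_rate = 0.9,
                      maf_min = 0.05, mendel_max = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!all(rownames(gm$calls) %in% ped$id)) {
    stop("pedigree does not cover all genotyped individuals")
  }
  calls <- gm$calls
  markers <- gm$markers
  report <- list(n_ind_in = nrow(calls), n_snp_in = ncol(calls))

  ## 1. individual call rate
  cr_ind <- rowMeans(!is.na(calls))
  drop_ind <- cr_ind <= ind_call_rate
  report$ind_low_call_rate <- sum(drop_ind)
  calls <- calls[!drop_ind, , drop = FALSE]
  if (nrow(calls) == 0L) stop("all individuals removed by QC")

  ## 2. SNP call rate
  cr_snp <- colMeans(!is.na(calls))
  drop_snp <- cr_snp <= snp_call_rate
  report$snp_low_call_rate <- sum(drop_snp)
  calls <- calls[, !drop_snp, drop = FALSE]
  markers <- markers[!drop_snp, , drop = FALSE]

  ## 3. minor allele frequency
  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_snp <- is.nan(maf) | maf < maf_min
  report$snp_low_maf <- sum(drop_snp)
  calls <- calls[, !drop_snp, drop = FALSE]
  markers <- markers[!drop_snp, , drop = FALSE]

  ## 4. Mendelian consistency against genotyped parents
  ids <- rownames(calls)
  trio <- ped[ped$id %in% ids & ped$sire %in% ids & ped$dam %in% ids, ]
  if (nrow(trio) > 0L && ncol(calls) > 0L) {
    bad <- matrix(FALSE, nrow(trio), ncol(calls))  # offspring x marker
    for (i in seq_len(nrow(trio))) {
      o <- calls[trio$id[i], ]
      s <- calls[trio$sire[i], ]
      d <- calls[trio$dam[i], ]
      obs <- !is.na(o) & !is.na(s) & !is.na(d)
      inc <- (o == 2L & (s == 0L | d == 0L)) |
        (o == 0L & (s == 2L | d == 2L)) |
        (o == 1L & ((s == 0L & d == 0L) | (s == 2L & d == 2L)))
      bad[i, ] <- obs & !is.na(inc) & inc
      bad[i, !obs] <- FALSE
    }
    n_cmp_ind <- vapply(seq_len(nrow(trio)), function(i) {
      sum(!is.na(calls[trio$id[i], ]) & !is.na(calls[trio$sire[i], ]) &
            !is.na(calls[trio$dam[i], ]))
    }, numeric(1))
    err_ind <- rowSums(bad) / pmax(n_cmp_ind, 1L)
    drop_off <- trio$id[err_ind > mendel_max]
    report$ind_mendel <- length(drop_off)

    n_cmp_snp <- colSums(!is.na(calls[trio$id, , drop = FALSE]) &
                           !is.na(calls[trio$sire, , drop = FALSE]) &
                           !is.na(calls[trio$dam, , drop = FALSE]))
    err_snp <- colSums(bad) / pmax(n_cmp_snp, 1L)
    drop_snp <- err_snp > mendel_max
    report$snp_mendel <- sum(drop_snp)

    keep_ind <- !(rownames(calls) %in% drop_off)
    calls <- calls[keep_ind, , drop = FALSE]
    bad <- bad[!(trio$id %in% drop_off), !drop_snp, drop = FALSE]
    trio <- trio[!(trio$id %in% drop_off), , drop = FALSE]
    calls <- calls[, !drop_snp, drop = FALSE]
    markers <- markers[!drop_snp, , drop = FALSE]
    ## remaining single inconsistent calls -> missing in the offspring
    if (nrow(trio) > 0L) {
      for (i in seq_len(nrow(trio))) {
        calls[trio$id[i], bad[i, ]] <- NA
      }
    }
    report$calls_set_missing <- sum(bad)
  } else {
    report$ind_mendel <- 0L
    report$snp_mendel <- 0L
    report$calls_set_missing <- 0L
  }

  ## 5. sex chromosomes
  is_w <- markers$chrom %in% c("W", "chrW")
  report$snp_w_linked <- sum(is_w)
  calls <- calls[, !is_w, drop = FALSE]
  markers <- markers[!is_w, , drop = FALSE]
  is_z <- markers$chrom %in% c("Z", "chrZ")
  if (any(is_z)) {
    sex <- ped$sex[match(rownames(calls), ped$id)]
    fem <- which(!is.na(sex) & sex == "F")
    zcols <- which(is_z)
    het <- calls[fem, zcols, drop = FALSE] == 1L
    het[is.na(het)] <- FALSE
    calls[fem, zcols][het] <- NA
    report$z_het_female_masked <- sum(het)
  } else {
    report$z_het_female_masked <- 0L
  }

  if (nrow(calls) == 0L) stop("all individuals removed by QC")
  report$n_ind_out <- nrow(calls)
  report$n_snp_out <- ncol(calls)
  structure(list(genotypes = genotype_matrix(calls, markers),
                 report = report),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<qc_result> %d/%d individuals, %d/%d SNPs retained\n",
              r$n_ind_out, r$n_ind_in, r$n_snp_out, r$n_snp_in))
  cat(sprintf(
    "  removed: %d ind (call rate), %d SNP (call rate), %d SNP (MAF),\n",
    r$ind_low_call_rate, r$snp_low_call_rate, r$snp_low_maf))
  cat(sprintf(
    "  %d ind + %d SNP (Mendelian), %d W-linked SNP; %d calls set missing\n",
    r$ind_mendel, r$snp_mendel, r$snp_w_linked, r$calls_set_missing))
  invisible(x)
}

#' Genomic kinship matrix
#'
#' Marker-based realized relatedness: genotypes are centred by twice the
#' allele frequency and scaled by `sqrt(2 p (1 - p))` per marker, missing
#' calls mean-imputed per marker, and the cross-product averaged over markers.
#'
#' Markers on the tested chromosome contribute relatedness that is collinear
#' with the tested genotypes; excluding that chromosome from the kinship
#' (leave-one-chromosome-out) avoids the resulting proximal contamination of
#' the mixed-model scan and is the recommended input to [assoc_scan()] when a
#' strong single-locus signal is expected.
#'
#' @param gm A [genotype_matrix()].
#' @param exclude_chrom Optional chromosome name(s) whose markers are left
#'   out of the kinship computation.
#' @return Symmetric kinship matrix with individual ids as dimnames.
#' @export
compute_kinship <- function(gm, exclude_chrom = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  x <- gm$calls
  if (!is.null(exclude_chrom)) {
    keep <- !(gm$markers$chrom %in% exclude_chrom)
    if (!any(keep)) stop("exclude_chrom removes every marker")
    x <- x[, keep, drop = FALSE]
  }
  if (nrow(x) < 2L || ncol(x) < 1L) stop("need >= 2 individuals and >= 1 marker")
  p <- colMeans(x, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.nan(p)
  if (!any(poly)) stop("degenerate kinship: all markers monomorphic")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(x, 2L, 2 * p)
  z[is.na(z)] <- 0  # mean imputation after centring
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  tcrossprod(z) / ncol(z)
}

## null mixed-model fit via kinship eigendecomposition; returns environmental
## residuals (GRAMMAR residuals, up to a positive scale factor)
.polygenic_residuals <- function(y, X, kin) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("model error: covariates are confounded (singular design)")
  }
  eg <- eigen(kin, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yr <- drop(crossprod(U, y))
  Xr <- crossprod(U, X)
  n <- length(y)
  nll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (delta * d + 1)
    fit <- stats::lm.wfit(Xr, yr, w)
    rss <- sum(w * fit$residuals^2)
    0.5 * (n * log(rss / n) + sum(log(delta * d + 1)))
  }
  opt <- stats::optimize(nll, c(-12, 12))
  delta <- if (opt$objective < nll(-30) - 1e-9) exp(opt$minimum) else 0
  w <- 1 / (delta * d + 1)
  fit <- stats::lm.wfit(Xr, yr, w)
  resid <- drop(U %*% (w * fit$residuals))
  list(residuals = resid, delta = delta,
       h2 = delta * mean(d) / (delta * mean(d) + 1))
}

## correlation score test of residuals against one marker, pairwise complete
.marker_test <- function(g, e) {
  obs <- !is.na(g)
  k <- sum(obs)
  if (k < 3L || stats::var(g[obs]) == 0) {
    return(c(stat = NA_real_, p = NA_real_, n = k))
  }
  r <- stats::cor(g[obs], e[obs])
  r <- min(max(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((k - 2) / (1 - r^2))
  c(stat = t, p = 2 * stats::pt(-abs(t), k - 2), n = k)
}

#' Kinship-corrected association scan
#'
#' Two-stage (GRAMMAR-style) linear mixed-model approximation: the phenotype
#' is first regressed on the covariate(s) with a polygenic random effect whose
#' covariance is proportional to the genomic kinship matrix (variance
#' components by maximum likelihood on the kinship eigendecomposition); each
#' marker is then score-tested against the environmental residuals. The
#' binary trait is analysed on the linear (0/1) scale.
#'
#' @param gm A [genotype_matrix()] (after QC).
#' @param ph Phenotype data frame with columns `id`, `mb_week10` and the
#'   covariate column.
#' @param kin Kinship matrix from [compute_kinship()].
#' @param covariate Name of the covariate column (default `"mb_at_birth"`).
#' @param condition_on Optional marker id whose genotype (mean-imputed) is
#'   added to the covariates; that marker itself is skipped.
#' @return An `assoc_result` data frame (`marker`, `chrom`, `bp`, `n`, `stat`,
#'   `p`, `neg_log10_p`, `r2_peak`) with attributes `delta` and `h2` from the
#'   polygenic fit and `peak_marker`.
#' @export
assoc_scan <- function(gm, ph, kin, covariate = "mb_at_birth",
                       condition_on = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"),
            all(c("id", "mb_week10", covariate) %in% names(ph)))
  ids <- intersect(rownames(gm$calls), ph$id)
  ids <- intersect(ids, rownames(kin))
  if (length(ids) < 10L) stop("too few phenotyped, genotyped individuals")
  y <- ph$mb_week10[match(ids, ph$id)]
  X <- cbind(1, as.matrix(ph[match(ids, ph$id), covariate, drop = FALSE]))
  if (!is.null(condition_on)) {
    if (!condition_on %in% colnames(gm$calls)) {
      stop(sprintf("conditioning marker '%s' not found", condition_on))
    }
    g_top <- gm$calls[ids, condition_on]
    g_top[is.na(g_top)] <- mean(g_top, na.rm = TRUE)
    X <- cbind(X, g_top)
  }
  fit <- .polygenic_residuals(y, X, kin[ids, ids])
  calls <- gm$calls[ids, , drop = FALSE]
  res <- t(vapply(seq_len(ncol(calls)),
                  function(j) .marker_test(calls[, j], fit$residuals),
                  numeric(3)))
  out <- data.frame(marker = gm$markers$id, chrom = gm$markers$chrom,
                    bp = gm$markers$bp, n = as.integer(res[, "n"]),
                    stat = res[, "stat"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  if (!is.null(condition_on)) {
    skip <- out$marker == condition_on
    if (any(skip)) {
      out$stat[skip] <- NA_real_
      out$p[skip] <- NA_real_
      message(sprintf("marker %s is the conditioning covariate; test skipped",
                      condition_on))
    }
  }
  out$neg_log10_p <- -log10(out$p)
  peak <- out$marker[which.min(out$p)]
  out$r2_peak <- vapply(out$marker, function(m) {
    tryCatch(ld_r2(gm, m, peak), error = function(e) NA_real_)
  }, numeric(1))
  attr(out, "delta") <- fit$delta
  attr(out, "h2") <- fit$h2
  attr(out, "peak_marker") <- peak
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Conditional association scan
#'
#' Re-runs [assoc_scan()] with the genotype of the given top marker appended
#' to the covariates, to test for a second independent signal.
#'
#' @inheritParams assoc_scan
#' @param top_marker Marker id to condition on.
#' @return An `assoc_result` data frame; the conditioning marker is skipped.
#' @export
conditional_scan <- function(gm, ph, kin, top_marker,
                             covariate = "mb_at_birth") {
  assoc_scan(gm, ph, kin, covariate = covariate, condition_on = top_marker)
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %d markers; polygenic h2 ~ %.2f\n",
              nrow(x), attr(x, "h2")))
  top <- x[which.min(x$p), ]
  cat(sprintf("  peak: %s (%s:%s), p = %.3g\n", top$marker, top$chrom,
              format(top$bp, big.mark = ","), top$p))
  invisible(x)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param n_tests Number of tests (`>= 1`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-test p-value threshold `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be >= 1")
  }
  alpha / n_tests
}

#' Linkage disequilibrium between two markers
#'
#' Squared Pearson correlation of genotype codes (pairwise-complete), the
#' composite r-squared commonly reported against a peak SNP.
#'
#' @param gm A [genotype_matrix()].
#' @param marker_a,marker_b Marker ids.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(gm, marker_a, marker_b) {
  stopifnot(inherits(gm, "genotype_matrix"))
  for (m in c(marker_a, marker_b)) {
    if (!m %in% colnames(gm$calls)) stop(sprintf("marker '%s' not found", m))
  }
  a <- gm$calls[, marker_a]
  b <- gm$calls[, marker_b]
  obs <- !is.na(a) & !is.na(b)
  if (stats::var(a[obs]) == 0 || stats::var(b[obs]) == 0) {
    stop("undefined LD: monomorphic marker")
  }
  stats::cor(a[obs], b[obs])^2
}
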