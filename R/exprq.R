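#' Relative expression by the 2^-ddCt method
#'
#' Per sample and gene, dCt is the replicate-paired difference between the
#' target and reference-gene Ct; ddCt subtracts the mean dCt of the
#' calibrator group for that gene; fold change is `2^-ddCt`. The calibrator
#' cell has fold change 1 by construction, and the whole computation is
#' invariant to adding a constant to every Ct (a plate shift).
#'
#' @param ct A `ct_table` (see [simulate_ct_table()]) with columns
#'   `sample_id`, `genotype`, `tissue`, `stage`, `gene`, `replicate`, `ct`.
#' @param ref_gene Reference gene name (default `"GAPDH"`).
#' @param calibrator Named list selecting the calibrator cells, e.g.
#'   `list(genotype = "mb/mb", tissue = "dorsal", stage = "adult")`.
#' @return An object of class `rel_expression`: list with `cells` (per
#'   (gene, genotype, tissue, stage): `fold`, `sd_ddct`, `n`) and
#'   `replicates` (replicate-level ddCt values).
#' @export
delta_delta_ct <- function(ct, ref_gene = "GAPDH", calibrator) {
  stopifnot(is.data.frame(ct))
  if (!ref_gene %in% ct$gene) stop("normalization error: reference gene missing")
  ref <- ct[ct$gene == ref_gene, ]
  tgt <- ct[ct$gene != ref_gene, ]
  key <- function(d) paste(d$sample_id, d$replicate)
  ref_ct <- ref$ct[match(key(tgt), key(ref))]
  if (any(is.na(ref_ct))) {
    stop("normalization error: reference gene missing for some replicates")
  }
  tgt$dct <- tgt$ct - ref_ct

  cal <- rep(TRUE, nrow(tgt))
  for (nm in names(calibrator)) cal <- cal & tgt[[nm]] == calibrator[[nm]]
  if (!any(cal)) stop("configuration error: empty calibrator group")
  cal_mean <- tapply(tgt$dct[cal], tgt$gene[cal], mean)
  if (any(is.na(cal_mean[unique(tgt$gene)]))) {
    stop("configuration error: calibrator lacks some genes")
  }
  tgt$ddct <- tgt$dct - cal_mean[tgt$gene]
  tgt$fold <- 2^(-tgt$ddct)

  cells <- stats::aggregate(ddct ~ gene + genotype + tissue + stage,
                            data = tgt, FUN = mean)
  names(cells)[names(cells) == "ddct"] <- "mean_ddct"
  cells$sd_ddct <- stats::aggregate(ddct ~ gene + genotype + tissue + stage,
                                    data = tgt, FUN = stats::sd)$ddct
  cells$n <- stats::aggregate(ddct ~ gene + genotype + tissue + stage,
                              data = tgt, FUN = length)$ddct
  cells$fold <- 2^(-cells$mean_ddct)
  structure(list(cells = cells, replicates = tgt, ref_gene = ref_gene,
                 calibrator = calibrator),
            class = "rel_expression")
}

#' @export
print.rel_expression <- function(x, ...) {
  cat(sprintf("<rel_expression> %d genes x %d cells (reference %s)\n",
              length(unique(x$cells$gene)), nrow(x$cells), x$ref_gene))
  invisible(x)
}

.sig_tier <- function(p) {
  if (is.na(p)) NA_character_
  else if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Compare expression between two groups
#'
#' Welch t-test on the ddCt scale between two groups of replicates, with the
#' conventional significance tiers (*** p<0.001, ** p<0.01, * p<0.05).
#'
#' @param rel A [delta_delta_ct()] result.
#' @param group_a,group_b Named lists of column filters (must include enough
#'   of `gene`, `genotype`, `tissue`, `stage` to select replicates).
#' @return List with `p`, `tier`, `log2_fc` (group a minus group b on the
#'   -ddCt scale) and group sizes.
#' @export
compare_groups <- function(rel, group_a, group_b) {
  stopifnot(inherits(rel, "rel_expression"))
  pick <- function(g) {
    sel <- rep(TRUE, nrow(rel$replicates))
    for (nm in names(g)) sel <- sel & rel$replicates[[nm]] == g[[nm]]
    rel$replicates$ddct[sel]
  }
  a <- pick(group_a)
  b <- pick(group_b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("insufficient data: need >= 2 replicates per group")
  }
  if (stats::sd(a) < 1e-10 && stats::sd(b) < 1e-10) {
    ## degenerate noiseless input: identical means are no evidence, distinct
    ## means are unambiguous
    tt <- list(p.value = if (abs(mean(a) - mean(b)) < 1e-8) 1 else 0)
  } else {
    tt <- stats::t.test(a, b)
  }
  list(p = tt$p.value, tier = .sig_tier(tt$p.value),
       log2_fc = mean(b) - mean(a), n_a = length(a), n_b = length(b))
}

#' Classify a candidate gene's expression pattern
#'
#' A gene is called Mb-consistent when (a) the carrier-vs-wild-type
#' differential in facial skin is significant at every assayed embryonic
#' stage and in adults, with higher expression in carriers, and (b)
#' wild-type facial expression is below a near-zero floor relative to the
#' carrier level — the continuous-ectopic-expression pattern expected of the
#' gene that establishes the phenotype during feather development.
#'
#' @param rel A [delta_delta_ct()] result covering facial skin at the
#'   embryonic stages and adult for both genotypes.
#' @param gene Gene to classify.
#' @param carrier,wildtype Genotype labels (defaults `"Mb/Mb"`, `"mb/mb"`).
#' @param tissue Tissue in which the pattern must hold (default `"facial"`).
#' @param embryonic_stages,adult_stage Stage labels.
#' @param alpha Per-stage significance level (default 0.05).
#' @param silent_floor Maximum wild-type/carrier fold ratio for "silent"
#'   (default 0.05).
#' @return An object of class `pattern_call`: list with `gene`,
#'   `mb_consistent` and per-stage `evidence`.
#' @export
classify_candidate <- function(rel, gene, carrier = "Mb/Mb",
                               wildtype = "mb/mb", tissue = "facial",
                               embryonic_stages = c("E7.5", "E8.5", "E9.5",
                                                    "E10.5"),
                               adult_stage = "adult", alpha = 0.05,
                               silent_floor = 0.05) {
  stopifnot(inherits(rel, "rel_expression"))
  stages <- c(embryonic_stages, adult_stage)
  cells <- rel$cells
  have <- cells$gene == gene & cells$tissue == tissue &
    cells$stage %in% stages & cells$genotype %in% c(carrier, wildtype)
  if (sum(have) < 2L * length(stages)) {
    stop("coverage error: required (stage x genotype) cells missing")
  }
  evidence <- data.frame(stage = stages, p = NA_real_, tier = NA_character_,
                         carrier_higher = NA, wt_over_carrier = NA_real_,
                         stringsAsFactors = FALSE)
  for (i in seq_along(stages)) {
    cmp <- compare_groups(
      rel,
      list(gene = gene, genotype = carrier, tissue = tissue, stage = stages[i]),
      list(gene = gene, genotype = wildtype, tissue = tissue, stage = stages[i])
    )
    f_car <- cells$fold[have & cells$genotype == carrier &
                          cells$stage == stages[i]]
    f_wt <- cells$fold[have & cells$genotype == wildtype &
                         cells$stage == stages[i]]
    evidence$p[i] <- cmp$p
    evidence$tier[i] <- cmp$tier
    evidence$carrier_higher[i] <- f_car > f_wt
    evidence$wt_over_carrier[i] <- f_wt / f_car
  }
  differential <- all(evidence$p < alpha & evidence$carrier_higher)
  silent <- all(evidence$wt_over_carrier < silent_floor)
  structure(list(gene = gene, mb_consistent = differential && silent,
                 evidence = evidence),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("<pattern_call> %s: %sMb-consistent\n", x$gene,
              if (x$mb_consistent) "" else "NOT "))
  print(x$evidence, digits = 3)
  invisible(x)
}
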