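#' Genotype matrix container
#'
#' Calls are coded 0/1/2 as the count of the designated (line-H / HB) allele;
#' `NA` is missing. Rows are individuals, columns are markers.
#'
#' @param calls Integer matrix (individuals x markers) with values in
#'   `c(0, 1, 2, NA)`; dimnames give individual and marker ids.
#' @param markers Data frame with columns `id`, `chrom`, `bp` (one row per
#'   column of `calls`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, markers) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(0L, 1L, 2L, NA))) {
    stop("genotype calls must be 0, 1, 2 or NA")
  }
  stopifnot(ncol(calls) == nrow(markers),
            all(c("id", "chrom", "bp") %in% names(markers)))
  if (is.null(colnames(calls))) colnames(calls) <- markers$id
  structure(list(calls = calls, markers = markers,
                 individuals = rownames(calls)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d markers (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Haldane map function
#'
#' Recombination fraction for a map distance in centiMorgans under Haldane's
#' model (no crossover interference): `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param d_cM Map distance in cM.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Configure an F2 intercross simulation
#'
#' Models an F2 intercross between two fully inbred founder lines (labelled
#' HB and HQLA after the motivating cross) segregating a fully penetrant
#' dominant locus. Founders are fixed for alternative alleles at every
#' informative marker; meioses follow the Haldane map function with no
#' interference.
#'
#' @param n_f2 Number of F2 individuals.
#' @param marker_positions_bp,marker_positions_cM Equal-length strictly
#'   increasing vectors of marker positions.
#' @param causal_locus_bp Physical position of the causal locus.
#' @param penetrance Probability that a carrier (one or two HB-origin alleles
#'   at the causal locus) expresses the phenotype at week 10.
#' @param birth_covariate_rate Probability that an expressing bird already
#'   shows the trait at birth (the covariate used in mapping).
#' @param informativeness Per-marker probability that founder lines are fixed
#'   for alternative alleles; uninformative markers segregate identically in
#'   both lines.
#' @param n_f1_pairs Number of F1 mating pairs.
#' @param chrom Chromosome name.
#' @param n_background_chrom Number of unlinked background chromosomes
#'   (default 4) carrying neutral markers, so the genomic kinship matrix is
#'   genome-wide rather than dominated by the trait chromosome, as with a
#'   genome-wide SNP chip.
#' @param background_markers Markers per background chromosome (default 26,
#'   spaced 2 cM).
#' @param seed Integer seed.
#' @return An object of class `cross_config`.
#' @export
cross_config <- function(n_f2, marker_positions_bp, marker_positions_cM,
                         causal_locus_bp, penetrance = 1,
                         birth_covariate_rate = 0.3, informativeness = 1,
                         n_f1_pairs = 10L, chrom = "chr27",
                         n_background_chrom = 4L, background_markers = 26L,
                         seed = 1L) {
  if (length(marker_positions_bp) == 0L) stop("empty marker map")
  stopifnot(length(marker_positions_bp) == length(marker_positions_cM),
            all(diff(marker_positions_bp) > 0),
            all(diff(marker_positions_cM) >= 0),
            penetrance >= 0, penetrance <= 1,
            birth_covariate_rate >= 0, birth_covariate_rate <= 1,
            n_f2 >= 1)
  structure(list(
    n_f2 = as.integer(n_f2),
    marker_positions_bp = as.numeric(marker_positions_bp),
    marker_positions_cM = as.numeric(marker_positions_cM),
    causal_locus_bp = as.numeric(causal_locus_bp),
    penetrance = penetrance,
    birth_covariate_rate = birth_covariate_rate,
    informativeness = informativeness,
    n_f1_pairs = as.integer(n_f1_pairs),
    chrom = chrom,
    n_background_chrom = as.integer(n_background_chrom),
    background_markers = as.integer(background_markers),
    seed = as.integer(seed)
  ), class = "cross_config")
}

#' Default Mb-style cross configuration
#'
#' One chromosome of 40 cM with markers every centiMorgan (1 cM = 100 kb) and
#' the causal locus at 5 cM, emulating the published mapping design (585 F2
#' birds; linkage peak at the 5 cM grid point).
#'
#' @param n_f2 Number of F2 individuals (default 585).
#' @param ... Passed on to [cross_config()].
#' @return A [cross_config()].
#' @export
mb_cross_config <- function(n_f2 = 585L, ...) {
  cm <- 0:40
  cross_config(
    n_f2 = n_f2,
    marker_positions_bp = cm * 1e5 + 5e4,
    marker_positions_cM = cm,
    causal_locus_bp = 5 * 1e5 + 5e4,
    ...
  )
}

## one gamete from an F1 parent: origin vector ("H"/"L") over `cm` positions
.sim_gamete <- function(cm) {
  n <- length(cm)
  origin <- integer(n)
  origin[1] <- sample(0:1, 1L)
  if (n > 1L) {
    r <- haldane_r(diff(cm))
    flips <- stats::runif(n - 1L) < r
    origin <- cumsum(c(origin[1], flips)) %% 2L
  }
  c("L", "H")[origin + 1L]
}

#' Simulate an F2 intercross
#'
#' Generates the pedigree (founders, F1, F2), genotype matrix (founders and F1
#' included so trio-based QC is possible), phenotype table for the F2, the
#' genetic map, and the ground-truth line origin of every F2 haplotype at
#' every marker and at the causal locus.
#'
#' Phenotype model: an F2 expresses the trait at week 10 iff it carries at
#' least one HB-origin allele at the causal locus and a `penetrance` coin
#' succeeds; expressing birds additionally show the trait at birth with
#' probability `birth_covariate_rate` (the mapping covariate).
#'
#' @param cfg A [cross_config()].
#' @return An object of class `mb_cross`: a list with elements `pedigree`,
#'   `genotypes` ([genotype_matrix()]), `phenotypes`, `map`, `true_origin`
#'   and `config`.
#' @export
simulate_cross <- function(cfg) {
  stopifnot(inherits(cfg, "cross_config"))
  set.seed(cfg$seed)
  nm <- length(cfg$marker_positions_bp)
  marker_ids <- sprintf("M%03d", seq_len(nm))
  map <- data.frame(marker = marker_ids, chrom = cfg$chrom,
                    bp = cfg$marker_positions_bp,
                    cM = cfg$marker_positions_cM, stringsAsFactors = FALSE)
  causal_cM <- if (nm < 2L) cfg$marker_positions_cM[1] else
    stats::approx(cfg$marker_positions_bp, cfg$marker_positions_cM,
                  xout = cfg$causal_locus_bp, rule = 2)$y
  ## simulation positions = markers + causal locus
  pos_cM <- c(cfg$marker_positions_cM, causal_cM)
  ord <- order(pos_cM)
  pos_cM_sorted <- pos_cM[ord]
  causal_idx <- which(ord == nm + 1L)

  informative <- stats::runif(nm) < cfg$informativeness

  ## pedigree ----------------------------------------------------------------
  founders <- data.frame(
    id = c("HB_M", "HB_F", "HQLA_M", "HQLA_F"),
    sire = NA_character_, dam = NA_character_,
    sex = c("M", "F", "M", "F"),
    generation = "F0",
    line = c("HB", "HB", "HQLA", "HQLA"), stringsAsFactors = FALSE
  )
  n_f1 <- 2L * cfg$n_f1_pairs
  f1_ids <- sprintf("F1_%03d", seq_len(n_f1))
  f1 <- data.frame(
    id = f1_ids,
    sire = rep(c("HB_M", "HQLA_M"), length.out = n_f1),
    dam = rep(c("HQLA_F", "HB_F"), length.out = n_f1),
    sex = rep(c("M", "F"), each = cfg$n_f1_pairs),
    generation = "F1", line = NA_character_, stringsAsFactors = FALSE
  )
  f1_sires <- f1_ids[seq_len(cfg$n_f1_pairs)]
  f1_dams <- f1_ids[cfg$n_f1_pairs + seq_len(cfg$n_f1_pairs)]
  pair <- sample.int(cfg$n_f1_pairs, cfg$n_f2, replace = TRUE)
  f2_ids <- sprintf("F2_%04d", seq_len(cfg$n_f2))
  f2 <- data.frame(
    id = f2_ids, sire = f1_sires[pair], dam = f1_dams[pair],
    sex = sample(c("M", "F"), cfg$n_f2, replace = TRUE),
    generation = "F2", line = NA_character_, stringsAsFactors = FALSE
  )
  pedigree <- rbind(founders, f1, f2)

  ## gametes and genotypes ---------------------------------------------------
  pat <- matrix("", cfg$n_f2, nm + 1L)
  mat <- matrix("", cfg$n_f2, nm + 1L)
  for (i in seq_len(cfg$n_f2)) {
    pat[i, ] <- .sim_gamete(pos_cM_sorted)
    mat[i, ] <- .sim_gamete(pos_cM_sorted)
  }
  marker_cols <- setdiff(seq_len(nm + 1L), causal_idx)
  pat_mark <- pat[, marker_cols, drop = FALSE]
  mat_mark <- mat[, marker_cols, drop = FALSE]

  f2_calls <- (pat_mark == "H") + (mat_mark == "H")
  founder_calls <- rbind(HB_M = rep(2L, nm), HB_F = rep(2L, nm),
                         HQLA_M = rep(0L, nm), HQLA_F = rep(0L, nm))
  f1_calls <- matrix(1L, n_f1, nm, dimnames = list(f1_ids, NULL))
  if (any(!informative)) {
    ## uninformative markers: both lines segregate the allele at freq 0.5
    ni <- which(!informative)
    n_all <- 4L + n_f1 + cfg$n_f2
    for (j in ni) {
      g <- stats::rbinom(n_all, 2L, 0.5)
      founder_calls[, j] <- g[1:4]
      f1_calls[, j] <- g[4L + seq_len(n_f1)]
      f2_calls[, j] <- g[4L + n_f1 + seq_len(cfg$n_f2)]
    }
  }
  calls <- rbind(founder_calls, f1_calls, f2_calls)
  rownames(calls) <- pedigree$id
  colnames(calls) <- marker_ids
  markers_df <- data.frame(id = marker_ids, chrom = cfg$chrom,
                           bp = cfg$marker_positions_bp,
                           stringsAsFactors = FALSE)

  ## unlinked background chromosomes (fully informative neutral markers)
  if (cfg$n_background_chrom > 0L && cfg$background_markers > 0L) {
    cm_bg <- seq(0, by = 2, length.out = cfg$background_markers)
    for (b in seq_len(cfg$n_background_chrom)) {
      bg_ids <- sprintf("BG%d_%03d", b, seq_len(cfg$background_markers))
      bg_f2 <- matrix(0L, cfg$n_f2, cfg$background_markers)
      for (i in seq_len(cfg$n_f2)) {
        bg_f2[i, ] <- (.sim_gamete(cm_bg) == "H") + (.sim_gamete(cm_bg) == "H")
      }
      bg_calls <- rbind(
        matrix(rep(c(2L, 2L, 0L, 0L), cfg$background_markers), 4L),
        matrix(1L, n_f1, cfg$background_markers),
        bg_f2
      )
      colnames(bg_calls) <- bg_ids
      calls <- cbind(calls, bg_calls)
      markers_df <- rbind(markers_df, data.frame(
        id = bg_ids, chrom = sprintf("chrBG%d", b),
        bp = seq_len(cfg$background_markers) * 1e5,
        stringsAsFactors = FALSE))
    }
  }
  gm <- genotype_matrix(calls, markers_df)

  ## phenotype ---------------------------------------------------------------
  carrier <- pat[, causal_idx] == "H" | mat[, causal_idx] == "H"
  mb10 <- as.integer(carrier & stats::runif(cfg$n_f2) < cfg$penetrance)
  mb0 <- as.integer(mb10 == 1L & stats::runif(cfg$n_f2) < cfg$birth_covariate_rate)
  phenotypes <- data.frame(id = f2_ids, mb_week10 = mb10, mb_at_birth = mb0,
                           stringsAsFactors = FALSE)

  true_origin <- structure(list(
    individuals = f2_ids,
    marker_cM = cfg$marker_positions_cM,
    paternal = structure(pat_mark, dimnames = list(f2_ids, marker_ids)),
    maternal = structure(mat_mark, dimnames = list(f2_ids, marker_ids)),
    causal_paternal = pat[, causal_idx],
    causal_maternal = mat[, causal_idx],
    causal_cM = causal_cM
  ), class = "true_origin_tracks")

  structure(list(pedigree = pedigree, genotypes = gm, phenotypes = phenotypes,
                 map = map, true_origin = true_origin, config = cfg),
            class = "mb_cross")
}

#' @export
print.mb_cross <- function(x, ...) {
  cat(sprintf(
    "<mb_cross> %d F2 (+%d F1, 4 founders), %d markers, penetrance %.2f\n",
    x$config$n_f2, 2L * x$config$n_f1_pairs, nrow(x$map),
    x$config$penetrance))
  cat(sprintf("  %d/%d F2 express the trait at week 10\n",
              sum(x$phenotypes$mb_week10), x$config$n_f2))
  invisible(x)
}

#' Write cross tables as CSV
#'
#' Writes `<prefix>_pedigree.csv`, `<prefix>_genotypes.csv`,
#' `<prefix>_phenotypes.csv` and `<prefix>_map.csv`.
#'
#' @param cross An [simulate_cross()] result.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_cross_csv <- function(cross, prefix) {
  paths <- paste0(prefix, c("_pedigree.csv", "_genotypes.csv",
                            "_phenotypes.csv", "_map.csv"))
  utils::write.csv(cross$pedigree, paths[1], row.names = FALSE)
  gm <- data.frame(id = rownames(cross$genotypes$calls),
                   cross$genotypes$calls, check.names = FALSE)
  utils::write.csv(gm, paths[2], row.names = FALSE)
  utils::write.csv(cross$phenotypes, paths[3], row.names = FALSE)
  utils::write.csv(cross$map, paths[4], row.names = FALSE)
  invisible(paths)
}
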