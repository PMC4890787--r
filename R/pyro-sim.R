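#' Configure pyrosequencing signal simulation
#'
#' Peak heights are dosage-proportional: `signal_per_copy * copy count` plus
#' Gaussian noise truncated at zero. Units are arbitrary instrument units.
#'
#' @param signal_per_copy Signal per allele copy (default 100).
#' @param noise_sd Gaussian noise SD in the same units (default 5).
#' @param seed Integer seed.
#' @return An object of class `pyro_sim_config`.
#' @export
pyro_sim_config <- function(signal_per_copy = 100, noise_sd = 5, seed = 1L) {
  stopifnot(signal_per_copy > 0, noise_sd >= 0)
  structure(list(signal_per_copy = signal_per_copy, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "pyro_sim_config")
}

#' Simulate a pyrosequencing signal from an allele copy configuration
#'
#' @param copy_config Named numeric vector of allele copy counts at the
#'   assayed site (e.g. `c(T = 2, C = 1)` for a heterozygous Mb carrier at the
#'   diagnostic site inside the tandem-duplicated interval).
#' @param cfg A [pyro_sim_config()].
#' @return A named numeric vector of peak heights (class `pyro_signal`).
#' @export
simulate_pyro_signal <- function(copy_config, cfg = pyro_sim_config()) {
  stopifnot(inherits(cfg, "pyro_sim_config"))
  if (is.null(names(copy_config)) || any(copy_config < 0)) {
    stop("copy_config must be a named vector of non-negative copy counts")
  }
  if (sum(copy_config) == 0) stop("all-zero copy configuration")
  set.seed(cfg$seed)
  heights <- cfg$signal_per_copy * copy_config +
    stats::rnorm(length(copy_config), 0, cfg$noise_sd)
  heights <- pmax(heights, 0)
  structure(heights, class = "pyro_signal")
}

#' @export
print.pyro_signal <- function(x, ...) {
  cat("<pyro_signal>", paste(sprintf("%s=%.1f", names(x), unname(x)),
                             collapse = " "), "\n")
  invisible(x)
}

#' Synthetic seven-gene expression pattern of the duplicated region
#'
#' True relative expression (vs the wild-type adult dorsal-skin calibrator)
#' for the seven genes in the duplicated segments, across facial and dorsal
#' skin, four embryonic stages, two-week chicks and adults, for the two
#' homozygous genotypes. The pattern emulates the published qPCR panel:
#' HOXB8 is ectopically and continuously expressed in Mb facial skin and
#' essentially silent in wild-type facial skin; CCR7/SMARCE1/KRT222 differ
#' only postnatally or in adults; SMARCD2 differs mostly in dorsal skin;
#' PSMC5 and HOXB7 show no consistent differential.
#'
#' @return Data frame with columns `gene`, `genotype`, `tissue`, `stage`,
#'   `rel_expr`.
#' @export
mb_expression_panel <- function() {
  stages <- c("E7.5", "E8.5", "E9.5", "E10.5", "2wk", "adult")
  embry <- stages[1:4]
  grid <- expand.grid(gene = c("PSMC5", "SMARCD2", "HOXB8", "HOXB7",
                               "CCR7", "SMARCE1", "KRT222"),
                      genotype = c("Mb/Mb", "mb/mb"),
                      tissue = c("facial", "dorsal"),
                      stage = stages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rel <- rep(1, nrow(grid))
  mb <- grid$genotype == "Mb/Mb"
  fac <- grid$tissue == "facial"
  ## HOXB8: silent in wild-type facial skin, high in Mb facial skin always
  g <- grid$gene == "HOXB8"
  rel[g & fac & !mb] <- 0.01
  rel[g & fac & mb] <- ifelse(grid$stage[g & fac & mb] %in% embry, 8, 10)
  rel[g & !fac & mb] <- 3
  ## SMARCD2: mostly dorsal differential, two-fold in adult facial skin
  g <- grid$gene == "SMARCD2"
  rel[g & !fac & mb & grid$stage %in% embry] <- 3
  rel[g & !fac & mb & !(grid$stage %in% embry)] <- 1.5
  rel[g & fac & mb] <- 2
  ## CCR7: facial differential only at 2wk and adult
  g <- grid$gene == "CCR7"
  rel[g & fac & mb & grid$stage %in% c("2wk", "adult")] <- 4
  ## SMARCE1 / KRT222: adult facial only
  for (nm in c("SMARCE1", "KRT222")) {
    g <- grid$gene == nm
    rel[g & fac & mb & grid$stage == "adult"] <- 3
  }
  grid$rel_expr <- rel
  grid
}

#' Simulate a qPCR Ct table
#'
#' For every (gene, genotype, tissue, stage) cell of the pattern, Ct values
#' for `n_replicates` technical replicates are drawn as
#' `ref_ct + base_dct - log2(rel_expr) + noise`; the reference gene is
#' measured alongside every cell. Six replicates per cell is the published
#' design (samples run in sextuplicate, normalized to GAPDH).
#'
#' @param pattern_spec Data frame with columns `gene`, `genotype`, `tissue`,
#'   `stage`, `rel_expr` (all `rel_expr > 0`), e.g. [mb_expression_panel()].
#' @param noise_sd Gaussian Ct noise SD in cycles (default 0.15).
#' @param seed Integer seed.
#' @param n_replicates Technical replicates per cell (default 6).
#' @param ref_gene Reference gene name (default `"GAPDH"`).
#' @param ref_ct Reference-gene mean Ct.
#' @param base_dct Target-vs-reference Ct offset at relative expression 1.
#' @return A `ct_table` data frame with columns `sample_id`, `genotype`,
#'   `tissue`, `stage`, `gene`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(pattern_spec, noise_sd = 0.15, seed = 1L,
                              n_replicates = 6L, ref_gene = "GAPDH",
                              ref_ct = 20, base_dct = 5) {
  stopifnot(all(c("gene", "genotype", "tissue", "stage", "rel_expr") %in%
                  names(pattern_spec)))
  if (any(pattern_spec$rel_expr <= 0)) {
    stop("relative expression must be positive (use a small value for silent)")
  }
  set.seed(seed)
  cells <- unique(pattern_spec[c("genotype", "tissue", "stage")])
  rows <- vector("list", nrow(cells) * 2L)
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sid <- paste(cell$genotype, cell$tissue, cell$stage, sep = "_")
    sub <- pattern_spec[pattern_spec$genotype == cell$genotype &
                          pattern_spec$tissue == cell$tissue &
                          pattern_spec$stage == cell$stage, ]
    ## reference gene for this sample
    k <- k + 1L
    rows[[k]] <- data.frame(
      sample_id = sid, genotype = cell$genotype, tissue = cell$tissue,
      stage = cell$stage, gene = ref_gene, replicate = seq_len(n_replicates),
      ct = ref_ct + stats::rnorm(n_replicates, 0, noise_sd),
      stringsAsFactors = FALSE
    )
    k <- k + 1L
    rows[[k]] <- data.frame(
      sample_id = sid, genotype = cell$genotype, tissue = cell$tissue,
      stage = cell$stage,
      gene = rep(sub$gene, each = n_replicates),
      replicate = rep(seq_len(n_replicates), nrow(sub)),
      ct = ref_ct + base_dct - rep(log2(sub$rel_expr), each = n_replicates) +
        stats::rnorm(n_replicates * nrow(sub), 0, noise_sd),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (any(out$ct <= 0)) out$ct <- pmax(out$ct, 1e-6)
  class(out) <- c("ct_table", "data.frame")
  out
}
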