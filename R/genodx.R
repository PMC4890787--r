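#' Discover copy-specific variants between duplicated copies
#'
#' Sites where the aligned per-copy consensus sequences carry different
#' alleles AND the copy-specific allele is absent from every haplotype of a
#' wild-type panel — the screen that identifies a diagnostic site able to
#' distinguish carrier genotypes.
#'
#' @param copy_seqs Named list of per-copy consensus sequences over the
#'   duplicated interval (equal length, aligned).
#' @param panel_seqs List of panel (wild-type) haplotype sequences over the
#'   same interval.
#' @param interval_start Reference coordinate of the first aligned base
#'   (default 1), used to report positions.
#' @return Data frame (`position`, `ref_allele`, `alt_allele`,
#'   `carrying_copy`), sorted by position; zero rows when no site qualifies.
#' @export
find_copy_specific_variants <- function(copy_seqs, panel_seqs,
                                        interval_start = 1) {
  lens <- vapply(copy_seqs, nchar, numeric(1))
  if (length(unique(lens)) != 1L) {
    stop("coordinate error: copy sequences differ in length")
  }
  n <- lens[1]
  if (any(vapply(panel_seqs, nchar, numeric(1)) != n)) {
    stop("coordinate error: panel sequences do not match the copies")
  }
  cp <- do.call(rbind, lapply(copy_seqs,
                              function(s) strsplit(s, "")[[1]]))
  pn <- do.call(rbind, lapply(panel_seqs,
                              function(s) strsplit(s, "")[[1]]))
  out <- list()
  for (j in seq_len(n)) {
    al <- cp[, j]
    if (length(unique(al)) == 1L) next
    for (copy in seq_along(al)) {
      a <- al[copy]
      if (sum(al == a) != 1L) next        # allele must be unique to one copy
      if (a %in% pn[, j]) next            # present in the wild-type panel
      out[[length(out) + 1L]] <- data.frame(
        position = interval_start + j - 1,
        ref_allele = al[setdiff(seq_along(al), copy)][1],
        alt_allele = a,
        carrying_copy = names(copy_seqs)[copy] %||% as.character(copy),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(position = numeric(0), ref_allele = character(0),
               alt_allele = character(0), carrying_copy = character(0),
               stringsAsFactors = FALSE)
  res[order(res$position), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Allele-dosage model for a site inside the tandem-duplicated interval
#'
#' Copy counts of each allele at the diagnostic site per genotype class. The
#' default is the Mb model at the T-to-C diagnostic site: a wild-type
#' chromosome carries one T copy, a carrier chromosome carries one T copy
#' (original) plus one C copy (duplicate), so total copies are
#' 2 + (number of carrier alleles).
#'
#' @param classes Named list of named copy-count vectors.
#' @return An object of class `dosage_model`.
#' @export
dosage_model <- function(classes) {
  for (cc in classes) {
    if (any(cc < 0) || sum(cc) == 0) stop("invalid copy configuration")
  }
  structure(list(classes = classes), class = "dosage_model")
}

#' @rdname dosage_model
#' @export
mb_dosage_model <- function() {
  dosage_model(list(
    "mb/mb" = c(T = 2, C = 0),
    "Mb/mb" = c(T = 2, C = 1),
    "Mb/Mb" = c(T = 2, C = 2)
  ))
}

#' @export
print.dosage_model <- function(x, ...) {
  cat("<dosage_model>\n")
  for (nm in names(x$classes)) {
    cat(sprintf("  %-6s: %s\n", nm,
                paste(sprintf("%s=%g", names(x$classes[[nm]]),
                              x$classes[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Expected allele ratio for a genotype class
#'
#' @param genotype_class Class name present in the dosage model.
#' @param dm A [dosage_model()] (default [mb_dosage_model()]).
#' @return Ratio of the first allele's copies to the second's; `Inf` with a
#'   `"T only"`-style label attribute when the denominator is zero.
#' @export
expected_allele_ratio <- function(genotype_class, dm = mb_dosage_model()) {
  if (!genotype_class %in% names(dm$classes)) {
    stop(sprintf("unknown genotype class '%s'", genotype_class))
  }
  cc <- dm$classes[[genotype_class]]
  ratio <- cc[1] / cc[2]
  if (cc[2] == 0) {
    attr(ratio, "label") <- sprintf("%s only", names(cc)[1])
  }
  ratio
}

#' Call a genotype from pyrosequencing peak heights
#'
#' For every genotype class, a Pearson chi-squared goodness-of-fit test of
#' the observed peak heights (rescaled to `effective_count` pseudo-counts)
#' against the class's expected allele proportions. A class expecting zero
#' signal for an allele is rejected when that allele's observed share of
#' total signal exceeds `zero_tol`; its remaining cells are tested as usual.
#' Classes with `p > alpha` survive; a unique survivor is the call, otherwise
#' the result is ambiguous (never forced). The call is invariant to scaling
#' all peak heights by a constant.
#'
#' @param sig Named numeric peak heights (e.g. from
#'   [simulate_pyro_signal()]).
#' @param dm A [dosage_model()].
#' @param alpha Rejection level (default 0.05).
#' @param effective_count Pseudo-count total for the chi-squared test
#'   (default 100).
#' @param zero_tol Maximum observed signal share for an allele expected at
#'   zero copies (default 0.10).
#' @return An object of class `genotype_call`: list with `class` (a model
#'   class name or `"ambiguous"`) and `p_values` per hypothesis.
#' @export
call_genotype_pyro <- function(sig, dm = mb_dosage_model(), alpha = 0.05,
                               effective_count = 100, zero_tol = 0.10) {
  tot <- sum(sig)
  if (tot <= 0) stop("zero total signal")
  p_values <- vapply(names(dm$classes), function(nm) {
    cc <- dm$classes[[nm]][names(sig)]
    if (any(is.na(cc))) return(0)
    zero <- cc == 0
    if (any(zero) && any(sig[zero] / tot > zero_tol)) return(0)
    obs <- sig[!zero] / sum(sig[!zero]) * effective_count
    expd <- cc[!zero] / sum(cc[!zero])
    if (length(obs) < 2L) return(1)
    unname(suppressWarnings(
      stats::chisq.test(obs, p = expd)$p.value))
  }, numeric(1))
  surv <- names(p_values)[p_values > alpha]
  structure(list(
    class = if (length(surv) == 1L) surv else "ambiguous",
    p_values = p_values
  ), class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s  (%s)\n", x$class,
              paste(sprintf("%s p=%.3g", names(x$p_values), x$p_values),
                    collapse = ", ")))
  invisible(x)
}

#' In-silico diagnostic PCR
#'
#' Exact-match primer binding: products are reported wherever the forward
#' primer matches the plus strand and the reverse complement of the reverse
#' primer matches downstream within `max_product` bases.
#'
#' @param primer_fwd,primer_rev Primer sequences (>= 15 nt, A/C/G/T).
#' @param genome A [toy_genome()].
#' @param max_product Maximum product length (default 10000).
#' @return Data frame (`start`, `end`, `length`), one row per product.
#' @export
insilico_pcr <- function(primer_fwd, primer_rev, genome, max_product = 10000) {
  for (p in c(primer_fwd, primer_rev)) {
    if (grepl("[^ACGTacgt]", p)) stop("primer contains non-ACGT characters")
    if (nchar(p) < 15L) stop("primers must be >= 15 nt")
  }
  subject <- Biostrings::DNAString(genome$sequence)
  f <- Biostrings::start(Biostrings::matchPattern(toupper(primer_fwd), subject))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(primer_rev))))
  r <- Biostrings::start(Biostrings::matchPattern(rc, subject))
  r_end <- r + nchar(primer_rev) - 1L
  out <- list()
  for (fs in f) {
    ok <- r_end > fs & (r_end - fs + 1L) <= max_product & r > fs
    for (re in r_end[ok]) {
      out[[length(out) + 1L]] <- data.frame(start = fs, end = re,
                                            length = re - fs + 1L)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      length = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Cross-tabulate diagnostic calls against phenotypes
#'
#' @param calls Data frame with `id` and `result` (e.g. genotype class or
#'   PCR positivity).
#' @param phenotypes Data frame with `id` and `phenotype`.
#' @return An object of class `concordance_table`: the contingency table with
#'   attribute `perfect` (TRUE when every result maps to a single phenotype,
#'   i.e. all off-diagonal cells of the best assignment are zero).
#' @export
cohort_concordance <- function(calls, phenotypes) {
  if (!all(calls$id %in% phenotypes$id)) {
    stop("join error: calls contain ids absent from the phenotype table")
  }
  ph <- phenotypes$phenotype[match(calls$id, phenotypes$id)]
  tab <- table(result = calls$result, phenotype = ph)
  perfect <- all(apply(tab, 1, function(row) sum(row > 0) <= 1L))
  structure(tab, perfect = perfect, class = c("concordance_table", class(tab)))
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("<concordance_table>", if (attr(x, "perfect")) "(complete association)\n"
      else "(discordant entries present)\n")
  print(unclass(x))
  invisible(x)
}
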