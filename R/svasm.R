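## longest common prefix length of two strings
.lcp <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(0L)
  xr <- charToRaw(substr(x, 1L, n))
  yr <- charToRaw(substr(y, 1L, n))
  d <- which(xr != yr)
  if (length(d) == 0L) n else d[1] - 1L
}

.rev_str <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Detect breakpoint junctions from reads
#'
#' Seed-and-extend split alignment against the reference: for every read that
#' does not align contiguously, the maximal exact prefix and suffix matches
#' are found (anchors of at least `min_anchor` bases, forward orientation
#' only); reads whose prefix and suffix map to discordant loci vote for a
#' non-reference adjacency. Votes are clustered within +-2 bp and reported
#' with consensus coordinates, microhomology/insertion classification, and
#' read support; clusters below `min_support` are dropped.
#'
#' Reported coordinates use the maximal-prefix convention: `left_end` is the
#' last reference base of the maximal left extension and `right_start` the
#' first reference base of the maximal right extension, so a junction with
#' microhomology `h` satisfies `derived = ref[..left_end] + ref[right_start + h..]`.
#'
#' @param reads Character vector / `DNAStringSet` of reads, or a FASTQ path.
#' @param ref A [toy_genome()] (use the homology-edited reference attached to
#'   [build_derived_haplotype()] output when detecting simulated junctions).
#' @param min_anchor Minimum exact anchor length (default 20).
#' @param min_support Minimum reads per reported junction (default 2).
#' @return A `breakpoint_junctions` data frame (`left_end`, `right_start`,
#'   `homology_len`, `inserted_seq`, `support`), sorted by `left_end`.
#' @export
detect_junctions <- function(reads, ref, min_anchor = 20L, min_support = 2L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_reads_fastq(reads)
  }
  reads <- as.character(reads)
  refchar <- if (inherits(ref, "toy_genome")) ref$sequence else as.character(ref)
  if (nchar(refchar) < min_anchor) {
    stop("reference shorter than min_anchor")
  }
  empty <- data.frame(left_end = numeric(0), right_start = numeric(0),
                      homology_len = integer(0), inserted_seq = character(0),
                      support = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("breakpoint_junctions", "data.frame")
  reads <- reads[nchar(reads) >= 2L * min_anchor]
  if (length(reads) == 0L) return(empty)

  refdna <- Biostrings::DNAString(refchar)
  widths <- nchar(reads)
  if (length(unique(widths)) == 1L) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads))
    conc <- Biostrings::countPDict(pd, refdna) > 0L
  } else {
    conc <- vapply(reads, function(r) {
      Biostrings::countPattern(r, refdna) > 0L
    }, logical(1), USE.NAMES = FALSE)
  }
  cand <- reads[!conc]
  if (length(cand) == 0L) return(empty)

  refrev <- .rev_str(refchar)
  nref <- nchar(refchar)
  votes <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    r <- cand[i]
    n <- nchar(r)
    ## maximal prefix extension
    hits <- Biostrings::start(Biostrings::matchPattern(
      substr(r, 1L, min_anchor), refdna))
    if (length(hits) == 0L) next
    exts <- vapply(hits, function(s) {
      min_anchor + .lcp(substring(r, min_anchor + 1L),
                        substring(refchar, s + min_anchor))
    }, numeric(1))
    a <- max(exts)
    s0 <- hits[which.max(exts)]  # which.max -> first (smallest) on ties
    left_end <- s0 + a - 1
    if (a >= n) next  # contiguous after all
    ## maximal suffix extension
    hits2 <- Biostrings::start(Biostrings::matchPattern(
      substr(r, n - min_anchor + 1L, n), refdna))
    if (length(hits2) == 0L) next
    rrev <- .rev_str(substr(r, 1L, n - min_anchor))
    exts2 <- vapply(hits2, function(t) {
      min_anchor + .lcp(rrev, substring(refrev, nref - t + 2L))
    }, numeric(1))
    s_len <- max(exts2)
    t0 <- hits2[which.max(exts2)]
    right_start <- t0 - (s_len - min_anchor)
    if (s_len >= n) next
    h <- max(0, a + s_len - n)
    ins <- if (a + s_len < n) substr(r, a + 1L, n - s_len) else ""
    if (ins == "" && right_start + h == left_end + 1) next  # reference-contiguous
    votes[[i]] <- data.frame(left_end = left_end, right_start = right_start,
                             h = h, ins = ins, stringsAsFactors = FALSE)
  }
  votes <- do.call(rbind, votes[!vapply(votes, is.null, logical(1))])
  if (is.null(votes) || nrow(votes) == 0L) return(empty)

  ## cluster votes within +-2 bp on both coordinates
  votes <- votes[order(votes$left_end, votes$right_start), , drop = FALSE]
  cl <- integer(nrow(votes))
  anchors <- list()
  for (i in seq_len(nrow(votes))) {
    assigned <- FALSE
    for (k in seq_along(anchors)) {
      if (abs(votes$left_end[i] - anchors[[k]][1]) <= 2 &&
          abs(votes$right_start[i] - anchors[[k]][2]) <= 2) {
        cl[i] <- k; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      anchors[[length(anchors) + 1L]] <- c(votes$left_end[i],
                                           votes$right_start[i])
      cl[i] <- length(anchors)
    }
  }
  out <- do.call(rbind, lapply(split(votes, cl), function(v) {
    key <- paste(v$left_end, v$right_start)
    tab <- sort(table(key), decreasing = TRUE)
    modal <- names(tab)[1]  # ties: table is sorted by key first -> smaller
    vm <- v[key == modal, , drop = FALSE]
    data.frame(left_end = vm$left_end[1], right_start = vm$right_start[1],
               homology_len = as.integer(names(sort(table(vm$h),
                                                    decreasing = TRUE))[1]),
               inserted_seq = names(sort(table(vm$ins), decreasing = TRUE))[1],
               support = nrow(v), stringsAsFactors = FALSE)
  }))
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$left_end, out$right_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("breakpoint_junctions", "data.frame")
  out
}

#' @export
print.breakpoint_junctions <- function(x, ...) {
  cat(sprintf("<breakpoint_junctions> %d junction(s)\n", nrow(x)))
  for (i in seq_len(nrow(x))) {
    desc <- if (x$homology_len[i] > 0) {
      sprintf("%d-nt microhomology", x$homology_len[i])
    } else if (nzchar(x$inserted_seq[i])) {
      sprintf("%d-nt insertion (%s)", nchar(x$inserted_seq[i]),
              x$inserted_seq[i])
    } else "blunt"
    cat(sprintf("  %s -> %s  %s  (support %d)\n",
                format(x$left_end[i], big.mark = ","),
                format(x$right_start[i], big.mark = ","), desc, x$support[i]))
  }
  invisible(x)
}

#' Classify a junction as microhomology, insertion or blunt
#'
#' Operational definition: the homology length is the maximal block
#' assignable to both the left segment's end and the right segment's start in
#' the junction consensus; bases matching neither flank are an untemplated
#' insertion. At most one of the two is nonzero; both zero is a blunt join.
#'
#' @param left_flank Reference sequence ending exactly at the junction's left
#'   breakpoint.
#' @param right_flank Reference sequence starting exactly at the junction's
#'   right breakpoint.
#' @param junction_consensus Sequence spanning the junction with at least
#'   `min_anchor` bases on each side.
#' @param min_anchor Minimum bases the consensus must share with each flank.
#' @return List with `homology_len` and `inserted_seq`.
#' @export
classify_junction <- function(left_flank, right_flank, junction_consensus,
                              min_anchor = 20L) {
  nc <- nchar(junction_consensus)
  nl <- nchar(left_flank)
  nr <- nchar(right_flank)
  a <- 0L
  for (m in seq(min(nc, nl), 0L)) {
    if (m == 0L) break
    if (substr(junction_consensus, 1L, m) == substr(left_flank, nl - m + 1L, nl)) {
      a <- m; break
    }
  }
  s <- 0L
  for (m in seq(min(nc, nr), 0L)) {
    if (m == 0L) break
    if (substr(junction_consensus, nc - m + 1L, nc) == substr(right_flank, 1L, m)) {
      s <- m; break
    }
  }
  if (a < min_anchor || s < min_anchor) {
    stop("classification error: consensus inconsistent with the flanks")
  }
  list(homology_len = max(0L, a + s - nc),
       inserted_seq = if (a + s < nc) {
         substr(junction_consensus, a + 1L, nc - s)
       } else "")
}

## ---------------------------------------------------------------------------
## derived-allele assembly

#' Assemble the derived allele from junctions and CNV calls
#'
#' Builds a directed adjacency graph whose nodes are segment copies (copy
#' counts derived from the CNV-call fold changes, `round(2^log2FC)` per
#' haplotype) and backbone pieces, with reference adjacencies plus the
#' detected junctions as edges, and enumerates every chromosome walk that
#' starts and ends on the reference backbone and consumes every copy. CNV
#' boundaries (window resolution) are refined to the base-precise junction
#' coordinates when within `boundary_tol`. A junction coordinate interior to
#' a backbone piece splits that piece (the cassette was inserted there).
#'
#' The junction set plus copy counts can admit more than one consistent walk
#' (circularly permuted cassette placements); `insertion_locus_hint` — the
#' approximate reference coordinate of the insertion — selects among them.
#' With no hint and several walks, all are returned as an ambiguity result.
#'
#' @param junctions A `breakpoint_junctions` data frame.
#' @param cnv_calls A `cnv_calls` data frame (gains in the carrier pool); a
#'   `copies` column overrides the fold-change-derived copy number.
#' @param insertion_locus_hint Optional reference coordinate near the
#'   cassette insertion site.
#' @param boundary_tol Tolerance for matching junction coordinates to CNV
#'   boundaries and to the hint (default 1000, one depth window).
#' @param max_walks Safety cap on enumeration.
#' @return A `derived_allele_model` (list with `walk`, `edges`, `cassette`,
#'   `insertion_locus`, `segments`), or an `allele_assembly_ambiguity`
#'   holding every consistent model.
#' @export
assemble_allele <- function(junctions, cnv_calls, insertion_locus_hint = NULL,
                            boundary_tol = 1000, max_walks = 1000L) {
  if (nrow(cnv_calls) == 0L) stop("no CNV calls: nothing to assemble")
  segs <- cnv_calls[order(cnv_calls$start), , drop = FALSE]
  segs$name <- sprintf("CNV%d", seq_len(nrow(segs)))
  segs$copies <- if ("copies" %in% names(segs)) segs$copies else
    pmax(2L, round(2^segs$mean_log2fc))
  if ("direction" %in% names(segs) && any(segs$direction != "gain_a")) {
    stop("only forward-orientation gains in the carrier pool are assembled")
  }

  ## refine segment boundaries to junction coordinates
  for (i in seq_len(nrow(segs))) {
    jl <- junctions$left_end[abs(junctions$left_end - segs$end[i]) <= boundary_tol]
    if (length(jl)) segs$end[i] <- jl[1]
    jr <- junctions$right_start[abs(junctions$right_start - segs$start[i]) <= boundary_tol]
    if (length(jr)) segs$start[i] <- jr[1]
  }

  ## backbone pieces between/around segments, split at interior junction coords
  chrom_end <- max(c(segs$end, junctions$left_end, junctions$right_start)) + boundary_tol
  bounds <- sort(unique(c(0, segs$start - 1, segs$end, chrom_end)))
  cuts <- numeric(0)
  for (i in seq_len(nrow(junctions))) {
    le <- junctions$left_end[i]; rs <- junctions$right_start[i]
    if (!any(abs(le - segs$end) <= 2)) cuts <- c(cuts, le)
    if (!any(abs(rs - segs$start) <= 2)) cuts <- c(cuts, rs - 1)
  }
  bounds <- sort(unique(c(bounds, cuts)))
  pieces <- data.frame(start = utils::head(bounds, -1) + 1,
                       end = bounds[-1])
  in_seg <- vapply(seq_len(nrow(pieces)), function(i) {
    any(segs$start <= pieces$start[i] & segs$end >= pieces$end[i])
  }, logical(1))
  back <- pieces[!in_seg, , drop = FALSE]
  back$name <- sprintf("B%d", seq_len(nrow(back)) - 1L)

  nodes <- rbind(
    data.frame(name = back$name, start = back$start, end = back$end,
               kind = "backbone", mult = 1L, stringsAsFactors = FALSE),
    data.frame(name = segs$name, start = segs$start, end = segs$end,
               kind = "segment", mult = segs$copies, stringsAsFactors = FALSE)
  )
  nodes <- nodes[order(nodes$start), , drop = FALSE]
  rownames(nodes) <- NULL

  ## edges: reference adjacencies + junctions
  edges <- list()
  add_edge <- function(from, to, type, h = 0L, ins = "") {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, type = type, homology_len = h, inserted_seq = ins,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(nodes) - 1L)) {
    if (nodes$end[i] + 1 == nodes$start[i + 1L]) {
      add_edge(nodes$name[i], nodes$name[i + 1L], "reference")
    }
  }
  for (i in seq_len(nrow(junctions))) {
    le <- junctions$left_end[i]; rs <- junctions$right_start[i]
    from <- nodes$name[abs(nodes$end - le) <= 2]
    to <- nodes$name[abs(nodes$start - rs) <= 2]
    if (length(from) == 0L || length(to) == 0L) {
      stop(sprintf("junction %s->%s matches no segment or backbone boundary",
                   le, rs))
    }
    add_edge(from[1], to[1], "junction",
             junctions$homology_len[i], junctions$inserted_seq[i])
  }
  edges <- do.call(rbind, edges)

  ## enumerate walks from the first to the last backbone piece
  start_node <- back$name[1]
  end_node <- back$name[nrow(back)]
  mult0 <- stats::setNames(nodes$mult, nodes$name)
  walks <- list()
  recurse <- function(path, eidx, mult) {
    if (length(walks) >= max_walks) return()
    cur <- path[length(path)]
    if (cur == end_node && all(mult == 0L)) {
      walks[[length(walks) + 1L]] <<- list(path = path, edges = eidx)
      return()
    }
    out_e <- which(edges$from == cur)
    for (e in out_e) {
      nxt <- edges$to[e]
      if (mult[nxt] > 0L) {
        m2 <- mult; m2[nxt] <- m2[nxt] - 1L
        recurse(c(path, nxt), c(eidx, e), m2)
      }
    }
  }
  m0 <- mult0; m0[start_node] <- m0[start_node] - 1L
  recurse(start_node, integer(0), m0)
  if (length(walks) == 0L) {
    stop("assembly infeasible: no walk consistent with the copy counts")
  }

  mk_model <- function(w) {
    walk <- nodes[match(w$path, nodes$name), c("name", "start", "end", "kind")]
    rownames(walk) <- NULL
    walk$copy <- stats::ave(seq_len(nrow(walk)), walk$name, FUN = seq_along)
    e <- edges[w$edges, , drop = FALSE]
    rownames(e) <- NULL
    ## role: original if flanked by reference edges on both sides
    walk$role <- NA_character_
    for (i in which(walk$kind == "segment")) {
      lt <- if (i > 1L) e$type[i - 1L] else "reference"
      rt <- if (i <= nrow(e)) e$type[i] else "reference"
      walk$role[i] <- if (lt == "reference" && rt == "reference") "original"
      else if (lt == "junction" && rt == "junction") "duplicate"
      else NA_character_
    }
    jpos <- which(e$type == "junction")
    insertion_locus <- if (length(jpos)) walk$end[jpos[1]] else NA_real_
    cassette <- if (length(jpos)) {
      span <- seq(jpos[1], jpos[length(jpos)] + 1L)
      walk$name[span][walk$kind[span] == "segment"]
    } else character(0)
    structure(list(walk = walk, edges = e, segments = segs,
                   cassette = cassette, insertion_locus = insertion_locus),
              class = "derived_allele_model")
  }
  models <- lapply(walks, mk_model)
  ## duplication-only events leave the backbone intact: walks that visit
  ## backbone pieces out of genomic order imply a backbone rearrangement and
  ## are discarded
  intact <- vapply(models, function(m) {
    !is.unsorted(m$walk$start[m$walk$kind == "backbone"])
  }, logical(1))
  if (!any(intact)) {
    stop("assembly infeasible: every walk rearranges the backbone")
  }
  models <- models[intact]
  if (!is.null(insertion_locus_hint)) {
    keep <- vapply(models, function(m) {
      !is.na(m$insertion_locus) &&
        abs(m$insertion_locus - insertion_locus_hint) <= boundary_tol
    }, logical(1))
    if (any(keep)) models <- models[keep]
  }
  ## deduplicate identical walks
  sig <- vapply(models, function(m) paste(m$walk$name, collapse = ">"),
                character(1))
  models <- models[!duplicated(sig)]
  if (length(models) == 1L) return(models[[1]])
  structure(models, class = "allele_assembly_ambiguity")
}

#' Segment-copy order through the cassette region
#'
#' @param model A `derived_allele_model`.
#' @return Character vector of segment names in derived-haplotype order
#'   across the rearranged region (e.g. `c("CNV1","CNV3","CNV2","CNV1")`).
#' @export
cassette_order <- function(model) {
  stopifnot(inherits(model, "derived_allele_model"))
  jpos <- which(model$edges$type == "junction")
  if (length(jpos) == 0L) return(character(0))
  span <- seq(jpos[1], jpos[length(jpos)] + 1L)
  lbl <- model$walk$name[span]
  lbl[model$walk$kind[span] == "segment"]
}

#' @export
print.derived_allele_model <- function(x, ...) {
  cat("<derived_allele_model>\n")
  cat(" ", allele_diagram(x), "\n")
  for (i in which(x$edges$type == "junction")) {
    j <- x$edges[i, ]
    desc <- if (j$homology_len > 0) sprintf("%d-nt microhomology", j$homology_len)
    else if (nzchar(j$inserted_seq)) sprintf("%d-nt insertion", nchar(j$inserted_seq))
    else "blunt"
    cat(sprintf("  junction %s -> %s: %s\n", j$from, j$to, desc))
  }
  invisible(x)
}

#' @export
print.allele_assembly_ambiguity <- function(x, ...) {
  cat(sprintf("<allele_assembly_ambiguity> %d consistent walks:\n", length(x)))
  for (m in x) cat(" ", allele_diagram(m), "\n")
  invisible(x)
}

#' Human-readable diagram of a derived-allele model
#'
#' @param model A `derived_allele_model`.
#' @return A single character string, e.g.
#'   `"B0 = CNV1 ~ CNV3 ~ CNV2 ~ CNV1 = B1 = CNV2 = B2 = CNV3 = B3"`
#'   (`=` reference adjacency, `~` novel junction).
#' @export
allele_diagram <- function(model) {
  sep <- ifelse(model$edges$type == "junction", "~", "=")
  lbl <- model$walk$name
  out <- lbl[1]
  for (i in seq_along(sep)) out <- paste(out, sep[i], lbl[i + 1L])
  out
}

#' Resolve which copy of a tandem-flanked duplication is the original
#'
#' Uses a recombinant individual: given a copy-specific variant inside an
#' interval present in two copies on the derived haplotype, every assignment
#' of the variant allele to a copy is combined with every recombination
#' hypothesis (which side of the crossover carries the variant haplotype, and
#' which copy the crossover fell in); each combination predicts the
#' recombinant's phenotype (does the recombinant chromosome retain any novel
#' junction?) and its genotype at the site. The unique assignment consistent
#' with the observed phenotype and genotype fixes the original/duplicate
#' flags: the copy carrying the panel-absent allele is the new copy.
#'
#' @param model A `derived_allele_model` with exactly two copies of the
#'   interval containing the variant.
#' @param evidence List with `phenotype` (`"Mb"` or `"non-Mb"`), `genotype`
#'   (character vector of observed alleles at the site) and `breakpoint_bp`
#'   (inferred crossover position, inside the duplicated interval).
#' @param copy_specific_variant List with `position`, `ref_allele`,
#'   `alt_allele`.
#' @return The model with `role` flags set on the two copies and attribute
#'   `resolution` describing the consistent hypothesis; if the evidence is
#'   uninformative the model is returned with attribute
#'   `resolution = "unresolved"`.
#' @export
resolve_copy_order <- function(model, evidence, copy_specific_variant) {
  stopifnot(inherits(model, "derived_allele_model"))
  v <- copy_specific_variant
  walk <- model$walk
  tgt <- which(walk$kind == "segment" & walk$start <= v$position &
                 walk$end >= v$position)
  if (length(tgt) != 2L) {
    stop("model must carry exactly two copies of the interval containing the variant")
  }
  if (!v$alt_allele %in% evidence$genotype) {
    message("evidence individual carries no copy of the variant allele; unresolved")
    attr(model, "resolution") <- "unresolved"
    return(model)
  }
  if (evidence$breakpoint_bp < walk$start[tgt[1]] ||
      evidence$breakpoint_bp > walk$end[tgt[1]]) {
    stop("breakpoint must lie within the duplicated interval")
  }
  site_off <- v$position - walk$start[tgt[1]]
  bk_off <- evidence$breakpoint_bp - walk$start[tgt[1]]
  is_mb <- identical(evidence$phenotype, "Mb") || identical(evidence$phenotype, 1L)
  junction_edge <- model$edges$type == "junction"

  consistent <- list()
  for (alt_on in c(1L, 2L)) {        # copy index (prox = 1, dist = 2) with alt
    for (side in c("left", "right")) {  # side of crossover from variant haplotype
      for (bk in c(1L, 2L)) {        # copy in which the crossover fell
        occ <- tgt[bk]
        if (side == "left") {
          kept_full <- seq_len(occ - 1L)
          phen <- any(junction_edge[seq_len(occ - 1L)])
          alt_carried <- (alt_on != bk && tgt[alt_on] %in% kept_full) ||
            (site_off <= bk_off && alt_on == bk)
        } else {
          kept_full <- if (occ < nrow(walk)) seq(occ + 1L, nrow(walk)) else integer(0)
          phen <- any(junction_edge[seq(occ, length(junction_edge))])
          alt_carried <- (alt_on != bk && tgt[alt_on] %in% kept_full) ||
            (site_off > bk_off && alt_on == bk)
        }
        if (phen == is_mb && alt_carried) {
          consistent[[length(consistent) + 1L]] <-
            list(alt_on = alt_on, side = side, bk = bk)
        }
      }
    }
  }
  if (length(consistent) == 0L) {
    stop("evidence-contradiction: no assignment explains phenotype and genotype")
  }
  alts <- unique(vapply(consistent, `[[`, integer(1), "alt_on"))
  if (length(alts) > 1L) {
    attr(model, "resolution") <- "unresolved"
    message("both copy assignments remain consistent; unresolved")
    return(model)
  }
  dup <- tgt[alts]
  orig <- tgt[setdiff(c(1L, 2L), alts)]
  model$walk$role[dup] <- "duplicate"
  model$walk$role[orig] <- "original"
  attr(model, "resolution") <- list(
    duplicate_copy = unname(alts), original_copy = setdiff(c(1L, 2L), alts),
    hypotheses = consistent)
  model
}

## ---------------------------------------------------------------------------
## output writers

#' Write junctions as a BEDPE-like TSV
#'
#' @param junctions A `breakpoint_junctions` data frame.
#' @param path Output file.
#' @param chrom Chromosome name.
#' @return `path`, invisibly.
#' @export
write_junctions_tsv <- function(junctions, path, chrom = "chrT") {
  df <- data.frame(
    chrom1 = chrom, start1 = junctions$left_end - 1L, end1 = junctions$left_end,
    chrom2 = chrom, start2 = junctions$right_start - 1L,
    end2 = junctions$right_start,
    name = sprintf("junction_%d", seq_len(nrow(junctions))),
    support = junctions$support, homology_len = junctions$homology_len,
    inserted_seq = ifelse(nzchar(junctions$inserted_seq),
                          junctions$inserted_seq, "."),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write junctions as minimal VCF breakend records
#'
#' @inheritParams write_junctions_tsv
#' @param ref A [toy_genome()] supplying REF bases.
#' @return `path`, invisibly.
#' @export
write_junctions_vcf <- function(junctions, path, ref, chrom = "chrT") {
  refchar <- if (inherits(ref, "toy_genome")) ref$sequence else as.character(ref)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=BND,Description=\"Breakend\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
    "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Microhomology length\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Inserted sequence\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Read support\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  for (i in seq_len(nrow(junctions))) {
    le <- junctions$left_end[i]; rs <- junctions$right_start[i]
    ins <- junctions$inserted_seq[i]
    b1 <- substr(refchar, le, le)
    b2 <- substr(refchar, rs, rs)
    info <- sprintf("SVTYPE=BND;HOMLEN=%d;SUPPORT=%d%s",
                    junctions$homology_len[i], junctions$support[i],
                    if (nzchar(ins)) paste0(";INSSEQ=", ins) else "")
    writeLines(sprintf("%s\t%d\tbnd_%d_a\t%s\t%s[%s:%d[\t.\tPASS\t%s;MATEID=bnd_%d_b",
                       chrom, le, i, b1, paste0(b1, ins), chrom, rs, info, i), con)
    writeLines(sprintf("%s\t%d\tbnd_%d_b\t%s\t]%s:%d]%s\t.\tPASS\t%s;MATEID=bnd_%d_a",
                       chrom, rs, i, b2, chrom, le, paste0(ins, b2), info, i), con)
  }
  invisible(path)
}

#' Export a derived-allele model as JSON
#'
#' @param model A `derived_allele_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_allele_model_json <- function(model, path) {
  jsonlite::write_json(
    list(walk = model$walk, edges = model$edges,
         cassette = cassette_order(model),
         insertion_locus = model$insertion_locus,
         diagram = allele_diagram(model)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
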