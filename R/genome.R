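#' Construct a toy genome
#'
#' A toy genome is a single chromosome represented as an A/C/G/T string. It
#' stands in for a real reference chromosome (in the motivating analysis,
#' chicken chromosome GGA27) at a scale small enough to simulate and assemble
#' exhaustively.
#'
#' @param sequence Character scalar over the alphabet A/C/G/T.
#' @param chrom_name Chromosome name (default `"chrT"`).
#' @return An object of class `toy_genome` with fields `chrom_name`,
#'   `sequence` and `length`.
#' @export
toy_genome <- function(sequence, chrom_name = "chrT") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("toy genome sequence must contain only A/C/G/T")
  }
  structure(
    list(chrom_name = chrom_name, sequence = sequence,
         length = nchar(sequence)),
    class = "toy_genome"
  )
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("<toy_genome> %s: %s bp\n", x$chrom_name,
              format(x$length, big.mark = ",")))
  invisible(x)
}

#' Simulate a random toy genome
#'
#' @param length Chromosome length in bases.
#' @param seed Integer seed; all bases are drawn from this seed.
#' @param chrom_name Chromosome name.
#' @param gc GC content (default 0.42, typical for an avian autosome).
#' @return A [toy_genome()].
#' @export
random_toy_genome <- function(length, seed = 1L, chrom_name = "chrT",
                              gc = 0.42) {
  stopifnot(length >= 1)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  toy_genome(paste(sample(names(p), length, replace = TRUE, prob = p),
                   collapse = ""), chrom_name)
}

#' Junction specifications for a structural-variant cassette
#'
#' A junction is either a microhomology of `k` bases shared by the two joined
#' flanks, or an untemplated insertion of a given sequence (a blunt join is
#' `junction_homology(0)`).
#'
#' @param k Homology length in bases (`k >= 0`).
#' @param seq Inserted sequence over A/C/G/T.
#' @return A list describing the junction, used in [sv_spec()].
#' @export
junction_homology <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  list(type = "homology", k = as.integer(k), seq = "")
}

#' @rdname junction_homology
#' @export
junction_insertion <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("insertion sequence must be A/C/G/T")
  list(type = "insertion", k = 0L, seq = seq)
}

#' Specify a duplication cassette
#'
#' Describes a derived allele in which one or more reference segments are
#' duplicated, joined into a cassette, and inserted after a given reference
#' coordinate. All coordinates are 1-based inclusive. One junction spec is
#' required per novel adjacency the insertion creates; an adjacency that is
#' already reference-contiguous (the joined coordinates are consecutive in the
#' reference) needs none.
#'
#' @param source_intervals Matrix-like or list of `c(start, end)` pairs, one
#'   per duplicated segment, in cassette order.
#' @param insertion_after Reference coordinate after which the cassette is
#'   inserted.
#' @param junctions List of [junction_homology()] / [junction_insertion()]
#'   specs, one per novel adjacency.
#' @return An object of class `sv_spec`.
#' @export
sv_spec <- function(source_intervals, insertion_after, junctions) {
  if (is.matrix(source_intervals)) {
    source_intervals <- lapply(seq_len(nrow(source_intervals)),
                               function(i) source_intervals[i, ])
  }
  for (iv in source_intervals) {
    stopifnot(length(iv) == 2L)
    if (iv[1] > iv[2]) stop("degenerate interval: start > end")
  }
  stopifnot(insertion_after >= 0)
  obj <- structure(
    list(source_intervals = lapply(source_intervals, as.numeric),
         insertion_after = as.numeric(insertion_after),
         junctions = junctions),
    class = "sv_spec"
  )
  n_novel <- length(.sv_adjacencies(obj)$novel)
  if (length(junctions) != n_novel) {
    stop(sprintf("spec creates %d novel adjacencies but %d junction specs given",
                 n_novel, length(junctions)))
  }
  obj
}

#' @export
print.sv_spec <- function(x, ...) {
  cat(sprintf("<sv_spec> %d segment(s) inserted after %s\n",
              length(x$source_intervals),
              format(x$insertion_after, big.mark = ",")))
  for (i in seq_along(x$source_intervals)) {
    iv <- x$source_intervals[[i]]
    cat(sprintf("  segment %d: %s-%s (%s bp)\n", i,
                format(iv[1], big.mark = ","), format(iv[2], big.mark = ","),
                format(iv[2] - iv[1] + 1, big.mark = ",")))
  }
  for (j in x$junctions) {
    cat(if (j$type == "homology") sprintf("  junction: homology %d nt\n", j$k)
        else sprintf("  junction: insertion %s (%d nt)\n", j$seq, nchar(j$seq)))
  }
  invisible(x)
}

## Adjacencies implied by a spec: (left_end -> right_start) pairs for the
## cassette walk insertion_after -> seg1 ... segm -> insertion_after + 1.
## Reference-contiguous joins (left + 1 == right) are dropped from `novel`.
.sv_adjacencies <- function(spec) {
  m <- length(spec$source_intervals)
  if (m == 0L) return(list(all = list(), novel = list()))
  starts <- vapply(spec$source_intervals, `[`, numeric(1), 1L)
  ends <- vapply(spec$source_intervals, `[`, numeric(1), 2L)
  lefts <- c(spec$insertion_after, ends)
  rights <- c(starts, spec$insertion_after + 1)
  adj <- Map(function(l, r) c(left_end = l, right_start = r), lefts, rights)
  novel <- adj[vapply(adj, function(a) a[1] + 1 != a[2], logical(1))]
  list(all = adj, novel = novel)
}

#' Printed breakpoints of the three duplicated segments at the Mb locus
#'
#' Returns the published breakpoint coordinates of the three copy-number
#' variants (CNV1 1,702,269-1,721,521; CNV2 3,578,409-3,592,890;
#' CNV3 4,470,331-4,503,417 on GGA27), optionally divided by a scale factor so
#' the architecture can be replayed on a small toy genome.
#'
#' @param scale Positive divisor applied to all coordinates (rounded).
#' @return Data frame with columns `name`, `start`, `end`.
#' @export
mb_breakpoints <- function(scale = 1) {
  stopifnot(scale > 0)
  data.frame(
    name = c("CNV1", "CNV2", "CNV3"),
    start = round(c(1702269, 3578409, 4470331) / scale),
    end = round(c(1721521, 3592890, 4503417) / scale),
    stringsAsFactors = FALSE
  )
}

#' The Mb derived-allele cassette specification
#'
#' The derived Mb haplotype carries a cassette of duplicated copies of CNV3,
#' CNV2 and CNV1 (in that order) inserted directly after the 3' end of the
#' original CNV1 copy, so the duplicated architecture reads
#' CNV1-CNV3-CNV2-CNV1 along the chromosome. The three novel junctions carry a
#' 2-nt microhomology, a 2-nt insertion and an 8-nt insertion respectively.
#' The inserted junction sequences are configurable generator defaults of the
#' published lengths.
#'
#' @param scale Coordinate divisor passed to [mb_breakpoints()].
#' @param ins2,ins8 Inserted sequences for the 2-nt and 8-nt junctions.
#' @return An [sv_spec()].
#' @export
mb_sv_spec <- function(scale = 1, ins2 = "TA", ins8 = "ACGTTGCA") {
  stopifnot(nchar(ins2) == 2L, nchar(ins8) == 8L)
  bp <- mb_breakpoints(scale)
  cnv <- split(bp, bp$name)
  sv_spec(
    source_intervals = list(
      c(cnv$CNV3$start, cnv$CNV3$end),
      c(cnv$CNV2$start, cnv$CNV2$end),
      c(cnv$CNV1$start, cnv$CNV1$end)
    ),
    insertion_after = cnv$CNV1$end,
    junctions = list(
      junction_homology(2),    # CNV1 3' -> CNV3 5'
      junction_insertion(ins2), # CNV3 3' -> CNV2 5'
      junction_insertion(ins8)  # CNV2 3' -> CNV1 5'
    )
  )
}

#' Build the derived haplotype carrying a duplication cassette
#'
#' Constructs the derived allele: the cassette of duplicated segments, joined
#' according to the junction specs, is inserted after `spec$insertion_after`.
#' The original copies of all source segments remain at their reference
#' positions. Microhomology junctions require the two joined flanks to share
#' the stated number of bases; when `enforce_homology = TRUE` (default) the
#' generator establishes this by editing the reference at the right-hand flank
#' before extracting segments, and the edited reference is attached to the
#' result as `attr(, "reference")` (it is the reference downstream stages
#' should align against).
#'
#' The derived length equals
#' `ref length + sum(segment lengths) - sum(homology k) + sum(insertion lengths)`.
#'
#' @param ref A [toy_genome()].
#' @param spec An [sv_spec()].
#' @param enforce_homology Edit the reference to satisfy homology junctions;
#'   if `FALSE`, an incompatible homology is an error.
#' @return A `toy_genome` for the derived haplotype, with attributes
#'   `reference` (the possibly edited reference) and `junction_table` (the
#'   novel adjacencies with their homology/insertion annotation).
#' @export
build_derived_haplotype <- function(ref, spec, enforce_homology = TRUE) {
  stopifnot(inherits(ref, "toy_genome"), inherits(spec, "sv_spec"))
  m <- length(spec$source_intervals)
  if (m == 0L) {
    out <- ref
    attr(out, "reference") <- ref
    attr(out, "junction_table") <- .junction_table(list(), list())
    return(out)
  }
  for (iv in spec$source_intervals) {
    if (iv[1] < 1 || iv[2] > ref$length) {
      stop(sprintf("source interval %d-%d out of reference bounds (1-%d)",
                   iv[1], iv[2], ref$length))
    }
  }
  if (spec$insertion_after < 1 || spec$insertion_after >= ref$length) {
    stop("insertion_after must lie strictly within the reference")
  }

  seq <- ref$sequence
  adj <- .sv_adjacencies(spec)
  novel <- adj$novel
  ## satisfy homology junctions by editing the right-hand flank of each;
  ## record which position pairs are tied (must stay equal)
  ties <- integer(0)
  for (i in seq_along(novel)) {
    j <- spec$junctions[[i]]
    if (j$type == "homology" && j$k > 0) {
      l <- novel[[i]]["left_end"]
      r <- novel[[i]]["right_start"]
      if (l - j$k + 1 < 1 || r + j$k - 1 > nchar(seq)) {
        stop("homology junction extends beyond the reference")
      }
      block <- substr(seq, l - j$k + 1, l)
      if (substr(seq, r, r + j$k - 1) != block) {
        if (!enforce_homology) {
          stop(sprintf("flanks do not share %d terminal bases at junction %d",
                       j$k, i))
        }
        substr(seq, r, r + j$k - 1) <- block
      }
      for (o in seq_len(j$k) - 1L) {
        ties[sprintf("%d", as.integer(r + o))] <- l - j$k + 1 + o
        ties[sprintf("%d", as.integer(l - j$k + 1 + o))] <- r + o
      }
    }
  }
  ## keep each junction's stated description canonical: the maximal exact
  ## extensions of a junction-spanning read must stop exactly at the planted
  ## coordinates, so a flank base that would let the alignment absorb
  ## homology/insertion bases is rotated to a different base
  if (enforce_homology) {
    rot <- c(A = "C", C = "G", G = "T", T = "A")
    guard <- function(pos, avoid) {
      if (pos >= 1 && pos <= nchar(seq) && nzchar(avoid) &&
          substr(seq, pos, pos) == avoid) {
        new <- rot[[substr(seq, pos, pos)]]
        substr(seq, pos, pos) <<- new
        ## an edited base tied to a homology block drags its partner along
        partner <- ties[sprintf("%d", as.integer(pos))]
        if (!is.na(partner)) substr(seq, partner, partner) <<- new
      }
    }
    for (i in seq_along(novel)) {
      j <- spec$junctions[[i]]
      l <- novel[[i]]["left_end"]
      r <- novel[[i]]["right_start"]
      if (j$type == "homology") {
        guard(l + 1, substr(seq, r + j$k, r + j$k))
        guard(r - 1, substr(seq, l - j$k, l - j$k))
      } else {
        guard(l + 1, substr(j$seq, 1, 1))
        guard(r - 1, substr(j$seq, nchar(j$seq), nchar(j$seq)))
      }
    }
  }
  ref_edited <- toy_genome(seq, ref$chrom_name)

  ## cassette: segments joined per junction spec; homology bases kept once
  jidx <- 0L
  all_adj <- adj$all
  is_novel <- vapply(all_adj, function(a) a[1] + 1 != a[2], logical(1))
  segs <- lapply(spec$source_intervals,
                 function(iv) substr(seq, iv[1], iv[2]))
  cassette <- ""
  tail_skip <- 0L  # homology bases of a trailing junction kept on the cassette
  for (i in seq_len(m + 1L)) {
    if (is_novel[i]) {
      jidx <- jidx + 1L
      j <- spec$junctions[[jidx]]
      if (i <= m) {
        nxt <- segs[[i]]
        if (j$type == "homology" && j$k > 0) {
          nxt <- substr(nxt, j$k + 1L, nchar(nxt))
        }
        cassette <- paste0(cassette, j$seq, nxt)
      } else {
        cassette <- paste0(cassette, j$seq)
        if (j$type == "homology") tail_skip <- j$k
      }
    } else if (i <= m) {
      cassette <- paste0(cassette, segs[[i]])
    }
  }
  derived <- paste0(
    substr(seq, 1, spec$insertion_after),
    cassette,
    substr(seq, spec$insertion_after + 1L + tail_skip, nchar(seq))
  )
  out <- toy_genome(derived, paste0(ref$chrom_name, "_Mb"))
  attr(out, "reference") <- ref_edited
  attr(out, "junction_table") <- .junction_table(novel, spec$junctions)
  out
}

.junction_table <- function(novel, junctions) {
  if (length(novel) == 0L) {
    return(data.frame(left_end = numeric(0), right_start = numeric(0),
                      homology_len = integer(0), inserted_seq = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    left_end = vapply(novel, `[`, numeric(1), "left_end"),
    right_start = vapply(novel, `[`, numeric(1), "right_start"),
    homology_len = vapply(junctions, function(j) j$k, integer(1)),
    inserted_seq = vapply(junctions, function(j) j$seq, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a toy genome as FASTA
#'
#' @param genome A [toy_genome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$chrom_name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a toy genome from FASTA
#'
#' @param path FASTA file with a single sequence.
#' @return A [toy_genome()].
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) stop("expected a single-sequence FASTA")
  toy_genome(as.character(x[[1]]), names(x)[1])
}
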