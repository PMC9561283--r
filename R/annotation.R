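#' @import methods
#' @importFrom stats plogis rbinom rlnorm runif rnorm rpois sd quantile setNames
#' @importFrom utils head tail write.table read.table
NULL

# All internal coordinates are 1-based inclusive (GTF dialect). BED input is
# converted at the read boundary (see read_sites_bed).

#' Construct a transcript model
#'
#' A `transcript_model` describes a single isoform: its ordered exons, an
#' optional CDS span, and the transcript span (TSS..TES). Exons are stored
#' 5'-to-3' in transcript orientation, so for a minus-strand transcript the
#' first exon is the one with the largest genomic coordinates.
#'
#' @param tx_id Transcript identifier.
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix-like of genomic exon `start`/`end`
#'   (1-based inclusive, `start <= end`); any row order is accepted.
#' @param cds Optional length-2 vector with the genomic coordinates of the
#'   first and last CDS nucleotide (`min, max` order), or `NULL` for a
#'   non-coding transcript.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(tx_id, gene_id, chrom, strand, exons, cds = NULL) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-' for ", tx_id)
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0L) stop("transcript ", tx_id, " has no exons")
  if (any(exons$start > exons$end)) stop("exon with start > end in ", tx_id)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in ", tx_id)
  # 5'->3' transcript orientation
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  tx_start <- min(exons$start)
  tx_end <- max(exons$end)
  if (!is.null(cds)) {
    cds <- as.integer(range(cds))
    ok <- vapply(cds, function(p) any(p >= exons$start & p <= exons$end), logical(1))
    if (!all(ok)) stop("CDS endpoints outside exonic space in ", tx_id)
  }
  structure(
    list(tx_id = tx_id, gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, cds = cds, tx_start = tx_start, tx_end = tx_end),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.null(x$cds)) "non-coding" else paste0("CDS ", x$cds[1], "-", x$cds[2])
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d(%s), %d exon(s), %s\n",
              x$tx_id, x$gene_id, x$chrom, x$tx_start, x$tx_end, x$strand,
              nrow(x$exons), cds))
  invisible(x)
}

#' Unspliced (primary transcript) length in nucleotides
#' @param tx A `transcript_model`.
#' @return Integer width of the TSS..TES span, introns included.
#' @export
tx_width <- function(tx) tx$tx_end - tx$tx_start + 1L

#' Spliced (mature transcript) length in nucleotides
#' @param tx A `transcript_model`.
#' @return Integer sum of exon widths.
#' @export
spliced_length <- function(tx) sum(tx$exons$end - tx$exons$start + 1L)

#' Parse transcript annotation from GTF/GFF3
#'
#' Reads `exon` and `CDS` features grouped by `transcript_id` and builds one
#' [transcript_model()] per transcript. UTRs are not read from the file; they
#' are inferred downstream from exons minus CDS. Transcripts with no exon
#' record, with a CDS endpoint outside exonic space, or with inconsistent
#' strand/chromosome are rejected (with a warning naming them).
#'
#' @param path Path to a GTF or GFF3 file.
#' @return A named list of `transcript_model` objects. The attribute
#'   `rejected` carries the ids of rejected transcripts and `n_warnings` the
#'   number of reject events.
#' @export
parse_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) {
    warning("no exon/CDS features found in ", path)
    out <- list()
    attr(out, "rejected") <- character(0)
    attr(out, "n_warnings") <- 1L
    return(out)
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    tx_id = as.character(md$transcript_id),
    gene_id = if (!is.null(md$gene_id)) as.character(md$gene_id) else NA_character_,
    stringsAsFactors = FALSE)
  df <- df[!is.na(df$tx_id), , drop = FALSE]
  models <- list()
  rejected <- character(0)
  for (id in unique(df$tx_id)) {
    rec <- df[df$tx_id == id, , drop = FALSE]
    ex <- rec[rec$type == "exon", , drop = FALSE]
    cd <- rec[rec$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L) {
      rejected <- c(rejected, id)
      next
    }
    cds <- if (nrow(cd) > 0L) c(min(cd$start), max(cd$end)) else NULL
    m <- tryCatch(
      transcript_model(id, ex$gene_id[1], ex$chrom[1], ex$strand[1], ex[, c("start", "end")], cds),
      error = function(e) e)
    if (inherits(m, "error")) {
      rejected <- c(rejected, id)
      next
    }
    models[[id]] <- m
  }
  if (length(rejected) > 0L)
    warning(length(rejected), " transcript(s) rejected: ",
            paste(utils::head(rejected, 5L), collapse = ", "))
  attr(models, "rejected") <- rejected
  attr(models, "n_warnings") <- length(rejected)
  models
}

#' Decompose a transcript into maximal typed region runs
#'
#' Tiles the transcript span (TSS..TES) with maximal runs of identical region
#' type, ordered 5'-to-3' in transcript orientation. Five region flags are
#' reported: `exon`, `intron`, `cds`, `utr5`, `utr3`; `exon + intron == 1` on
#' every run, and the CDS/UTR flags are zero on introns. UTRs are inferred as
#' exonic space outside the CDS span (the stop codon is taken as annotated,
#' with no adjustment).
#'
#' @param tx A `transcript_model`.
#' @return A data.frame with columns `start`, `end` (genomic), `width`,
#'   `exon`, `intron`, `cds`, `utr5`, `utr3`, rows ordered 5'-to-3'.
#' @export
decompose_regions <- function(tx) {
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE] # genomic order here
  pieces <- list()
  add <- function(s, e, exon) {
    if (s > e) return()
    pieces[[length(pieces) + 1L]] <<- c(s, e, exon)
  }
  if (is.null(tx$cds)) {
    for (i in seq_len(nrow(ex))) add(ex$start[i], ex$end[i], 1L)
  } else {
    cs <- tx$cds[1]; ce <- tx$cds[2]
    for (i in seq_len(nrow(ex))) {
      s <- ex$start[i]; e <- ex$end[i]
      add(s, min(e, cs - 1L), 1L)              # exonic, left of CDS span
      add(max(s, cs), min(e, ce), 1L)          # exonic, inside CDS span
      add(max(s, ce + 1L), e, 1L)              # exonic, right of CDS span
    }
  }
  # introns between genomically adjacent exons
  if (nrow(ex) > 1L)
    for (i in seq_len(nrow(ex) - 1L)) add(ex$end[i] + 1L, ex$start[i + 1L] - 1L, 0L)
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1]), , drop = FALSE]
  runs <- data.frame(start = m[, 1], end = m[, 2], exon = m[, 3])
  runs$intron <- 1L - runs$exon
  runs$cds <- 0L; runs$utr5 <- 0L; runs$utr3 <- 0L
  if (!is.null(tx$cds)) {
    cs <- tx$cds[1]; ce <- tx$cds[2]
    inside <- runs$exon == 1L & runs$start >= cs & runs$end <= ce
    runs$cds[inside] <- 1L
    left <- runs$exon == 1L & runs$end < cs    # genomic-left of CDS
    right <- runs$exon == 1L & runs$start > ce # genomic-right of CDS
    if (tx$strand == "+") {
      runs$utr5[left] <- 1L; runs$utr3[right] <- 1L
    } else {
      runs$utr3[left] <- 1L; runs$utr5[right] <- 1L
    }
  }
  # merge adjacent runs with identical flags (maximality)
  flags <- c("exon", "intron", "cds", "utr5", "utr3")
  keep <- rep(TRUE, nrow(runs))
  i <- 1L
  while (i < nrow(runs)) {
    j <- i + 1L
    if (runs$end[i] + 1L == runs$start[j] &&
        all(runs[i, flags] == runs[j, flags])) {
      runs$end[i] <- runs$end[j]
      runs <- runs[-j, , drop = FALSE]
    } else i <- i + 1L
  }
  rownames(runs) <- NULL
  runs$width <- runs$end - runs$start + 1L
  if (tx$strand == "-") runs <- runs[rev(seq_len(nrow(runs))), , drop = FALSE]
  rownames(runs) <- NULL
  runs[, c("start", "end", "width", flags)]
}

#' Map a genomic position onto a transcript
#'
#' Converts a genomic coordinate into a 1-based transcript position counted
#' from the transcript 5' end in transcript orientation. In `"spliced"` space
#' introns are excised; a genomic position falling in an intron returns `NA`
#' (a "not-on-transcript" signal, not an error). In `"unspliced"` space the
#' whole TSS..TES span is counted.
#'
#' @param tx A `transcript_model`.
#' @param gpos Genomic position (1-based), may be a vector.
#' @param space `"spliced"` or `"unspliced"`.
#' @return Integer transcript position(s); `NA` where not on the transcript.
#' @export
map_coordinate <- function(tx, gpos, space = c("spliced", "unspliced")) {
  space <- match.arg(space)
  if (space == "unspliced") {
    out <- if (tx$strand == "+") gpos - tx$tx_start + 1L else tx$tx_end - gpos + 1L
    out[gpos < tx$tx_start | gpos > tx$tx_end] <- NA_integer_
    return(as.integer(out))
  }
  ex <- tx$exons # already 5'->3'
  w <- ex$end - ex$start + 1L
  off <- cumsum(c(0L, w[-length(w)]))
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(ex))) {
    hit <- gpos >= ex$start[i] & gpos <= ex$end[i]
    if (!any(hit)) next
    within <- if (tx$strand == "+") gpos[hit] - ex$start[i] + 1L else ex$end[i] - gpos[hit] + 1L
    out[hit] <- off[i] + within
  }
  as.integer(out)
}

#' Inverse of [map_coordinate()]: transcript position to genomic coordinate
#'
#' @param tx A `transcript_model`.
#' @param tpos 1-based transcript position(s) in the chosen space.
#' @param space `"spliced"` or `"unspliced"`.
#' @return Genomic coordinate(s); `NA` where out of range.
#' @export
tx_to_genome <- function(tx, tpos, space = c("spliced", "unspliced")) {
  space <- match.arg(space)
  if (space == "unspliced") {
    out <- if (tx$strand == "+") tx$tx_start + tpos - 1L else tx$tx_end - tpos + 1L
    out[tpos < 1L | tpos > tx_width(tx)] <- NA_integer_
    return(as.integer(out))
  }
  ex <- tx$exons
  w <- ex$end - ex$start + 1L
  off <- cumsum(c(0L, w[-length(w)]))
  out <- rep(NA_integer_, length(tpos))
  for (i in seq_len(nrow(ex))) {
    hit <- tpos > off[i] & tpos <= off[i] + w[i]
    if (!any(hit)) next
    within <- tpos[hit] - off[i]
    out[hit] <- if (tx$strand == "+") ex$start[i] + within - 1L else ex$end[i] - within + 1L
  }
  as.integer(out)
}

#' Find isoforms overlapping a genomic site
#'
#' @param chrom,pos,strand Site identity (single nucleotide) or, with `end`,
#'   a closed genomic interval `pos..end`.
#' @param models List of `transcript_model` objects.
#' @param mode `"mature"`: the site must be contained in exonic space;
#'   `"primary"`: containment in the TSS..TES span suffices.
#' @param end Optional interval end (defaults to `pos`).
#' @return The (possibly empty) sub-list of overlapping isoforms.
#' @export
overlapping_isoforms <- function(chrom, pos, strand, models,
                                 mode = c("mature", "primary"), end = pos) {
  mode <- match.arg(mode)
  hit <- vapply(models, function(tx) {
    if (tx$chrom != chrom || tx$strand != strand) return(FALSE)
    if (pos < tx$tx_start || end > tx$tx_end) return(FALSE)
    if (mode == "primary") return(TRUE)
    all(vapply(pos:end, function(p)
      any(p >= tx$exons$start & p <= tx$exons$end), logical(1)))
  }, logical(1))
  models[hit]
}

#' Select one isoform from a candidate list
#'
#' `"longest"` picks the maximal spliced length, ties broken by lexicographic
#' transcript id; `"random"` draws uniformly, reproducibly under `seed`.
#'
#' @param isoforms Non-empty list of `transcript_model` objects.
#' @param policy `"longest"` or `"random"`.
#' @param seed Integer seed used by the `"random"` policy.
#' @return A single `transcript_model`.
#' @export
select_isoform <- function(isoforms, policy = c("longest", "random"), seed = 1L) {
  policy <- match.arg(policy)
  if (length(isoforms) == 0L) stop("no isoform to select from")
  if (policy == "longest") {
    len <- vapply(isoforms, spliced_length, integer(1))
    ids <- vapply(isoforms, function(tx) tx$tx_id, character(1))
    ord <- order(-len, ids)
    return(isoforms[[ord[1L]]])
  }
  idx <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample.int(length(isoforms), 1L)
  })
  isoforms[[idx]]
}
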