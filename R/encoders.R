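# Geographic encoders. All encoders work in transcript orientation: position
# 1 is the transcript 5' end, so a transcript and its minus-strand mirror give
# identical encodings for mirrored sites. The default frame is the unspliced
# (primary) transcript, so intronic structure is visible to the matrix
# encoders; a spliced frame is available for landmark distances.

REGION_FLAGS <- c("exon", "intron", "cds", "utr5", "utr3")

# region runs with transcript-space (unspliced) coordinates attached
.runs_tx <- function(tx) {
  runs <- decompose_regions(tx)
  w <- runs$width
  runs$t_end <- cumsum(w)
  runs$t_start <- runs$t_end - w + 1L
  runs
}

.log_width <- function(w) log(w + 1)

#' Landmark-distance encoding of a site on one isoform
#'
#' Encodes a single target ribonucleotide as its distances to six transcript
#' landmarks: the 5' and 3' boundaries of the containing exon, of the CDS,
#' and of the whole transcript. Distances are positional differences, so a
#' site sitting on a boundary has distance 0 and the containing region width
#' equals `d5 + d3 + 1`. The CDS distances are signed: `d_cds5` is negative
#' for a site 5' of the CDS start (in the 5'UTR) and `d_cds3` is negative for
#' a site 3' of the CDS end (in the 3'UTR). Exon/transcript distances are
#' always non-negative.
#'
#' @param tx A `transcript_model`.
#' @param site Genomic position of the target ribonucleotide.
#' @param frame `"unspliced"` (default) measures distances on the primary
#'   transcript; `"spliced"` on the mature transcript.
#' @param allow_intronic If `TRUE` and `frame = "unspliced"`, an intronic
#'   site is encoded against its containing intron run instead of erroring.
#' @return Named numeric vector of length 6:
#'   `d_exon5, d_exon3, d_cds5, d_cds3, d_tx5, d_tx3`. For a non-coding
#'   transcript the CDS fields are 0 and the attribute `has_cds` is `FALSE`.
#' @export
encode_landmark_tx <- function(tx, site, frame = c("unspliced", "spliced"),
                               allow_intronic = FALSE) {
  frame <- match.arg(frame)
  pos <- map_coordinate(tx, site, frame)
  if (is.na(pos)) stop("site ", site, " is not on transcript ", tx$tx_id,
                       " in the ", frame, " frame")
  L <- if (frame == "unspliced") tx_width(tx) else spliced_length(tx)
  ex <- tx$exons
  hit <- which(site >= ex$start & site <= ex$end)
  if (length(hit) == 0L) {
    if (!allow_intronic || frame == "spliced")
      stop("site ", site, " is intronic on ", tx$tx_id,
           "; set allow_intronic = TRUE to encode against the intron")
    runs <- .runs_tx(tx)
    r <- runs[runs$start <= site & runs$end >= site, , drop = FALSE]
    b5 <- if (tx$strand == "+") r$start[1] else r$end[1]
    b3 <- if (tx$strand == "+") r$end[1] else r$start[1]
  } else {
    b5 <- if (tx$strand == "+") ex$start[hit] else ex$end[hit]
    b3 <- if (tx$strand == "+") ex$end[hit] else ex$start[hit]
  }
  p5 <- map_coordinate(tx, b5, frame)
  p3 <- map_coordinate(tx, b3, frame)
  has_cds <- !is.null(tx$cds)
  if (has_cds) {
    c5g <- if (tx$strand == "+") tx$cds[1] else tx$cds[2]
    c3g <- if (tx$strand == "+") tx$cds[2] else tx$cds[1]
    pc5 <- map_coordinate(tx, c5g, frame)
    pc3 <- map_coordinate(tx, c3g, frame)
    d_cds5 <- pos - pc5
    d_cds3 <- pc3 - pos
  } else {
    d_cds5 <- 0
    d_cds3 <- 0
  }
  out <- c(d_exon5 = pos - p5, d_exon3 = p3 - pos,
           d_cds5 = d_cds5, d_cds3 = d_cds3,
           d_tx5 = pos - 1, d_tx3 = L - pos)
  storage.mode(out) <- "double"
  attr(out, "has_cds") <- has_cds
  attr(out, "frame") <- frame
  out
}

# target interval in unspliced transcript coordinates, 5'->3'
.target_tspan <- function(tx, site, end) {
  ta <- map_coordinate(tx, site, "unspliced")
  tb <- map_coordinate(tx, end, "unspliced")
  if (anyNA(c(ta, tb))) stop("target ", site, "-", end,
                             " is not within the span of ", tx$tx_id)
  sort(c(ta, tb))
}

#' Equal-width grid encoding of a transcript around a target
#'
#' Lays a grid of `G` near-equal fragments (widths differing by at most 1)
#' over the unspliced transcript span, 5' to 3'. Each row reports the
#' fraction of fragment nucleotides in each of the five region types, the
#' log-transformed fragment width, and a flag marking fragments that overlap
#' the target site or area.
#'
#' @param tx A `transcript_model`.
#' @param site Genomic position of the target (or interval start).
#' @param G Number of grid fragments (`1 <= G <=` transcript width).
#' @param end Optional interval end for an area target (defaults to `site`).
#' @return A `G x 7` matrix of class `grid_matrix` with columns
#'   `frac_exon, frac_intron, frac_cds, frac_utr5, frac_utr3, log_width,
#'   target`.
#' @export
encode_grid_tx <- function(tx, site, G, end = site) {
  L <- tx_width(tx)
  if (G < 1L) stop("G must be >= 1")
  if (G > L) stop("G = ", G, " exceeds the transcript width (", L,
                  " nt); use the one-hot region encoding instead")
  tsp <- .target_tspan(tx, site, end)
  base <- L %/% G
  widths <- rep.int(base, G)
  extra <- L %% G
  if (extra > 0L) widths[seq_len(extra)] <- widths[seq_len(extra)] + 1L
  t_end <- cumsum(widths)
  t_start <- t_end - widths + 1L
  runs <- .runs_tx(tx)
  out <- matrix(0, nrow = G, ncol = 7L,
                dimnames = list(NULL, c(paste0("frac_", REGION_FLAGS),
                                        "log_width", "target")))
  for (f in seq_len(G)) {
    ov <- pmin(runs$t_end, t_end[f]) - pmax(runs$t_start, t_start[f]) + 1L
    ov[ov < 0L] <- 0L
    for (fl in REGION_FLAGS)
      out[f, paste0("frac_", fl)] <- sum(ov * runs[[fl]]) / widths[f]
    out[f, "log_width"] <- .log_width(widths[f])
    out[f, "target"] <- as.numeric(t_start[f] <= tsp[2] && t_end[f] >= tsp[1])
  }
  structure(out, class = c("grid_matrix", "matrix", "array"),
            params = list(G = G, log_policy = "log(width + 1)"),
            tx_id = tx$tx_id)
}

# split region runs at the target interval; returns the run table with a
# target column, ordered 5'->3'
.split_runs_at_target <- function(tx, tsp) {
  runs <- .runs_tx(tx)
  rows <- list()
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    if (r$t_end < tsp[1] || r$t_start > tsp[2]) {
      rows[[length(rows) + 1L]] <- cbind(r, target = 0L)
      next
    }
    seg <- function(a, b, tgt) {
      if (a > b) return()
      piece <- r
      piece$t_start <- a; piece$t_end <- b
      piece$width <- b - a + 1L
      g <- sort(tx_to_genome(tx, c(a, b), "unspliced"))
      piece$start <- g[1]; piece$end <- g[2]
      rows[[length(rows) + 1L]] <<- cbind(piece, target = tgt)
    }
    seg(r$t_start, tsp[1] - 1L, 0L)
    seg(max(r$t_start, tsp[1]), min(r$t_end, tsp[2]), 1L)
    seg(tsp[2] + 1L, r$t_end, 0L)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Region-chunk encoding of a transcript centered on a target
#'
#' Recomputes the transcript's maximal region runs with the target splitting
#' its containing run into left / target / right sub-regions, then centers
#' the (first) target row in a fixed-height matrix of `C` rows: the short
#' side is zero-padded and the long side trimmed. Each populated row carries
#' binary region-type indicators, the log-transformed run width, and the
#' target flag. This encoding is lossless whenever no trimming occurs: see
#' [decode_chunk_tx()].
#'
#' @param tx A `transcript_model`.
#' @param site Genomic position of the target (or interval start).
#' @param C Odd number of chunk rows (default 35, sized to the typical
#'   region-count distribution of human genes).
#' @param end Optional interval end for an area target.
#' @param target_column If `FALSE`, a whole-transcript variant is returned:
#'   no target split and a `C x 6` matrix without the target column.
#' @return A `C x 7` (or `C x 6`) matrix of class `chunk_matrix` with columns
#'   `exon, intron, cds, utr5, utr3, log_width[, target]`. Attributes:
#'   `run_table` (genomic interval per populated row), `trimmed`,
#'   `target_covered`, `params`.
#' @export
encode_chunk_tx <- function(tx, site, C = 35L, end = site, target_column = TRUE) {
  if (C %% 2L != 1L) stop("C must be odd (got ", C, ")")
  if (!target_column) {
    runs <- .runs_tx(tx)
    runs$target <- 0L
    n <- min(nrow(runs), C)
    out <- matrix(0, nrow = C, ncol = 6L,
                  dimnames = list(NULL, c(REGION_FLAGS, "log_width")))
    rt <- data.frame(row = seq_len(C), start = NA_integer_, end = NA_integer_,
                     target = 0L)
    for (i in seq_len(n)) {
      out[i, REGION_FLAGS] <- as.numeric(runs[i, REGION_FLAGS])
      out[i, "log_width"] <- .log_width(runs$width[i])
      rt$start[i] <- runs$start[i]; rt$end[i] <- runs$end[i]
    }
    return(structure(out, class = c("chunk_matrix", "matrix", "array"),
                     run_table = rt, trimmed = nrow(runs) > C,
                     target_covered = NA, tx_id = tx$tx_id,
                     params = list(C = C, target_column = FALSE,
                                   log_policy = "log(width + 1)")))
  }
  tsp <- .target_tspan(tx, site, end)
  runs <- .split_runs_at_target(tx, tsp)
  t_first <- which(runs$target == 1L)[1]
  center <- (C + 1L) %/% 2L
  # row i of runs goes to matrix row center + (i - t_first)
  dest <- center + seq_len(nrow(runs)) - t_first
  keep <- dest >= 1L & dest <= C
  trimmed <- any(!keep)
  out <- matrix(0, nrow = C, ncol = 7L,
                dimnames = list(NULL, c(REGION_FLAGS, "log_width", "target")))
  rt <- data.frame(row = seq_len(C), start = NA_integer_, end = NA_integer_,
                   target = 0L)
  for (i in which(keep)) {
    d <- dest[i]
    out[d, REGION_FLAGS] <- as.numeric(runs[i, REGION_FLAGS])
    out[d, "log_width"] <- .log_width(runs$width[i])
    out[d, "target"] <- runs$target[i]
    rt$start[d] <- runs$start[i]; rt$end[d] <- runs$end[i]
    rt$target[d] <- runs$target[i]
  }
  structure(out, class = c("chunk_matrix", "matrix", "array"),
            run_table = rt, trimmed = trimmed, target_covered = TRUE,
            tx_id = tx$tx_id,
            params = list(C = C, target_column = TRUE,
                          log_policy = "log(width + 1)"))
}

#' Decode a chunk encoding back into its region layout
#'
#' Inverts [encode_chunk_tx()]: padding rows are dropped, widths are
#' recovered by inverting the log transform, and the ordered region layout
#' (flags, width, target mark) is returned. Exact whenever the matrix was
#' not trimmed; a trimmed matrix yields a partial layout with the attribute
#' `truncated = TRUE`.
#'
#' @param m A `chunk_matrix`.
#' @return A data.frame with columns `exon, intron, cds, utr5, utr3, width,
#'   target`, one row per populated chunk, 5' to 3'.
#' @export
decode_chunk_tx <- function(m) {
  flags <- REGION_FLAGS[REGION_FLAGS %in% colnames(m)]
  pop <- rowSums(abs(m[, flags, drop = FALSE])) > 0
  has_target <- "target" %in% colnames(m)
  out <- as.data.frame(m[pop, flags, drop = FALSE])
  out$width <- as.integer(round(exp(m[pop, "log_width"]) - 1))
  out$target <- if (has_target) as.integer(m[pop, "target"]) else 0L
  rownames(out) <- NULL
  trimmed <- isTRUE(attr(m, "trimmed"))
  attr(out, "truncated") <- trimmed
  out
}

#' One-hot region-type encoding of a window around a site
#'
#' A `W`-row window centered on the target in the unspliced frame; each row
#' is the five-way region-type indicator of one nucleotide. Rows falling
#' outside the transcript span are all-zero.
#'
#' @param tx A `transcript_model`.
#' @param site Genomic position of the target.
#' @param W Odd window width in nucleotides (101 and 251 are the usual
#'   choices, giving 505 and 1255 features).
#' @return A `W x 5` binary matrix of class `onehot_region_matrix`.
#' @export
encode_onehot_region <- function(tx, site, W) {
  if (W %% 2L != 1L) stop("W must be odd")
  tp <- map_coordinate(tx, site, "unspliced")
  if (is.na(tp)) stop("site ", site, " is not within the span of ", tx$tx_id)
  h <- (W - 1L) %/% 2L
  tpos <- (tp - h):(tp + h)
  runs <- .runs_tx(tx)
  out <- matrix(0, nrow = W, ncol = 5L, dimnames = list(NULL, REGION_FLAGS))
  L <- tx_width(tx)
  inside <- which(tpos >= 1L & tpos <= L)
  if (length(inside) > 0L) {
    idx <- findInterval(tpos[inside], runs$t_start)
    for (fl in REGION_FLAGS) out[inside, fl] <- runs[[fl]][idx]
  }
  structure(out, class = c("onehot_region_matrix", "matrix", "array"),
            params = list(W = W), tx_id = tx$tx_id)
}

#' One-hot sequence encoding of a window around a genomic site
#'
#' Extracts `W` nucleotides centered on the site from the genome, oriented
#' 5' to 3' on the given strand (reverse-complemented for `"-"`), and one-hot
#' encodes them over the RNA alphabet A/C/G/U (T is read as U; N and
#' out-of-chromosome positions give all-zero rows).
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param chrom,pos,strand Site identity.
#' @param W Odd window width.
#' @return A `W x 4` binary matrix of class `onehot_seq_matrix` with columns
#'   `A, C, G, U`.
#' @export
encode_onehot_seq <- function(genome, chrom, pos, strand, W) {
  if (W %% 2L != 1L) stop("W must be odd")
  if (methods::is(genome, "DNAStringSet"))
    genome <- as.character(genome)
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " not in genome")
  s <- genome[[chrom]]
  h <- (W - 1L) %/% 2L
  gpos <- (pos - h):(pos + h)
  chars <- rep("N", W)
  inside <- gpos >= 1L & gpos <= nchar(s)
  if (any(inside))
    chars[inside] <- strsplit(substr(s, max(1L, pos - h),
                                     min(nchar(s), pos + h)), "")[[1]]
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")
    chars <- rev(unname(comp[toupper(chars)]))
    chars[is.na(chars)] <- "N"
  } else {
    chars <- toupper(chars)
  }
  out <- matrix(0, nrow = W, ncol = 4L, dimnames = list(NULL, c("A", "C", "G", "U")))
  out[chars == "A", "A"] <- 1
  out[chars == "C", "C"] <- 1
  out[chars == "G", "G"] <- 1
  out[chars %in% c("T", "U"), "U"] <- 1
  structure(out, class = c("onehot_seq_matrix", "matrix", "array"),
            params = list(W = W))
}

#' Truncate a chunk encoding to the span of a sequencing read
#'
#' Restricts a chunk encoding to the part of the transcript actually covered
#' by one read: rows entirely outside the read span are zeroed, boundary
#' rows get their widths reduced to the covered part, and the target row is
#' preserved when covered. A read that does not cover the target returns a
#' flagged encoding (all target flags zero, `target_covered = FALSE`) rather
#' than an error.
#'
#' @param m A `chunk_matrix` produced by [encode_chunk_tx()].
#' @param read_start,read_end Genomic span of the read (1-based inclusive).
#' @return The read-specific `chunk_matrix`.
#' @export
truncate_to_read <- function(m, read_start, read_end) {
  rt <- attr(m, "run_table")
  if (is.null(rt)) stop("chunk matrix lacks a run_table attribute")
  out <- m
  covered_target <- FALSE
  for (i in seq_len(nrow(rt))) {
    if (is.na(rt$start[i])) next
    s <- max(rt$start[i], read_start)
    e <- min(rt$end[i], read_end)
    if (s > e) {
      out[i, ] <- 0
      rt$start[i] <- NA_integer_; rt$end[i] <- NA_integer_; rt$target[i] <- 0L
      next
    }
    rt$start[i] <- s; rt$end[i] <- e
    out[i, "log_width"] <- .log_width(e - s + 1L)
    if ("target" %in% colnames(out) && out[i, "target"] == 1)
      covered_target <- TRUE
  }
  if (!covered_target && "target" %in% colnames(out))
    out[, "target"] <- 0
  attr(out, "run_table") <- rt
  attr(out, "target_covered") <- covered_target
  out
}

.zero_like <- function(m) {
  z <- m
  z[] <- 0
  attr(z, "real") <- FALSE
  z
}

#' Assemble the isoform bag of one site
#'
#' Encodes one site against every overlapping isoform, producing the bag
#' consumed by the attention-based multiple instance learning models.
#'
#' @param chrom,pos,strand Site identity.
#' @param models List of `transcript_model` objects.
#' @param encoder Encoder to apply per isoform: `"chunk"`, `"grid"`,
#'   `"landmark"` or `"onehot_region"`.
#' @param mode Isoform overlap mode passed to [overlapping_isoforms()].
#' @param ... Encoder parameters (`C`, `G`, `W`, ...).
#' @return An object of class `isoform_bag`: list with `site` and `members`
#'   (named list of encodings, one per isoform).
#' @export
build_bag <- function(chrom, pos, strand, models, encoder = c("chunk", "grid",
                      "landmark", "onehot_region"),
                      mode = c("mature", "primary"), ...) {
  encoder <- match.arg(encoder)
  mode <- match.arg(mode)
  iso <- overlapping_isoforms(chrom, pos, strand, models, mode)
  if (length(iso) == 0L)
    stop("no isoform overlaps site ", chrom, ":", pos, "(", strand, ")")
  members <- lapply(iso, function(tx) switch(encoder,
    chunk = encode_chunk_tx(tx, pos, ...),
    grid = encode_grid_tx(tx, pos, ...),
    landmark = encode_landmark_tx(tx, pos, ...),
    onehot_region = encode_onehot_region(tx, pos, ...)))
  structure(list(site = list(chrom = chrom, pos = pos, strand = strand),
                 members = members),
            class = "isoform_bag")
}

#' Assemble the fixed-size read bag of one site
#'
#' Builds read-specific chunk encodings (via [truncate_to_read()]) for the
#' reads covering a site and returns a bag of exactly `bag_size` members:
#' when more reads are available they are down-sampled reproducibly under
#' `seed`; when fewer, all-zero padding members are appended (padding members
#' carry `real = FALSE` and are masked out of attention and Noisy-OR
#' aggregation downstream).
#'
#' @param tx The `transcript_model` carrying the site.
#' @param site Genomic position of the target.
#' @param read_spans Data.frame with columns `start`, `end` (genomic read
#'   spans).
#' @param bag_size Number of members in the bag (default 20).
#' @param C Chunk rows for the underlying encoding.
#' @param seed Integer seed for the down-sampling draw.
#' @return An object of class `read_bag`: list with `site`, `members`
#'   (list of `chunk_matrix`), and `real` (logical vector).
#' @export
build_read_bag <- function(tx, site, read_spans, bag_size = 20L, C = 35L,
                           seed = 1L) {
  if (nrow(read_spans) == 0L) stop("no reads for site ", site)
  base <- encode_chunk_tx(tx, site, C = C)
  n <- nrow(read_spans)
  idx <- seq_len(n)
  if (n > bag_size) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    idx <- sort(sample.int(n, bag_size))
  }
  members <- lapply(idx, function(i) {
    enc <- truncate_to_read(base, read_spans$start[i], read_spans$end[i])
    attr(enc, "real") <- TRUE
    enc
  })
  real <- rep(TRUE, length(members))
  while (length(members) < bag_size) {
    members[[length(members) + 1L]] <- .zero_like(base)
    real <- c(real, FALSE)
  }
  structure(list(site = site, tx_id = tx$tx_id, members = members, real = real),
            class = "read_bag")
}
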