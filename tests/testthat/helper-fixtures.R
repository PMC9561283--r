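# Shared fixtures: a small two-exon coding transcript and friends, plus an
# independent per-nucleotide classification oracle used against the
# interval-arithmetic implementation.

tx1 <- function() transcript_model(
  "TX1", "G1", "c1", "+",
  data.frame(start = c(101L, 301L), end = c(200L, 400L)),
  cds = c(151L, 350L))

# minus-strand mirror of tx1 across position 501 (x -> 501 - x): exons
# 101-200/301-400, CDS 151-350 map onto themselves
tx1_minus <- function() transcript_model(
  "TX1M", "G1", "c1", "-",
  data.frame(start = c(101L, 301L), end = c(200L, 400L)),
  cds = c(151L, 350L))

tx1_short <- function() transcript_model(
  "TX1S", "G1", "c1", "+",
  data.frame(start = 101L, end = 200L))

# Per-nucleotide oracle: classify every genomic position of the span one at a
# time, then collapse to maximal runs. Independent of decompose_regions().
nt_flags <- function(tx, gpos) {
  in_exon <- any(gpos >= tx$exons$start & gpos <= tx$exons$end)
  f <- c(exon = as.integer(in_exon), intron = as.integer(!in_exon),
         cds = 0L, utr5 = 0L, utr3 = 0L)
  if (in_exon && !is.null(tx$cds)) {
    if (gpos >= tx$cds[1] && gpos <= tx$cds[2]) f["cds"] <- 1L
    else {
      five_side <- if (tx$strand == "+") gpos < tx$cds[1] else gpos > tx$cds[2]
      if (five_side) f["utr5"] <- 1L else f["utr3"] <- 1L
    }
  }
  f
}

oracle_runs <- function(tx) {
  gpos <- tx$tx_start:tx$tx_end
  if (tx$strand == "-") gpos <- rev(gpos)
  fl <- t(vapply(gpos, function(p) nt_flags(tx, p), integer(5)))
  key <- apply(fl, 1, paste, collapse = "")
  brk <- c(TRUE, key[-1] != key[-length(key)])
  grp <- cumsum(brk)
  data.frame(
    start = as.integer(tapply(gpos, grp, min)),
    end = as.integer(tapply(gpos, grp, max)),
    width = as.integer(tapply(gpos, grp, length)),
    exon = as.integer(tapply(fl[, "exon"], grp, function(v) v[1])),
    intron = as.integer(tapply(fl[, "intron"], grp, function(v) v[1])),
    cds = as.integer(tapply(fl[, "cds"], grp, function(v) v[1])),
    utr5 = as.integer(tapply(fl[, "utr5"], grp, function(v) v[1])),
    utr3 = as.integer(tapply(fl[, "utr3"], grp, function(v) v[1])),
    row.names = NULL)
}

# small random transcript generator for property sweeps (independent of the
# synthetic module so encoder properties are not tested through it)
random_tx <- function(id = "R1", seed = NULL, max_exons = 6L, coding = TRUE,
                      strand = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_ex <- sample(1:max_exons, 1L)
  widths <- sample(20:200, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1L) sample(30:300, n_ex - 1L, replace = TRUE) else integer(0)
  start <- sample(1000:2000, 1L)
  s <- integer(n_ex); e <- integer(n_ex)
  cur <- start
  for (i in seq_len(n_ex)) {
    s[i] <- cur; e[i] <- cur + widths[i] - 1L
    cur <- e[i] + 1L + if (i < n_ex) gaps[i] else 0L
  }
  if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
  cds <- NULL
  sl <- sum(widths)
  if (coding && sl >= 40L) {
    a <- sample(1:(sl %/% 3), 1L)
    b <- sample((2L * sl %/% 3):sl, 1L)
    tmp <- transcript_model(id, "G", "cR", strand, data.frame(start = s, end = e))
    cds <- sort(c(tx_to_genome(tmp, a, "spliced"), tx_to_genome(tmp, b, "spliced")))
  }
  transcript_model(id, "G", "cR", strand, data.frame(start = s, end = e), cds = cds)
}

write_toy_gtf <- function(path) {
  lines <- c(
    paste0('c1\ttoy\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "TX1";'),
    paste0('c1\ttoy\texon\t301\t400\t.\t+\t.\tgene_id "G1"; transcript_id "TX1";'),
    paste0('c1\ttoy\tCDS\t151\t200\t.\t+\t0\tgene_id "G1"; transcript_id "TX1";'),
    paste0('c1\ttoy\tCDS\t301\t350\t.\t+\t0\tgene_id "G1"; transcript_id "TX1";'))
  writeLines(lines, path)
  path
}
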