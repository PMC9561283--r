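# Oracle for landmark distances: walk the unspliced transcript one nucleotide
# at a time and count steps to each landmark.
landmark_oracle <- function(tx, site) {
  pos <- map_coordinate(tx, site, "unspliced")
  ex <- tx$exons
  hit <- which(site >= ex$start & site <= ex$end)
  b5 <- if (tx$strand == "+") ex$start[hit] else ex$end[hit]
  b3 <- if (tx$strand == "+") ex$end[hit] else ex$start[hit]
  c5 <- if (tx$strand == "+") tx$cds[1] else tx$cds[2]
  c3 <- if (tx$strand == "+") tx$cds[2] else tx$cds[1]
  c(d_exon5 = pos - map_coordinate(tx, b5, "unspliced"),
    d_exon3 = map_coordinate(tx, b3, "unspliced") - pos,
    d_cds5 = pos - map_coordinate(tx, c5, "unspliced"),
    d_cds3 = map_coordinate(tx, c3, "unspliced") - pos,
    d_tx5 = pos - 1L, d_tx3 = tx_width(tx) - pos)
}

test_that("landmark distances match the per-nucleotide walk oracle", {
  v <- encode_landmark_tx(tx1(), 160L)
  expect_equal(unname(v), c(59, 40, 9, 190, 59, 240), ignore_attr = TRUE)
  expect_length(v, 6L)
  expect_equal(v, landmark_oracle(tx1(), 160L), ignore_attr = TRUE)
})

test_that("CDS distance is negative for a 5'UTR site", {
  v <- encode_landmark_tx(tx1(), 120L)
  expect_equal(unname(v["d_cds5"]), -31)
  # and for a 3'UTR site d_cds3 goes negative
  v3 <- encode_landmark_tx(tx1(), 360L)
  expect_lt(v3["d_cds3"], 0)
})

test_that("landmark encoding is strand-invariant for mirrored sites", {
  # mirror map: x -> 501 - x, so site 160 on + mirrors to 341 on -
  v_plus <- encode_landmark_tx(tx1(), 160L)
  v_minus <- encode_landmark_tx(tx1_minus(), 501L - 160L)
  expect_equal(v_plus, v_minus)
})

test_that("landmark exon additivity holds on random sites", {
  set.seed(3)
  for (i in 1:20) {
    tx <- random_tx()
    ex <- tx$exons
    j <- sample(nrow(ex), 1L)
    site <- sample(ex$start[j]:ex$end[j], 1L)
    v <- encode_landmark_tx(tx, site)
    expect_equal(unname(v["d_exon5"] + v["d_exon3"] + 1),
                 ex$end[j] - ex$start[j] + 1)
    expect_equal(unname(v["d_tx5"] + v["d_tx3"] + 1), tx_width(tx))
    if (!is.null(tx$cds)) expect_equal(v, landmark_oracle(tx, site),
                                       ignore_attr = TRUE)
  }
})

test_that("non-coding transcripts carry zero CDS fields and has_cds = FALSE", {
  tx <- transcript_model("NC", "G", "c", "+", data.frame(start = 1L, end = 100L))
  v <- encode_landmark_tx(tx, 50L)
  expect_equal(unname(v[c("d_cds5", "d_cds3")]), c(0, 0))
  expect_false(attr(v, "has_cds"))
  expect_length(v, 6L)
})

test_that("grid encoding reproduces the per-nucleotide counting oracle", {
  g <- encode_grid_tx(tx1(), 160L, G = 3L)
  expect_equal(dim(g), c(3L, 7L))
  expect_equal(unname(g[1, ]), c(1, 0, 0.5, 0.5, 0, log(101), 1))
  expect_equal(unname(g[2, ]), c(0, 1, 0, 0, 0, log(101), 0))
  expect_equal(unname(g[3, ]), c(1, 0, 0.5, 0, 0.5, log(101), 0))
})

test_that("grid G=1 gives whole-transcript composition with target flagged", {
  g <- encode_grid_tx(tx1(), 160L, G = 1L)
  expect_equal(nrow(g), 1L)
  expect_equal(unname(g[1, "frac_exon"]), 200 / 300)
  expect_equal(unname(g[1, "frac_cds"]), 100 / 300)
  expect_equal(unname(g[1, "target"]), 1)
})

test_that("grid rows always satisfy frac_exon + frac_intron = 1", {
  set.seed(5)
  for (i in 1:15) {
    tx <- random_tx()
    ex <- tx$exons
    site <- sample(ex$start[1]:ex$end[1], 1L)
    G <- sample(2:20, 1L)
    g <- encode_grid_tx(tx, site, G = G)
    expect_equal(unname(g[, "frac_exon"] + g[, "frac_intron"]), rep(1, G))
    expect_true(all(g[, "frac_cds"] + g[, "frac_utr5"] + g[, "frac_utr3"]
                    <= g[, "frac_exon"] + 1e-12))
    expect_gte(sum(g[, "target"]), 1)
  }
})

test_that("grid at fragment width one equals the one-hot region indicators", {
  set.seed(9)
  for (i in 1:10) {
    tx <- random_tx(max_exons = 4L)
    ex <- tx$exons
    site <- sample(ex$start[1]:ex$end[1], 1L)
    L <- tx_width(tx)
    g <- encode_grid_tx(tx, site, G = L)
    # wide one-hot window covering the whole span
    W <- 2L * L + 1L
    oh <- encode_onehot_region(tx, site, W)
    tp <- map_coordinate(tx, site, "unspliced")
    offset <- tp - ((W - 1L) %/% 2L) - 1L  # tpos p sits at one-hot row p - offset
    rows <- seq_len(L) - offset
    expect_equal(unname(g[, 1:5]), unname(oh[rows, ]))
    expect_equal(which(g[, "target"] == 1), tp)
  }
})

test_that("grid errors when G exceeds the transcript width", {
  expect_error(encode_grid_tx(tx1(), 160L, G = 1000L), "one-hot")
})

test_that("chunk encoding centers the target and pads/trims as specified", {
  ch <- encode_chunk_tx(tx1(), 160L, C = 7L)
  expect_equal(dim(ch), c(7L, 7L))
  # row 1 pad; rows 2..7: utr5 w50, cds w9, TARGET cds w1, cds w40,
  # intron w100, cds w50; the trailing utr3 run is trimmed
  expect_equal(unname(ch[1, ]), rep(0, 7))
  w <- function(x) round(exp(x) - 1)
  expect_equal(w(ch[2:7, "log_width"]), c(50, 9, 1, 40, 100, 50))
  expect_equal(unname(ch[, "target"]), c(0, 0, 0, 1, 0, 0, 0))
  expect_equal(unname(ch[2, "utr5"]), 1)
  expect_equal(unname(ch[3, "cds"]), 1)
  expect_equal(unname(ch[6, "intron"]), 1)
  expect_true(attr(ch, "trimmed"))
})

test_that("default chunk encoding has 245 entries with 7 populated rows", {
  ch <- encode_chunk_tx(tx1(), 160L, C = 35L)
  expect_equal(length(ch), 245L)
  pop <- rowSums(abs(ch[, 1:5])) > 0
  expect_equal(sum(pop), 7L)
  expect_equal(which(ch[, "target"] == 1), 18L)  # center row of 35
  expect_false(attr(ch, "trimmed"))
})

test_that("single-run transcript with C=3 puts the only target row at center", {
  tx <- transcript_model("T", "G", "c", "+", data.frame(start = 10L, end = 10L))
  ch <- encode_chunk_tx(tx, 10L, C = 3L)
  expect_equal(unname(ch[, "target"]), c(0, 1, 0))
  expect_equal(unname(ch[1, ]), rep(0, 7))
  expect_equal(unname(ch[3, ]), rep(0, 7))
})

test_that("chunk encoding is strand-invariant for mirrored sites", {
  a <- encode_chunk_tx(tx1(), 160L, C = 35L)
  b <- encode_chunk_tx(tx1_minus(), 501L - 160L, C = 35L)
  expect_equal(unclass(a)[, ], unclass(b)[, ])
})

test_that("decode inverts encode on the fixture", {
  lay <- decode_chunk_tx(encode_chunk_tx(tx1(), 160L, C = 35L))
  expect_equal(nrow(lay), 7L)
  expect_equal(lay$width, c(50L, 9L, 1L, 40L, 100L, 50L, 50L))
  expect_equal(lay$target, c(0L, 0L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(lay$utr5, c(1L, 0L, 0L, 0L, 0L, 0L, 0L))
  expect_equal(lay$utr3, c(0L, 0L, 0L, 0L, 0L, 0L, 1L))
  expect_false(attr(lay, "truncated"))
})

test_that("decode of an all-zero matrix is an empty layout", {
  m <- structure(matrix(0, 35, 7,
                        dimnames = list(NULL, c("exon", "intron", "cds",
                                                "utr5", "utr3", "log_width",
                                                "target"))),
                 class = c("chunk_matrix", "matrix", "array"))
  expect_equal(nrow(decode_chunk_tx(m)), 0L)
})

test_that("decode-encode identity holds over random transcripts", {
  set.seed(21)
  for (i in 1:40) {
    tx <- random_tx(max_exons = 6L)
    ex <- tx$exons
    j <- sample(nrow(ex), 1L)
    site <- sample(ex$start[j]:ex$end[j], 1L)
    ch <- encode_chunk_tx(tx, site, C = 35L)
    if (attr(ch, "trimmed")) next
    lay <- decode_chunk_tx(ch)
    tsp <- map_coordinate(tx, site, "unspliced")
    ref <- geotx:::.split_runs_at_target(tx, c(tsp, tsp))
    expect_equal(lay$width, ref$width)
    expect_equal(lay$target, ref$target)
    expect_equal(lay$exon, ref$exon)
    expect_equal(lay$cds, ref$cds)
  }
})

test_that("one-hot region window is classified per nucleotide", {
  oh <- encode_onehot_region(tx1(), 160L, W = 5L)
  expect_equal(dim(oh), c(5L, 5L))
  for (r in 1:5) expect_equal(unname(oh[r, ]), c(1, 0, 1, 0, 0))
  expect_equal(length(encode_onehot_region(tx1(), 160L, W = 101L)), 505L)
  expect_equal(length(encode_onehot_region(tx1(), 160L, W = 251L)), 1255L)
  # out-of-span rows are zero
  oh2 <- encode_onehot_region(tx1(), 102L, W = 7L)
  expect_equal(unname(oh2[1:2, ]), matrix(0, 2, 5))
})

test_that("one-hot sequence encoding handles strand and N", {
  genome <- c(c1 = "AANGGACTTT")
  oh <- encode_onehot_seq(genome, "c1", 6L, "+", W = 5L)
  expect_equal(colnames(oh), c("A", "C", "G", "U"))
  # window 4..8 = G G A C T
  expect_equal(unname(rowSums(oh)), c(1, 1, 1, 1, 1))
  expect_equal(unname(oh[3, ]), c(1, 0, 0, 0))
  expect_equal(unname(oh[5, ]), c(0, 0, 0, 1))  # T read as U
  # N gives an all-zero row
  ohn <- encode_onehot_seq(genome, "c1", 3L, "+", W = 3L)
  expect_equal(unname(ohn[2, ]), c(0, 0, 0, 0))
  # minus strand: reverse complement of G G A C T -> A G U C C
  ohm <- encode_onehot_seq(genome, "c1", 6L, "-", W = 5L)
  expect_equal(unname(ohm[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(ohm[3, ]), c(0, 0, 0, 1))
  expect_equal(unname(ohm[5, ]), c(0, 1, 0, 0))
  expect_true(all(rowSums(ohm) <= 1))
})

test_that("read truncation crops boundary chunks and zeroes uncovered ones", {
  ch <- encode_chunk_tx(tx1(), 160L, C = 7L)
  full <- truncate_to_read(ch, 101L, 400L)
  expect_equal(unclass(full)[, ], unclass(ch)[, ])

  tr <- truncate_to_read(ch, 151L, 250L)
  w <- function(x) round(exp(x) - 1)
  expect_equal(unname(tr[2, ]), rep(0, 7))          # utr5 row zeroed
  expect_equal(unname(w(tr[6, "log_width"])), 50)   # intron cropped to 201-250
  expect_equal(unname(tr[, "target"]), c(0, 0, 0, 1, 0, 0, 0))
  expect_true(attr(tr, "target_covered"))

  off <- truncate_to_read(ch, 351L, 400L)
  expect_equal(sum(off[, "target"]), 0)
  expect_false(attr(off, "target_covered"))
})

test_that("isoform bags contain one encoding per overlapping isoform", {
  models <- list(TX1 = tx1(), TX1S = tx1_short())
  bag <- build_bag("c1", 160L, "+", models, encoder = "chunk", C = 35L)
  expect_s3_class(bag, "isoform_bag")
  expect_length(bag$members, 2L)
  expect_setequal(names(bag$members), c("TX1", "TX1S"))
  expect_error(build_bag("c1", 50L, "+", models), "no isoform")
})

test_that("read bags are padded or down-sampled to exactly 20 members", {
  tx <- tx1()
  spans7 <- data.frame(start = 101L + 0:6 * 10L, end = 200L + 0:6 * 10L)
  bag <- build_read_bag(tx, 160L, spans7, bag_size = 20L, C = 35L)
  expect_length(bag$members, 20L)
  expect_equal(sum(bag$real), 7L)
  expect_true(all(vapply(bag$members[!bag$real], function(m) all(m == 0), logical(1))))

  spans50 <- data.frame(start = rep(101L, 50L), end = 101L + seq_len(50L) * 5L)
  b1 <- build_read_bag(tx, 160L, spans50, seed = 9L)
  b2 <- build_read_bag(tx, 160L, spans50, seed = 9L)
  expect_identical(lapply(b1$members, function(m) unclass(m)[, ]),
                   lapply(b2$members, function(m) unclass(m)[, ]))
  expect_equal(sum(b1$real), 20L)
})
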