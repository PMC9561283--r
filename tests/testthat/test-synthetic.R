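small_cfg <- function(...) sim_config(n_genes = 30L, n_sites = NULL, seed = 11L, ...)

test_that("emitted GTF re-parses to the generated models", {
  cfg <- sim_config(n_genes = 3L, seed = 2L)
  ann <- simulate_annotation(cfg)
  path <- tempfile(fileext = ".gtf")
  write_gtf(ann$models, path)
  back <- parse_annotation(path)
  expect_setequal(names(back), names(ann$models))
  for (id in names(ann$models)) {
    a <- ann$models[[id]]; b <- back[[id]]
    expect_equal(b$exons, a$exons)
    expect_equal(b$cds, a$cds)
    expect_equal(b$strand, a$strand)
    expect_equal(b$gene_id, a$gene_id)
  }
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_annotation(sim_config(n_genes = 5L, seed = 9L))
  b <- simulate_annotation(sim_config(n_genes = 5L, seed = 9L))
  expect_identical(a$genome, b$genome)
  expect_identical(a$models, b$models)
  p1 <- tempfile(); p2 <- tempfile()
  write_gtf(a$models, p1); write_gtf(b$models, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generated models satisfy all transcript invariants", {
  ann <- simulate_annotation(small_cfg())
  genes <- split(names(ann$models),
                 vapply(ann$models, function(m) m$gene_id, character(1)))
  for (tx in ann$models) {
    runs <- decompose_regions(tx)
    expect_equal(sum(runs$width), tx_width(tx))
    expect_true(all(runs$exon + runs$intron == 1L))
    if (!is.null(tx$cds)) {
      for (p in tx$cds)
        expect_true(any(p >= tx$exons$start & p <= tx$exons$end))
    }
  }
  # isoforms of a gene share at least one exon
  for (ids in genes) {
    if (length(ids) < 2L) next
    key <- function(tx) paste(tx$exons$start, tx$exons$end, sep = "-")
    shared <- Reduce(intersect, lapply(ann$models[ids], key))
    expect_gte(length(shared), 1L)
  }
  # genome FASTA round-trips
  fp <- tempfile(fileext = ".fa")
  write_genome_fasta(ann$genome, fp)
  expect_identical(read_genome_fasta(fp), ann$genome)
})

test_that("DRACH scan matches a regex oracle including overlaps", {
  expect_equal(scan_drach("GGACU"), 3L)
  expect_equal(scan_drach("CCCCC"), integer(0))
  set.seed(10)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE), collapse = "")
  got <- scan_drach(s)
  hits <- gregexpr("(?=[AGT][AG]AC[ACT])", s, perl = TRUE)[[1]]
  want <- if (hits[1] == -1L) integer(0) else as.integer(hits) + 2L
  expect_equal(got, want)
})

test_that("planted sites sit on DRACH motifs of their transcript", {
  cfg <- small_cfg()
  d <- simulate_dataset(cfg)
  expect_true(all(d$sites$label %in% 0:1))
  idx <- sample(nrow(d$sites), 25L)
  for (i in idx) {
    tx <- d$models[[d$sites$tx_id[i]]]
    tpos <- map_coordinate(tx, d$sites$gpos[i], "spliced")
    expect_false(is.na(tpos))
    sseq <- tx_sequence(d$genome, tx)
    expect_true(tpos %in% scan_drach(sseq))
    expect_equal(substr(sseq, tpos, tpos), "A")
  }
})

test_that("null effect sizes give a near-baseline positive rate and no geography signal", {
  cfg <- small_cfg(beta = c(-1, 0, 0, 0), seq_effect = 0)
  ann <- simulate_annotation(cfg)
  pl <- plant_sites(ann$models, ann$genome, cfg)
  # before ratio-subsampling the per-candidate rate is logistic(-1);
  # check via the geography features: positives look like negatives
  s <- pl$sites
  expect_gt(nrow(s), 100)
  p_last_pos <- mean(s$last_exon[s$label == 1])
  p_last_neg <- mean(s$last_exon[s$label == 0])
  expect_lt(abs(p_last_pos - p_last_neg), 0.1)
})

test_that("a strong last-exon effect enriches positives in last exons", {
  cfg <- sim_config(n_genes = 60L, n_sites = NULL, seed = 11L,
                    beta = c(-2, 3, 0, 0), seq_effect = 0)
  ann <- simulate_annotation(cfg)
  pl <- plant_sites(ann$models, ann$genome, cfg)
  s <- pl$sites
  n1 <- sum(s$label == 1); n0 <- sum(s$label == 0)
  p1 <- mean(s$last_exon[s$label == 1]); p0 <- mean(s$last_exon[s$label == 0])
  pp <- (p1 * n1 + p0 * n0) / (n1 + n0)
  z <- (p1 - p0) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n0))
  expect_gt(z, 3)
})

test_that("logistic fit on the true features recovers the planted signs", {
  cfg <- sim_config(n_genes = 250L, n_sites = NULL, seed = 4L, seq_effect = 0)
  ann <- simulate_annotation(cfg)
  pl <- plant_sites(ann$models, ann$genome, cfg)
  s <- pl$sites
  s$stopf <- exp(-s$d_stop / cfg$tau)
  fit <- stats::glm(label ~ last_exon + log(exon_width) + stopf,
                    family = stats::binomial(), data = s)
  co <- stats::coef(fit)
  expect_gt(co[["last_exon"]], 0)
  expect_gt(co[["log(exon_width)"]], 0)
  expect_gt(co[["stopf"]], 0)
})

test_that("positive:negative ratio and upsampling are honored", {
  cfg <- small_cfg(neg_per_pos = 2L)
  d <- simulate_dataset(cfg)
  n1 <- sum(d$sites$label == 1)
  expect_equal(sum(d$sites$label == 0), 2L * n1)
  d10 <- simulate_dataset(small_cfg(), upsample_pos = 10L)
  base <- simulate_dataset(small_cfg())
  expect_equal(sum(d10$sites$label == 1), 10L * sum(base$sites$label == 1))
  expect_equal(sum(d10$sites$label == 0), sum(base$sites$label == 0))
})

test_that("simulated technique sets reproduce expected consistency levels", {
  truth <- paste0("c:", 1:10000, ":+")
  universe <- paste0("c:", 1:40000, ":+")
  perfect <- simulate_technique_sets(truth, universe, 2L, sensitivity = 1,
                                     fp_rate = 0, seed = 1L)
  m <- pairwise_consistency(perfect)
  expect_equal(unname(m[2, 1]), 100)
  half <- simulate_technique_sets(truth, universe, 2L, sensitivity = 0.5,
                                  fp_rate = 0, seed = 2L)
  mh <- pairwise_consistency(half)
  expect_lt(abs(unname(mh[2, 1]) - 50), 2)
  fp_only <- simulate_technique_sets(character(0), universe, 2L,
                                     sensitivity = 1, fp_rate = 0.02, seed = 3L)
  mf <- pairwise_consistency(fp_only)
  expect_lt(unname(mf[2, 1]), 10)
})

test_that("read bags respect stoichiometry and the Noisy-OR closed form", {
  cfg <- small_cfg()
  d <- simulate_dataset(cfg)
  sites <- d$sites[1:20, ]
  rb1 <- simulate_read_bags(sites, d$models, stoichiometry = 1, seed = 5L)
  for (r in rb1[sites$label == 1]) {
    expect_true(all(r$reads$modified == 1L))
    expect_equal(noisy_or(r$reads$modified), 1)
  }
  rb0 <- simulate_read_bags(sites, d$models, stoichiometry = 0, seed = 5L)
  for (r in rb0) if (r$label == 1) expect_equal(noisy_or(r$reads$modified), 0)
  for (r in rb0[sites$label == 0]) expect_true(all(r$reads$modified == 0L))
  # spans stay inside the transcript
  for (r in rb1) {
    tx <- d$models[[r$tx_id]]
    expect_true(all(r$reads$start >= tx$tx_start))
    expect_true(all(r$reads$end <= tx$tx_end))
  }
})
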