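# Synthetic annotation, genome, site and technique-set generator. The
# generator emulates the statistical structure the analyses assume:
# multi-isoform genes with exon/intron/CDS/UTR structure, DRACH candidate
# sites, and positives planted with a geographic preference for long exons,
# last exons and stop-codon proximity via a logistic model. Everything is
# reproducible under one seed.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions used throughout the package tests:
#' 800 genes with 1-5 isoforms each, lognormal exon (median 150 nt) and
#' intron (median 300 nt) widths, DRACH candidates planted about every 75
#' exonic nt, and positives drawn from a logistic model of transcript
#' geography, `P(pos) = logistic(b0 + b_last * lastExon + b_logw *
#' log(exonWidth/150) + b_stop * exp(-distToStop/tau))`, with effect sizes
#' calibrated so that geography alone carries a Bayes AUC of roughly 0.8.
#' Half of the positives additionally carry the canonical GGACU motif
#' (`seq_effect`), giving the sequence channel independent but weaker
#' signal. `beta = c(0, 0, 0, 0)` (keeping `b0`) produces geography-free
#' labels.
#'
#' @param n_genes Number of genes.
#' @param n_sites Total number of labeled sites to emit (positives +
#'   negatives); `NULL` keeps every positive.
#' @param neg_per_pos Negative:positive ratio (1 for balanced training, 10
#'   for independent testing).
#' @param isoform_probs Probabilities of 1-5 isoforms per gene.
#' @param exon_count_range Range of exon numbers per gene.
#' @param beta Effect sizes `c(b0, b_lastexon, b_logexonwidth, b_stopdist)`.
#' @param tau Stop-distance decay scale in nt.
#' @param seq_effect Probability that a positive site's motif is rewritten to
#'   the canonical GGACU.
#' @param drach_spacing Mean exonic nt between planted DRACH candidates.
#' @param major_isoform_prob Probability that the longest isoform is the one
#'   carrying (generating) a site.
#' @param p_coding Probability that an isoform is coding.
#' @param seed Integer seed.
#' @return Config list.
#' @export
sim_config <- function(n_genes = 800L, n_sites = 4000L, neg_per_pos = 1L,
                       isoform_probs = c(0.35, 0.25, 0.2, 0.12, 0.08),
                       exon_count_range = c(2L, 8L),
                       beta = c(-3.5, 2.0, 0.9, 3.0), tau = 200,
                       seq_effect = 0.5, drach_spacing = 75L,
                       major_isoform_prob = 0.75, p_coding = 0.9,
                       seed = 1L) {
  as.list(environment())
}

.rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

.rand_drach <- function() paste0(sample(c("A", "G", "T"), 1L),
                                 sample(c("A", "G"), 1L), "A", "C",
                                 sample(c("A", "C", "T"), 1L))

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# write a transcript-orientation motif into a chromosome character vector
.write_motif <- function(chars, gpos, strand, motif) {
  m <- strsplit(motif, "")[[1]]
  h <- (length(m) - 1L) %/% 2L
  if (strand == "+") chars[(gpos - h):(gpos + h)] <- m
  else chars[(gpos + h):(gpos - h)] <- .COMP[m]
  chars
}

#' Simulate transcript annotation and genome sequence
#'
#' Genes are laid out along one synthetic chromosome with random intergenic
#' gaps. Each gene gets a full-length isoform plus up to four derived
#' isoforms (3'-truncations or single internal exon skips), so isoforms of a
#' gene always share exons. Coding isoforms receive a CDS placed at 10-20%
#' to 60-85% of the spliced length. DRACH candidate motifs are planted in
#' exonic sequence at the configured spacing.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return List with `models` (named list of [transcript_model()]) and
#'   `genome` (named character vector of chromosome sequences).
#' @export
simulate_annotation <- function(config = sim_config(), seed = config$seed) {
  .with_seed(seed, {
    segs <- character(0)   # ordered chromosome segments
    models <- list()
    cursor <- 1L
    for (g in seq_len(config$n_genes)) {
      gap <- sample(500:1500, 1L)
      segs <- c(segs, .rand_seq(gap))
      gstart <- cursor + gap
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(config$exon_count_range[1]:config$exon_count_range[2], 1L)
      ew <- pmin(pmax(round(rlnorm(n_ex, log(150), 0.6)), 30L), 1500L)
      iw <- if (n_ex > 1L) pmin(pmax(round(rlnorm(n_ex - 1L, log(300), 0.7)),
                                     60L), 3000L) else integer(0)
      es <- integer(n_ex); ee <- integer(n_ex)
      cur <- gstart
      for (i in seq_len(n_ex)) {
        es[i] <- cur; ee[i] <- cur + ew[i] - 1L
        cur <- ee[i] + 1L + if (i < n_ex) iw[i] else 0L
      }
      glen <- cur - gstart
      gchars <- strsplit(.rand_seq(glen), "")[[1]]
      # plant DRACH candidates in exons (transcript-strand orientation)
      for (i in seq_len(n_ex)) {
        n_mot <- max(1L, rpois(1L, ew[i] / config$drach_spacing))
        if (ew[i] < 11L) next
        at <- sample((es[i] + 3L):(ee[i] - 3L), min(n_mot, ew[i] %/% 6L))
        for (p in at) gchars <- .write_motif(gchars, p - gstart + 1L, strand,
                                             .rand_drach())
      }
      segs <- c(segs, paste(gchars, collapse = ""))
      cursor <- cur
      gene_id <- sprintf("G%04d", g)
      n_iso <- sample(1:5, 1L, prob = config$isoform_probs)
      exon_sets <- list(seq_len(n_ex))  # isoform 1: all exons
      if (n_iso > 1L) for (k in 2:n_iso) {
        if (n_ex >= 3L && runif(1) < 0.3) {
          drop_ex <- sample(2:(n_ex - 1L), 1L)   # internal exon skip
          exon_sets[[k]] <- setdiff(seq_len(n_ex), drop_ex)
        } else if (n_ex >= 2L) {
          j <- sample(seq_len(n_ex - 1L), 1L)    # alternative termination
          exon_sets[[k]] <- if (strand == "+") seq_len(j) else (n_ex - j + 1L):n_ex
        } else exon_sets[[k]] <- 1L
      }
      exon_sets <- unique(exon_sets)
      for (k in seq_along(exon_sets)) {
        idx <- exon_sets[[k]]
        tx_id <- sprintf("%s.T%d", gene_id, k)
        tmp <- transcript_model(tx_id, gene_id, "chr1", strand,
                                data.frame(start = es[idx], end = ee[idx]))
        cds <- NULL
        sl <- spliced_length(tmp)
        if (sl >= 200L && runif(1) < config$p_coding) {
          a <- max(1L, round(runif(1, 0.10, 0.20) * sl))
          b <- min(sl, round(runif(1, 0.60, 0.85) * sl))
          if (b - a >= 60L)
            cds <- sort(tx_to_genome(tmp, c(a, b), "spliced"))
        }
        models[[tx_id]] <- transcript_model(tx_id, gene_id, "chr1", strand,
                                            data.frame(start = es[idx],
                                                       end = ee[idx]), cds)
      }
    }
    genome <- c(chr1 = paste(segs, collapse = ""))
    list(models = models, genome = genome)
  })
}

#' Write transcript models as GTF
#'
#' @param models Named list of `transcript_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(tx) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', tx$gene_id, tx$tx_id)
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    out <- sprintf("%s\tgeotx\texon\t%d\t%d\t.\t%s\t.\t%s",
                   tx$chrom, ex$start, ex$end, tx$strand, attrs)
    if (!is.null(tx$cds)) {
      runs <- decompose_regions(tx)
      cr <- runs[runs$cds == 1L, , drop = FALSE]
      out <- c(out, sprintf("%s\tgeotx\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                            tx$chrom, cr$start, cr$end, tx$strand, attrs))
    }
    out
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*", "", names(ss)))
}

#' Spliced or unspliced sequence of a transcript
#'
#' @param genome Named character vector of chromosome sequences.
#' @param tx A `transcript_model`.
#' @param spliced Excise introns (default) or keep the full span.
#' @return Character scalar, 5' to 3' in transcript orientation (DNA
#'   alphabet).
#' @export
tx_sequence <- function(genome, tx, spliced = TRUE) {
  s <- genome[[tx$chrom]]
  if (spliced) {
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    seqs <- vapply(seq_len(nrow(ex)), function(i)
      substr(s, ex$start[i], ex$end[i]), character(1))
    out <- paste(seqs, collapse = "")
  } else {
    out <- substr(s, tx$tx_start, tx$tx_end)
  }
  if (tx$strand == "-")
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(out)))
  out
}

#' Positions of DRACH motif centers in a sequence
#'
#' Scans for the m6A consensus DRACH (D = A/G/U, R = A/G, then the
#' methylatable A, C, H = A/C/U) and reports the 1-based position of the
#' central A of every (possibly overlapping) match. U and T are equivalent.
#'
#' @param x Character sequence (DNA or RNA alphabet).
#' @return Integer vector of A positions.
#' @export
scan_drach <- function(x) {
  x <- chartr("Uu", "Tt", x)
  m <- Biostrings::matchPattern("DRACH", Biostrings::DNAString(toupper(x)),
                                fixed = FALSE)
  as.integer(Biostrings::start(m)) + 2L
}

#' Plant labeled modification sites on DRACH candidates
#'
#' For each gene one generating isoform is chosen (the longest with
#' probability `major_isoform_prob`). Its spliced sequence is scanned for
#' DRACH candidates, and each candidate is labeled positive with probability
#' `logistic(b0 + b_last*lastExon + b_logw*log(w/150) + b_stop*exp(-d/tau))`
#' computed from the candidate's geography on the generating isoform.
#' Negatives are sampled from the remaining candidates of the same
#' transcripts at `neg_per_pos` per positive. A fraction `seq_effect` of the
#' positives has its motif rewritten to the canonical GGACU in the genome.
#'
#' @param models Named list of `transcript_model` objects (isoforms grouped
#'   by `gene_id`).
#' @param genome Named character vector of chromosome sequences.
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @param upsample_pos Replicate positives this many times in the returned
#'   table (10 for imbalanced training sets; labels only, the genome is
#'   edited once).
#' @return List with `sites` (data.frame: chrom, gpos, strand, label, tx_id,
#'   motif, last_exon, exon_width, d_stop) and the (possibly motif-edited)
#'   `genome`.
#' @export
plant_sites <- function(models, genome, config = sim_config(),
                        seed = config$seed, upsample_pos = 1L) {
  .with_seed(seed, {
    b <- config$beta
    by_gene <- split(models, vapply(models, function(m) m$gene_id, character(1)))
    rows <- list()
    for (iso_list in by_gene) {
      iso_list <- unname(iso_list)
      len <- vapply(iso_list, spliced_length, integer(1))
      ids <- vapply(iso_list, function(m) m$tx_id, character(1))
      longest <- order(-len, ids)[1]
      gen <- if (length(iso_list) == 1L || runif(1) < config$major_isoform_prob)
        longest else sample(setdiff(seq_along(iso_list), longest), 1L)
      tx <- iso_list[[gen]]
      sseq <- tx_sequence(genome, tx, spliced = TRUE)
      cand <- scan_drach(sseq)
      if (length(cand) == 0L) next
      gpos <- tx_to_genome(tx, cand, "spliced")
      ex <- tx$exons # 5'->3'
      exi <- vapply(gpos, function(p) which(p >= pmin(ex$start, ex$end) &
                                            p <= pmax(ex$start, ex$end))[1],
                    integer(1))
      w <- ex$end[exi] - ex$start[exi] + 1L
      last_ex <- as.integer(exi == nrow(ex))
      if (!is.null(tx$cds)) {
        stop_g <- if (tx$strand == "+") tx$cds[2] else tx$cds[1]
        stop_t <- map_coordinate(tx, stop_g, "spliced")
        d_stop <- abs(cand - stop_t)
      } else d_stop <- rep(Inf, length(cand))
      eta <- b[1] + b[2] * last_ex + b[3] * (log(w) - log(150)) +
        b[4] * exp(-d_stop / config$tau)
      label <- rbinom(length(cand), 1L, plogis(eta))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, gpos = gpos, strand = tx$strand, label = label,
        tx_id = tx$tx_id,
        motif = substr(sseq, cand - 2L, cand + 2L),
        last_exon = last_ex, exon_width = w, d_stop = d_stop,
        stringsAsFactors = FALSE)
    }
    sites <- do.call(rbind, rows)
    pos <- sites[sites$label == 1L, , drop = FALSE]
    neg <- sites[sites$label == 0L, , drop = FALSE]
    n_pos <- nrow(pos)
    if (!is.null(config$n_sites)) {
      want_pos <- round(config$n_sites / (1 + config$neg_per_pos))
      if (want_pos < n_pos) {
        pos <- pos[sample.int(n_pos, want_pos), , drop = FALSE]
        n_pos <- want_pos
      }
    }
    want_neg <- n_pos * config$neg_per_pos
    if (nrow(neg) < want_neg)
      stop("only ", nrow(neg), " negative candidates for ", want_neg,
           " requested; increase n_genes or lower neg_per_pos")
    neg <- neg[sample.int(nrow(neg), want_neg), , drop = FALSE]
    # strengthen the canonical motif on a fraction of positives
    flip <- runif(nrow(pos)) < config$seq_effect
    if (any(flip)) {
      chars <- strsplit(genome[["chr1"]], "")[[1]]
      for (i in which(flip)) {
        chars <- .write_motif(chars, pos$gpos[i], pos$strand[i], "GGACT")
        pos$motif[i] <- "GGACT"
      }
      genome[["chr1"]] <- paste(chars, collapse = "")
    }
    if (upsample_pos > 1L)
      pos <- pos[rep(seq_len(nrow(pos)), upsample_pos), , drop = FALSE]
    sites <- rbind(pos, neg)
    sites <- sites[sample.int(nrow(sites)), , drop = FALSE]
    rownames(sites) <- NULL
    list(sites = sites, genome = genome)
  })
}

#' Geographic features of a site on one isoform
#'
#' The three geographic covariates of the planting model, computed for a
#' genomic position against a given isoform: whether the containing exon is
#' the last exon, the containing exon width, and the spliced distance to the
#' stop codon (`Inf` for non-coding isoforms).
#'
#' @param tx A `transcript_model`.
#' @param gpos Genomic position (must be exonic on `tx`).
#' @return List with `last_exon`, `exon_width`, `d_stop`.
#' @export
site_geography <- function(tx, gpos) {
  ex <- tx$exons
  i <- which(gpos >= ex$start & gpos <= ex$end)[1]
  if (is.na(i)) stop("position ", gpos, " is not exonic on ", tx$tx_id)
  d_stop <- if (is.null(tx$cds)) Inf else {
    stop_g <- if (tx$strand == "+") tx$cds[2] else tx$cds[1]
    abs(map_coordinate(tx, gpos, "spliced") -
          map_coordinate(tx, stop_g, "spliced"))
  }
  list(last_exon = as.integer(i == nrow(ex)),
       exon_width = ex$end[i] - ex$start[i] + 1L,
       d_stop = d_stop)
}

#' Planted positive propensity of a site on one isoform
#'
#' Evaluates the generator's logistic linear predictor for a site's
#' geography on a given isoform. Used to identify, within an isoform bag,
#' which member(s) carry positive-preferring geography.
#'
#' @param tx A `transcript_model`.
#' @param gpos Genomic position.
#' @param config A [sim_config()] supplying `beta` and `tau`.
#' @return The linear predictor (log-odds scale).
#' @export
planted_score <- function(tx, gpos, config = sim_config()) {
  g <- site_geography(tx, gpos)
  b <- config$beta
  b[1] + b[2] * g$last_exon + b[3] * (log(g$exon_width) - log(150)) +
    b[4] * exp(-g$d_stop / config$tau)
}

#' Simulate isoform bags where exactly one member carries the signal
#'
#' A purified condition for the isoform-attention recovery experiment: DRACH
#' candidates are screened against every overlapping mature isoform, and a
#' candidate becomes a positive bag only when its planted positive
#' propensity (see [planted_score()]) is at least `p_hi` on exactly one
#' member isoform and at most `p_lo` on all others; negative bags have
#' propensity at most `p_lo` on every member. Labels are deterministic given
#' geography, so the signal-carrying isoform is well defined per bag. Only
#' multi-isoform bags are kept.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed`.
#' @param n_bags Total bags to return (balanced classes, subject to
#'   availability).
#' @param p_hi,p_lo Propensity cutoffs defining signal-carrying and
#'   background members.
#' @return List with `models`, `genome`, and `sites` (data.frame with
#'   `chrom`, `gpos`, `strand`, `label` and the signal-carrying `tx_id` for
#'   positives).
#' @export
simulate_isoform_signal_bags <- function(config = sim_config(),
                                         seed = config$seed, n_bags = 1000L,
                                         p_hi = 0.7, p_lo = 0.3) {
  ann <- simulate_annotation(config, seed = seed)
  .with_seed(seed + 2L, {
    spans <- .model_spans(ann$models)
    by_gene <- split(names(ann$models),
                     vapply(ann$models, function(m) m$gene_id, character(1)))
    pos_rows <- list(); neg_rows <- list()
    for (ids in by_gene) {
      if (length(ids) < 2L) next
      cand_g <- unique(unlist(lapply(ids, function(id) {
        tx <- ann$models[[id]]
        tpos <- scan_drach(tx_sequence(ann$genome, tx))
        tx_to_genome(tx, tpos, "spliced")
      })))
      for (gp in cand_g) {
        tx0 <- ann$models[[ids[1]]]
        members <- .mature_isoforms(tx0$chrom, gp, tx0$strand, ann$models, spans)
        if (length(members) < 2L) next
        p <- vapply(members, function(tx)
          plogis(planted_score(tx, gp, config)), numeric(1))
        hi <- which(p >= p_hi)
        if (length(hi) == 1L && all(p[-hi] <= p_lo)) {
          pos_rows[[length(pos_rows) + 1L]] <- data.frame(
            chrom = tx0$chrom, gpos = gp, strand = tx0$strand, label = 1L,
            tx_id = names(members)[hi], stringsAsFactors = FALSE)
        } else if (all(p <= p_lo)) {
          neg_rows[[length(neg_rows) + 1L]] <- data.frame(
            chrom = tx0$chrom, gpos = gp, strand = tx0$strand, label = 0L,
            tx_id = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
    pos <- do.call(rbind, pos_rows)
    neg <- do.call(rbind, neg_rows)
    if (is.null(pos) || is.null(neg))
      stop("no qualifying bags; increase n_genes")
    k <- min(nrow(pos), nrow(neg), n_bags %/% 2L)
    pos <- pos[sample.int(nrow(pos), k), , drop = FALSE]
    neg <- neg[sample.int(nrow(neg), k), , drop = FALSE]
    sites <- rbind(pos, neg)
    sites <- sites[sample.int(nrow(sites)), , drop = FALSE]
    rownames(sites) <- NULL
    list(models = ann$models, genome = ann$genome, sites = sites)
  })
}

#' Simulate technique-specific site sets from a ground truth
#'
#' Each technique reports each true site with probability `sensitivity` and
#' additionally reports each non-true universe site with probability
#' `fp_rate`.
#'
#' @param truth Character vector of true site keys (`chrom:pos:strand`).
#' @param universe Character vector of all candidate keys (superset of
#'   `truth`).
#' @param n_techniques Number of technique sets.
#' @param sensitivity,fp_rate Per-site detection and false-positive rates.
#' @param seed Integer seed.
#' @return List of `technique_set` objects.
#' @export
simulate_technique_sets <- function(truth, universe, n_techniques = 9L,
                                    sensitivity = 0.5, fp_rate = 0,
                                    seed = 1L) {
  if (sensitivity < 0 || sensitivity > 1 || fp_rate < 0 || fp_rate > 1)
    stop("rates must be in [0, 1]")
  .with_seed(seed, {
    bg <- setdiff(universe, truth)
    lapply(seq_len(n_techniques), function(i) {
      keep <- truth[runif(length(truth)) < sensitivity]
      fp <- bg[runif(length(bg)) < fp_rate]
      technique_set(sprintf("tech%02d", i), c(keep, fp))
    })
  })
}

#' Simulate read coverage for sites
#'
#' Draws a read count per site (Poisson, at least one read), read spans
#' around the site on the carrier transcript, and per-read modification
#' labels: Bernoulli(`stoichiometry`) for positive sites, 0 for negatives.
#'
#' @param sites Site data.frame from [plant_sites()].
#' @param models Named list of `transcript_model` objects.
#' @param mean_reads Mean reads per site (default 15).
#' @param stoichiometry Per-read modification probability on positive sites.
#' @param read_length Mean read length in nt.
#' @param seed Integer seed.
#' @return List of per-site records: `tx_id`, `gpos`, `label`, `reads`
#'   (data.frame start/end/modified).
#' @export
simulate_read_bags <- function(sites, models, mean_reads = 15, stoichiometry = 0.5,
                               read_length = 800L, seed = 1L) {
  .with_seed(seed, {
    lapply(seq_len(nrow(sites)), function(i) {
      tx <- models[[sites$tx_id[i]]]
      n <- max(1L, rpois(1L, mean_reads))
      len <- pmax(100L, round(rnorm(n, read_length, read_length / 4)))
      off <- round(runif(n, 0.1, 0.9) * len)
      start <- pmax(tx$tx_start, sites$gpos[i] - off)
      end <- pmin(tx$tx_end, start + len - 1L)
      modified <- if (sites$label[i] == 1L)
        rbinom(n, 1L, stoichiometry) else integer(n)
      list(tx_id = tx$tx_id, gpos = sites$gpos[i], label = sites$label[i],
           reads = data.frame(start = start, end = end, modified = modified))
    })
  })
}

#' One-call synthetic dataset: annotation, genome and labeled sites
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @param upsample_pos Passed to [plant_sites()].
#' @return List with `models`, `genome` (motif-edited), `sites`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed,
                             upsample_pos = 1L) {
  ann <- simulate_annotation(config, seed = seed)
  pl <- plant_sites(ann$models, ann$genome, config, seed = seed + 1L,
                    upsample_pos = upsample_pos)
  list(models = ann$models, genome = pl$genome, sites = pl$sites)
}
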