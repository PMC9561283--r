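# Assembly of model-ready datasets from labeled sites: chunk-encoded
# geography, one-hot sequence windows, and isoform bags.

# span index over the model list so per-site isoform lookup is vectorized
.model_spans <- function(models) {
  data.frame(
    chrom = vapply(models, function(m) m$chrom, character(1)),
    strand = vapply(models, function(m) m$strand, character(1)),
    start = vapply(models, function(m) m$tx_start, integer(1)),
    end = vapply(models, function(m) m$tx_end, integer(1)),
    stringsAsFactors = FALSE)
}

.mature_isoforms <- function(chrom, pos, strand, models, spans) {
  cand <- which(spans$chrom == chrom & spans$strand == strand &
                spans$start <= pos & spans$end >= pos)
  hit <- cand[vapply(cand, function(j) {
    ex <- models[[j]]$exons
    any(pos >= ex$start & pos <= ex$end)
  }, logical(1))]
  models[hit]
}

#' Stack a list of equal-shaped encoding matrices into a batch array
#'
#' @param mats List of `L x C` matrices.
#' @return `[n, L, C]` numeric array.
#' @export
stack_encodings <- function(mats) {
  d <- dim(mats[[1]])
  out <- array(0, c(length(mats), d[1], d[2]))
  for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
  out
}

#' Assemble a fixed-shape site dataset (one isoform per site)
#'
#' Encodes every site against one overlapping isoform chosen by `policy`
#' (the longest mature isoform by default), producing the chunk-encoded
#' geography and the one-hot sequence window consumed by the fixed-shape
#' models. Sites with no overlapping isoform are dropped (counted in the
#' `n_skipped` attribute).
#'
#' @param sites Site data.frame (`chrom`, `gpos`, `strand`, `label`).
#' @param models Named list of `transcript_model` objects.
#' @param genome Named character vector of chromosome sequences.
#' @param C Chunk rows (default 35).
#' @param W Sequence window (default 101).
#' @param policy Isoform selection policy, see [select_isoform()].
#' @param seed Seed for the `"random"` policy.
#' @return List `x_geo` (`[n, C, 7]`), `x_seq` (`[n, W, 4]`), `y`, `meta`
#'   (data.frame with the chosen isoform per site).
#' @export
assemble_site_dataset <- function(sites, models, genome, C = 35L, W = 101L,
                                  policy = "longest", seed = 1L) {
  geo <- vector("list", nrow(sites))
  seqm <- vector("list", nrow(sites))
  chosen <- character(nrow(sites))
  keep <- logical(nrow(sites))
  spans <- .model_spans(models)
  for (i in seq_len(nrow(sites))) {
    iso <- .mature_isoforms(sites$chrom[i], sites$gpos[i], sites$strand[i],
                            models, spans)
    if (length(iso) == 0L) next
    tx <- select_isoform(iso, policy, seed = seed + i)
    geo[[i]] <- encode_chunk_tx(tx, sites$gpos[i], C = C)
    seqm[[i]] <- encode_onehot_seq(genome, sites$chrom[i], sites$gpos[i],
                                   sites$strand[i], W = W)
    chosen[i] <- tx$tx_id
    keep[i] <- TRUE
  }
  out <- list(x_geo = stack_encodings(geo[keep]),
              x_seq = stack_encodings(seqm[keep]),
              y = sites$label[keep],
              meta = data.frame(site = which(keep), tx_id = chosen[keep],
                                stringsAsFactors = FALSE))
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Assemble an isoform-bag dataset for the attention MIL models
#'
#' One bag per site containing the chunk encodings of every overlapping
#' mature isoform plus the shared one-hot sequence window.
#'
#' @inheritParams assemble_site_dataset
#' @return List `bags` (each `list(geo = [m, C, 7], seq = [W, 4],
#'   tx_ids)`), `y`, `meta` (includes the generating isoform id when the
#'   sites table carries one).
#' @export
assemble_bag_dataset <- function(sites, models, genome, C = 35L, W = 101L) {
  bags <- vector("list", nrow(sites))
  keep <- logical(nrow(sites))
  tx_ids <- vector("list", nrow(sites))
  spans <- .model_spans(models)
  for (i in seq_len(nrow(sites))) {
    iso <- .mature_isoforms(sites$chrom[i], sites$gpos[i], sites$strand[i],
                            models, spans)
    if (length(iso) == 0L) next
    encs <- lapply(iso, function(tx) encode_chunk_tx(tx, sites$gpos[i], C = C))
    bags[[i]] <- list(
      geo = stack_encodings(encs),
      seq = unclass(encode_onehot_seq(genome, sites$chrom[i], sites$gpos[i],
                                      sites$strand[i], W = W))[, ],
      tx_ids = names(iso))
    tx_ids[[i]] <- names(iso)
    keep[i] <- TRUE
  }
  meta <- data.frame(site = which(keep), stringsAsFactors = FALSE)
  if (!is.null(sites$tx_id)) meta$generating <- sites$tx_id[keep]
  meta$n_isoforms <- lengths(tx_ids[keep])
  out <- list(bags = bags[keep], y = sites$label[keep], meta = meta)
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Assemble a read-bag dataset for the Noisy-OR read model
#'
#' @param read_sites Output of [simulate_read_bags()].
#' @param models Named list of `transcript_model` objects.
#' @param bag_size Reads per bag after padding/down-sampling (default 20).
#' @param C Chunk rows.
#' @param seed Down-sampling seed.
#' @return List `bags` (each `list(geo = [bag_size, C, 7], real)`), `y`.
#' @export
assemble_read_dataset <- function(read_sites, models, bag_size = 20L, C = 35L,
                                  seed = 1L) {
  bags <- lapply(seq_along(read_sites), function(i) {
    rs <- read_sites[[i]]
    rb <- build_read_bag(models[[rs$tx_id]], rs$gpos, rs$reads,
                         bag_size = bag_size, C = C, seed = seed + i)
    list(geo = stack_encodings(rb$members), real = rb$real)
  })
  list(bags = bags, y = vapply(read_sites, function(r) r$label, integer(1)))
}
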