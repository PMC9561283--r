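# Format boundaries. BED input is 0-based half-open and converted to the
# internal 1-based inclusive convention on read; GTF is read natively
# 1-based. Encoded datasets are serialized as RDS with their encoder
# parameters attached.

#' Read single-nucleotide sites from BED6
#'
#' Each record must span one nucleotide (or its start is taken as the site)
#' and carry a strand. BED is 0-based half-open; the returned positions are
#' 1-based.
#'
#' @param path BED file path.
#' @return Data.frame with `chrom`, `gpos`, `strand` (and `name`, `label`
#'   parsed from the score column when present).
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("BED sites must carry a strand: ", path)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    gpos = GenomicRanges::start(gr),  # GRanges import already converts to 1-based
    strand = strand,
    stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$name)) out$name <- as.character(md$name)
  if (!is.null(md$score)) out$label <- as.integer(md$score)
  message(nrow(out), " site(s) read from ", path)
  out
}

#' Write single-nucleotide sites as BED6
#'
#' @param sites Data.frame with `chrom`, `gpos`, `strand` and optionally
#'   `label` (written to the score column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(
    chrom = sites$chrom,
    start = sites$gpos - 1L,      # back to 0-based half-open
    end = sites$gpos,
    name = if (!is.null(sites$tx_id)) sites$tx_id else ".",
    score = if (!is.null(sites$label)) sites$label else 0L,
    strand = sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read sites from a TSV (chrom, pos, strand[, label])
#'
#' @param path TSV path with a header line.
#' @return Data.frame with `chrom`, `gpos`, `strand` and optional `label`.
#' @export
read_sites_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[names(df) == "pos"] <- "gpos"
  stopifnot(all(c("chrom", "gpos", "strand") %in% names(df)))
  df
}

#' Save an encoded dataset with its parameters
#'
#' @param dataset A dataset list (from [assemble_site_dataset()],
#'   [assemble_bag_dataset()] or a manual build).
#' @param path Output `.rds` path.
#' @param params Encoder/provenance parameters stored alongside.
#' @return `path`, invisibly.
#' @export
save_encodings <- function(dataset, path, params = list()) {
  saveRDS(list(dataset = dataset, params = params,
               geotx_version = as.character(utils::packageVersion("geotx"))),
          path)
  invisible(path)
}

#' Load an encoded dataset saved by [save_encodings()]
#'
#' @param path `.rds` path.
#' @return The archive list (`dataset`, `params`, `geotx_version`).
#' @export
load_encodings <- function(path) readRDS(path)

# provenance record written next to CLI outputs
.write_provenance <- function(dir, config) {
  rec <- list(config = config,
              geotx_version = as.character(utils::packageVersion("geotx")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
}
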