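# Agreement between technique-specific epitranscriptomes. Site identity is
# (chrom, pos, strand) at single-nucleotide resolution; no fuzzy matching.

#' Construct a technique site set
#'
#' @param name Technique name.
#' @param sites Data.frame with columns `chrom`, `pos`, `strand` (or a
#'   character vector of ready-made `chrom:pos:strand` keys).
#' @return An object of class `technique_set` with unique site keys.
#' @export
technique_set <- function(name, sites) {
  keys <- if (is.character(sites)) sites
          else paste(sites$chrom, sites$pos, sites$strand, sep = ":")
  structure(list(name = name, sites = unique(keys)), class = "technique_set")
}

#' Min-normalized overlap consistency between two site sets
#'
#' The consistency of two techniques reporting `nA` and `nB` sites with
#' `nAB` sites in common is `100 * nAB / min(nA, nB)`, i.e. the overlap as a
#' percentage of the smaller set. Computed at full precision; round to two
#' decimals for display.
#'
#' @param nA,nB Set sizes (>= 1).
#' @param nAB Intersection count (`0 <= nAB <= min(nA, nB)`).
#' @return Consistency percentage in `[0, 100]`.
#' @export
consistency_score <- function(nA, nB, nAB) {
  if (nA < 1 || nB < 1) stop("set sizes must be >= 1")
  if (nAB < 0 || nAB > min(nA, nB))
    stop("impossible overlap: nAB = ", nAB, " exceeds min(", nA, ", ", nB, ")")
  100 * nAB / min(nA, nB)
}

.consistency_from_counts <- function(sizes, overlap) {
  n <- length(sizes)
  mat <- matrix(NA_real_, n, n, dimnames = list(names(sizes), names(sizes)))
  diag(mat) <- sizes
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mat[i, j] <- overlap[i, j]
    mat[j, i] <- consistency_score(sizes[i], sizes[j], overlap[i, j])
  }
  structure(mat, class = c("consistency_matrix", "matrix", "array"),
            mean_consistency = mean(mat[lower.tri(mat)]))
}

#' Pairwise consistency matrix across technique site sets
#'
#' Diagonal: set sizes; upper triangle: pairwise intersection counts; lower
#' triangle: consistency percentages (see [consistency_score()]). The mean of
#' the lower triangle is attached as attribute `mean_consistency`.
#'
#' @param sets List of `technique_set` objects (>= 2, unique names), or a
#'   ready-made list with elements `sizes` (named vector) and `overlap`
#'   (upper-triangle count matrix) for counts taken from a published table.
#' @return A `consistency_matrix`.
#' @export
pairwise_consistency <- function(sets) {
  if (!is.null(sets$sizes) && !is.null(sets$overlap))
    return(.consistency_from_counts(sets$sizes, sets$overlap))
  if (length(sets) < 2L) stop("need at least two technique sets")
  nm <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate technique names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  sizes <- stats::setNames(vapply(sets, function(s) length(s$sites), numeric(1)), nm)
  n <- length(sets)
  overlap <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    overlap[i, j] <- length(intersect(sets[[i]]$sites, sets[[j]]$sites))
  .consistency_from_counts(sizes, overlap)
}

#' @export
print.consistency_matrix <- function(x, ...) {
  y <- unclass(x)
  lower <- lower.tri(y)
  disp <- format(round(y, 2))
  disp[lower] <- paste0(format(round(y[lower], 2)), "%")
  print(disp, quote = FALSE)
  cat(sprintf("mean pairwise consistency: %.2f%%\n",
              attr(x, "mean_consistency")))
  invisible(x)
}

#' Published per-technique m6A site counts on housekeeping genes
#'
#' Loads the bundled table of site-set sizes and pairwise intersection counts
#' for nine m6A profiling techniques (m6A-seq, PA-m6A-seq, miCLIP,
#' m6A-CLIP-seq, m6A-REF-seq, MAZTER-seq, DART-seq, m6ACE-seq,
#' m6A-Label-seq), restricted to housekeeping genes, as reported in the
#' epitranscriptome profiling literature.
#'
#' @return List with `sizes` (named numeric) and `overlap` (upper-triangle
#'   count matrix), suitable for [pairwise_consistency()].
#' @export
technique_overlap_counts <- function() {
  path <- system.file("extdata", "m6a_technique_overlap_counts.tsv",
                      package = "geotx", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  nm <- df[[1]]
  m <- as.matrix(df[, -1])
  rownames(m) <- nm
  sizes <- stats::setNames(diag(m), nm)
  overlap <- m
  diag(overlap) <- NA_real_
  overlap[lower.tri(overlap)] <- NA_real_
  list(sizes = sizes, overlap = overlap)
}

#' Per-site technique support counts
#'
#' @param sets List of `technique_set` objects.
#' @return Named integer vector: for every site in the union, the number of
#'   techniques reporting it.
#' @export
support_counts <- function(sets) {
  tab <- table(unlist(lapply(sets, function(s) s$sites)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Select sites supported by at least k techniques
#'
#' @param sets List of `technique_set` objects.
#' @param k_min Minimum support count (>= 1).
#' @return A `technique_set` named `"support>=k"` whose sites have support
#'   `>= k_min`; the attribute `support` carries each site's count.
#' @export
select_high_confidence <- function(sets, k_min = 4L) {
  if (k_min < 1L) stop("k_min must be >= 1")
  cnt <- support_counts(sets)
  keep <- cnt[cnt >= k_min]
  out <- technique_set(paste0("support>=", k_min), names(keep))
  attr(out, "support") <- keep
  out
}

#' Permutation FDR for multi-technique support thresholds
#'
#' Estimates how many sites would reach each support level k by chance if
#' every technique placed its reported sites independently and uniformly at
#' random over the candidate motif universe (each technique's site count is
#' preserved). The observed cumulative counts `N_obs(>=k)` are compared with
#' the mean permuted counts `N_perm(>=k)`, and `FDR(k) = N_perm / N_obs`
#' (capped at 1 for reporting).
#'
#' @param sets List of `technique_set` objects.
#' @param universe Character vector of candidate site keys (must contain all
#'   reported sites).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer RNG seed.
#' @return Data.frame with columns `k`, `n_obs`, `n_perm`, `fdr` (and
#'   `fdr_capped`), one row per support level `1..length(sets)`.
#' @export
permutation_fdr <- function(sets, universe, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  universe <- unique(universe)
  U <- length(universe)
  missing <- setdiff(unlist(lapply(sets, function(s) s$sites)), universe)
  if (length(missing) > 0L)
    stop(length(missing), " reported site(s) absent from the universe, e.g. ",
         missing[1])
  K <- length(sets)
  sizes <- vapply(sets, function(s) length(s$sites), integer(1))
  obs <- support_counts(sets)
  n_obs <- vapply(seq_len(K), function(k) sum(obs >= k), numeric(1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  acc <- numeric(K)
  cnt <- integer(U)
  for (p in seq_len(n_perm)) {
    cnt[] <- 0L
    for (t in seq_len(K)) {
      idx <- sample.int(U, sizes[t])
      cnt[idx] <- cnt[idx] + 1L
    }
    tab <- tabulate(cnt[cnt > 0L], nbins = K)
    acc <- acc + rev(cumsum(rev(tab)))
  }
  n_perm_mean <- acc / n_perm
  fdr <- ifelse(n_obs > 0, n_perm_mean / n_obs, NA_real_)
  data.frame(k = seq_len(K), n_obs = n_obs, n_perm = n_perm_mean,
             fdr = fdr, fdr_capped = pmin(fdr, 1))
}
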