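#' Parsimony-informative site matrix of an alignment
#'
#' Encodes an alignment as integers (A=0, C=1, G=2, T=3, anything else
#' missing) and retains the columns that are parsimony informative: at least
#' two states each carried by at least two taxa. Genomic column order is
#' preserved.
#'
#' @param aln Named character vector of aligned sequences, or a character
#'   matrix (rows = taxa).
#' @return List of class `informative_sites`: `codes` (taxa x sites integer
#'   matrix, `-1` = missing), `original_positions` (1-based column indices in
#'   the input alignment), `taxa`, `n_informative`.
#' @export
informative_sites <- function(aln) {
  mat <- as_aln_matrix(aln)
  codes <- matrix(match(mat, .ACGT, nomatch = 0L) - 1L,
                  nrow = nrow(mat), dimnames = dimnames(mat))
  keep <- apply(codes, 2L, function(col) {
    tab <- tabulate(col[col >= 0L] + 1L, nbins = 4L)
    sum(tab >= 2L) >= 2L
  })
  structure(
    list(
      codes = codes[, keep, drop = FALSE],
      original_positions = which(keep),
      taxa = rownames(mat),
      n_informative = sum(keep)
    ),
    class = "informative_sites"
  )
}

as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(toupper(aln))
  if (methods::is(aln, "XStringSet")) aln <- as.character(aln)
  if (!is.character(aln)) stop("`aln` must be character or DNAStringSet")
  if (length(unique(nchar(aln))) != 1L) stop("aligned rows differ in length")
  matrix(unlist(strsplit(toupper(aln), "", fixed = TRUE), use.names = FALSE),
         nrow = length(aln), byrow = TRUE,
         dimnames = list(names(aln), NULL))
}

#' Refined incompatibility of two alignment columns
#'
#' The minimum number of extra character changes needed for two sites to
#' have evolved on a single tree, computed as the cycle rank `E - V + C` of
#' the bipartite graph whose vertices are the observed states of each column
#' and whose edges are the observed state combinations. Zero means the two
#' characters are compatible (binary case: the four-gamete test passes).
#' Taxa with a gap or ambiguity at either column are dropped pairwise.
#'
#' @param site_i,site_j Character vectors of equal length (one base per
#'   taxon) or integer code vectors as stored by [informative_sites()].
#' @return Nonnegative integer.
#' @examples
#' incompatibility_score(c("A","A","G","G"), c("A","G","A","G")) # all 4 gametes
#' @export
incompatibility_score <- function(site_i, site_j) {
  incompat_pair_cpp(as_site_codes(site_i), as_site_codes(site_j))
}

as_site_codes <- function(x) {
  if (is.character(x)) x <- match(toupper(x), .ACGT, nomatch = 0L) - 1L
  as.integer(x)
}

#' Pairwise homoplasy index of an informative-site matrix
#'
#' Mean refined incompatibility over all pairs of parsimony-informative
#' sites at most `window` apart in the informative-site ordering. Low values
#' relative to a permuted ordering indicate that nearby sites are more
#' mutually compatible than distant ones — the footprint of recombination.
#'
#' @param m An [informative_sites()] object (or alignment coercible to one).
#' @param window Maximum pair separation, counted in informative sites
#'   (default 100).
#' @return The mean incompatibility, or `NA` if fewer than two informative
#'   sites / no eligible pair exists.
#' @export
phi_statistic <- function(m, window = 100L) {
  m <- as_informative(m)
  k <- m$n_informative
  if (k < 2L) return(NA_real_)
  M <- incompat_matrix_cpp(m$codes)
  phi_band_mean_cpp(M, 0:(k - 1L), as.integer(window))
}

as_informative <- function(m) {
  if (inherits(m, "informative_sites")) m else informative_sites(m)
}

#' PHI permutation test for recombination
#'
#' Permutes the order of the informative sites `n_perm` times and compares
#' the observed statistic against the permuted ones. The test is one-sided
#' towards low PHI (recombination makes nearby sites more compatible than a
#' random ordering); the add-one estimator
#' `p = (1 + #\{phi_perm <= phi_obs\}) / (n_perm + 1)` keeps p-values off
#' zero, with floor `1/(n_perm + 1)`.
#'
#' @inheritParams phi_statistic
#' @param n_perm Number of permutations (default 1000; published analyses of
#'   this kind use 10000).
#' @param seed Optional integer seed for reproducible permutations.
#' @return One-row tibble: `phi_observed`, `p_perm`, `n_informative`,
#'   `n_pairs`. `phi_observed` is `NA` (and `p_perm` `NA`) when the
#'   alignment has insufficient information.
#' @export
phi_permutation_test <- function(m, window = 100L, n_perm = 1000L,
                                 seed = NULL) {
  if (n_perm < 1L) stop("`n_perm` must be at least 1")
  m <- as_informative(m)
  k <- m$n_informative
  window <- as.integer(window)
  if (k < 2L) {
    return(tibble::tibble(phi_observed = NA_real_, p_perm = NA_real_,
                          n_informative = k, n_pairs = 0L))
  }
  M <- incompat_matrix_cpp(m$codes)
  obs <- phi_band_mean_cpp(M, 0:(k - 1L), window)
  n_pairs <- n_band_pairs(k, window)
  perm_stats <- with_seed_if(seed, {
    perms <- vapply(seq_len(n_perm), function(i) sample.int(k) - 1L,
                    integer(k))
    phi_perm_stats_cpp(M, t(perms), window)
  })
  p <- (1 + sum(perm_stats <= obs)) / (n_perm + 1)
  tibble::tibble(phi_observed = obs, p_perm = p,
                 n_informative = k, n_pairs = n_pairs)
}

n_band_pairs <- function(k, window) {
  sum(pmin(seq_len(k) - 1L, window))
}

#' Benjamini-Hochberg recombination calls
#'
#' Step-up false-discovery-rate control over a vector of permutation
#' p-values; returns the per-gene boolean decision at the given FDR.
#'
#' @param pvalues Numeric vector in `[0, 1]` (`NA` allowed; returns `NA`).
#' @param fdr Target false discovery rate (default 0.05).
#' @return Logical vector, `TRUE` = called recombining.
#' @export
bh_correct <- function(pvalues, fdr = 0.05) {
  if (length(pvalues) == 0L) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH") <= fdr
}

#' GC contrast between recombining and non-recombining genes
#'
#' Per cluster, the mean GC of genes called recombining and of genes not so
#' called; clusters lacking either class are excluded. Across clusters a
#' paired t-test compares the two classes, and a Welch two-sample t-test
#' compares the per-cluster difference between Ku-encoding clusters (at
#' least one member genome carries Ku) and Ku-lacking clusters.
#'
#' @param gene_results Tibble with columns `cluster_id`, `gene_id`,
#'   `recombining` (logical) and `gene_gc` (mean GC across the gene's
#'   aligned sequences).
#' @param ku_table Optional tibble `genome_id`, `ku` (0/1) plus a
#'   `cluster_id` column mapping genomes to clusters; a cluster is
#'   Ku-encoding if any member has `ku == 1`.
#' @return List of class `gc_contrast`: `clusters` (per-cluster means and
#'   difference, plus `ku_cluster` when available), `paired_test`
#'   (`htest` or `NULL` when fewer than 2 clusters), `welch_test` (`htest`
#'   or `NULL`).
#' @export
gc_contrast <- function(gene_results, ku_table = NULL) {
  stopifnot(all(c("cluster_id", "gene_id", "recombining", "gene_gc")
                %in% names(gene_results)))
  per <- gene_results |>
    dplyr::filter(!is.na(.data$recombining)) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      gc_recombining = mean(.data$gene_gc[.data$recombining]),
      gc_nonrecombining = mean(.data$gene_gc[!.data$recombining]),
      n_recombining = sum(.data$recombining),
      n_nonrecombining = sum(!.data$recombining),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_recombining > 0, .data$n_nonrecombining > 0) |>
    dplyr::mutate(gc_diff = .data$gc_recombining - .data$gc_nonrecombining)
  if (!is.null(ku_table)) {
    ku_by_cluster <- ku_table |>
      dplyr::group_by(.data$cluster_id) |>
      dplyr::summarise(ku_cluster = as.integer(any(.data$ku == 1)),
                       .groups = "drop")
    per <- dplyr::left_join(per, ku_by_cluster, by = "cluster_id")
  }
  paired <- NULL
  welch <- NULL
  if (nrow(per) >= 2L) {
    paired <- t.test(per$gc_recombining, per$gc_nonrecombining,
                     paired = TRUE)
    if (!is.null(ku_table) &&
        length(unique(stats::na.omit(per$ku_cluster))) == 2L &&
        min(table(per$ku_cluster)) >= 2L) {
      welch <- t.test(gc_diff ~ ku_cluster, data = per)
    }
  }
  structure(list(clusters = per, paired_test = paired, welch_test = welch),
            class = "gc_contrast")
}

#' @export
print.gc_contrast <- function(x, ...) {
  cat("<gc_contrast> ", nrow(x$clusters),
      " clusters with both gene classes\n", sep = "")
  if (!is.null(x$paired_test)) {
    cat(sprintf("  paired t: mean diff %.4f, t = %.3f, df = %d, p = %.3g\n",
                mean(x$clusters$gc_diff), x$paired_test$statistic,
                as.integer(x$paired_test$parameter), x$paired_test$p.value))
  }
  if (!is.null(x$welch_test)) {
    cat(sprintf("  Welch t (Ku vs no-Ku cluster diff): t = %.3f, p = %.3g\n",
                x$welch_test$statistic, x$welch_test$p.value))
  }
  invisible(x)
}
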