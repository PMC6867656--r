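#' Bundle per-gene alignments of one genome cluster
#'
#' A cluster holds multiple alignments of orthologous genes over the same set
#' of closely related genomes (the structure provided by alignable-tight
#' genome-cluster resources), plus the concatenated core alignment used for
#' identity computation.
#'
#' @param cluster_id Cluster identifier.
#' @param gene_alignments Named list of gene alignments. Each element is a
#'   named character vector (names = genome ids, values = aligned sequences
#'   of equal length, gap character `-`). Every gene must contain every
#'   genome exactly once.
#' @return An object of class `cluster_alignments` with elements
#'   `cluster_id`, `genomes`, `gene_alignments` (character matrices, rows =
#'   genomes) and `core_concat` (column-bound matrix over all genes).
#' @export
cluster_alignments <- function(cluster_id, gene_alignments) {
  if (length(gene_alignments) == 0L) stop("no gene alignments supplied")
  if (is.null(names(gene_alignments)) || any(!nzchar(names(gene_alignments)))) {
    stop("`gene_alignments` must be a named list (gene ids)")
  }
  genomes <- sort(names(gene_alignments[[1]]))
  if (length(genomes) < 2L) stop("a cluster needs at least two genomes")
  mats <- purrr::imap(gene_alignments, function(aln, gene) {
    if (!setequal(names(aln), genomes) || anyDuplicated(names(aln))) {
      stop("gene ", gene, ": genomes do not match the cluster's genome set")
    }
    if (length(unique(nchar(aln))) != 1L) {
      stop("gene ", gene, ": aligned rows have unequal length")
    }
    aln <- toupper(aln[genomes])
    mat <- matrix(unlist(strsplit(aln, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(genomes), byrow = TRUE,
                  dimnames = list(genomes, NULL))
    mat
  })
  structure(
    list(
      cluster_id = cluster_id,
      genomes = genomes,
      gene_alignments = mats,
      core_concat = do.call(cbind, unname(mats))
    ),
    class = "cluster_alignments"
  )
}

#' @export
print.cluster_alignments <- function(x, ...) {
  cat("<cluster_alignments> ", x$cluster_id, ": ", length(x$genomes),
      " genomes, ", length(x$gene_alignments), " genes, core ",
      ncol(x$core_concat), " columns\n", sep = "")
  invisible(x)
}

#' Pairwise identity over the aligned core genome
#'
#' Fraction of matching bases between two genomes over alignment columns
#' where both have unambiguous, non-gap bases.
#'
#' @param cluster A [cluster_alignments()] object (or a character matrix with
#'   genome ids as row names).
#' @param a,b Genome ids.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(cluster, a, b) {
  mat <- if (inherits(cluster, "cluster_alignments")) cluster$core_concat
         else cluster
  if (!all(c(a, b) %in% rownames(mat))) stop("genome id not in alignment")
  ra <- mat[a, ]
  rb <- mat[b, ]
  ok <- ra %in% .ACGT & rb %in% .ACGT
  if (!any(ok)) stop("no comparable columns between ", a, " and ", b)
  mean(ra[ok] == rb[ok])
}

# full identity matrix over a cluster's core alignment
identity_matrix <- function(cluster) {
  g <- cluster$genomes
  m <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) {
    m[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      v <- pairwise_identity(cluster, g[i], g[j])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

#' Assign focal/nearest/outgroup triplets within a cluster
#'
#' Every genome serves as focal once; its nearest neighbour is the genome
#' with maximal core identity to it (the comparison partner for calling
#' recent polymorphisms) and the outgroup is the most diverged genome
#' (minimal identity), used to polarize. Ties are broken by lexicographic
#' genome id for determinism.
#'
#' @param cluster A [cluster_alignments()] object with at least 3 genomes.
#' @return Tibble with columns `cluster_id`, `focal`, `nearest`, `outgroup`,
#'   `identity_focal_nearest`.
#' @export
assign_triplets <- function(cluster) {
  if (length(cluster$genomes) < 3L) {
    stop("cluster ", cluster$cluster_id, " has fewer than 3 genomes")
  }
  idm <- identity_matrix(cluster)
  purrr::map_dfr(cluster$genomes, function(f) {
    others <- setdiff(cluster$genomes, f)
    ident <- idm[f, others]
    # which.max/min on a sorted (lexicographic) candidate list -> stable ties
    ord <- order(names(ident))
    ident <- ident[ord]
    nearest <- names(ident)[which.max(ident)]
    outgroup <- names(ident)[which.min(ident)]
    tibble::tibble(
      cluster_id = cluster$cluster_id,
      focal = f, nearest = nearest, outgroup = outgroup,
      identity_focal_nearest = unname(ident[nearest])
    )
  })
}

#' Polarize polymorphisms in a genome triplet
#'
#' Scans every gene alignment column where focal, nearest and outgroup all
#' carry unambiguous non-gap bases. The outgroup base is taken as the
#' ancestral state; a column where the focal differs from the nearest while
#' the outgroup matches the nearest is a derived change on the focal lineage.
#' Changes are informative when they cross the AT/GC boundary; within-class
#' changes (A<->T, G<->C) are surveyed but not informative; columns where the
#' outgroup matches neither genome are discarded.
#'
#' @param cluster A [cluster_alignments()] object.
#' @param focal,nearest,outgroup Genome ids (e.g. one row of
#'   [assign_triplets()]).
#' @param fourfold_only If `TRUE`, survey only columns that are fourfold
#'   degenerate in the outgroup's reading frame (alignments are assumed
#'   codon-aligned with frame 0 in each gene).
#' @param denominator `"consistent"` (default) counts as surveyed only
#'   columns where the outgroup matches the nearest genome, classed by the
#'   ancestral base; `"all"` counts every column with three unambiguous
#'   bases, classed by the outgroup base.
#' @param code_table Genetic code id used when `fourfold_only = TRUE`.
#' @return One-row tibble: `n_at_to_gc`, `n_gc_to_at`, `n_at_sites`,
#'   `n_gc_sites`, `n_informative`.
#' @export
polarize_polymorphisms <- function(cluster, focal, nearest, outgroup,
                                   fourfold_only = FALSE,
                                   denominator = c("consistent", "all"),
                                   code_table = "1") {
  denominator <- match.arg(denominator)
  stopifnot(all(c(focal, nearest, outgroup) %in% cluster$genomes))
  tot <- c(n_at_to_gc = 0L, n_gc_to_at = 0L, n_at_sites = 0L, n_gc_sites = 0L)
  for (mat in cluster$gene_alignments) {
    f <- mat[focal, ]; n <- mat[nearest, ]; o <- mat[outgroup, ]
    good <- f %in% .ACGT & n %in% .ACGT & o %in% .ACGT
    if (fourfold_only) {
      good <- good & fourfold_columns(o, code_table = code_table)
    }
    if (!any(good)) next
    f <- f[good]; n <- n[good]; o <- o[good]
    consistent <- o == n
    anc_at <- o %in% .AT
    if (denominator == "consistent") {
      tot["n_at_sites"] <- tot["n_at_sites"] + sum(consistent & anc_at)
      tot["n_gc_sites"] <- tot["n_gc_sites"] + sum(consistent & !anc_at)
    } else {
      tot["n_at_sites"] <- tot["n_at_sites"] + sum(anc_at)
      tot["n_gc_sites"] <- tot["n_gc_sites"] + sum(!anc_at)
    }
    derived <- consistent & f != n
    tot["n_at_to_gc"] <- tot["n_at_to_gc"] +
      sum(derived & anc_at & f %in% .GC)
    tot["n_gc_to_at"] <- tot["n_gc_to_at"] +
      sum(derived & !anc_at & f %in% .AT)
  }
  tibble::tibble(
    n_at_to_gc = unname(tot["n_at_to_gc"]),
    n_gc_to_at = unname(tot["n_gc_to_at"]),
    n_at_sites = unname(tot["n_at_sites"]),
    n_gc_sites = unname(tot["n_gc_sites"]),
    n_informative = unname(tot["n_at_to_gc"] + tot["n_gc_to_at"])
  )
}

# logical mask over alignment columns: fourfold degenerate in the reference
# row's reading frame (gaps in the reference shift the frame accordingly)
fourfold_columns <- function(ref_row, code_table = "1") {
  mask <- rep(FALSE, length(ref_row))
  nongap <- which(ref_row != "-")
  if (length(nongap) < 3L) return(mask)
  ungapped <- paste(ref_row[nongap], collapse = "")
  pos0 <- fourfold_sites(gsub("[^ACGT]", "N", ungapped),
                         frame = 0L, code_table = code_table)
  mask[nongap[pos0 + 1L]] <- TRUE
  mask
}

#' Restrict polarization to fourfold degenerate sites
#'
#' Convenience wrapper around [polarize_polymorphisms()] with
#' `fourfold_only = TRUE`: only third codon positions of fourfold codon
#' families (read off the outgroup sequence) are surveyed, giving a
#' composition estimate shielded from amino-acid-level selection.
#'
#' @inheritParams polarize_polymorphisms
#' @export
fourfold_restrict <- function(cluster, focal, nearest, outgroup,
                              denominator = c("consistent", "all"),
                              code_table = "1") {
  polarize_polymorphisms(cluster, focal, nearest, outgroup,
                         fourfold_only = TRUE,
                         denominator = denominator, code_table = code_table)
}

#' Filter focal rows by divergence and information content
#'
#' Keeps focal genomes whose nearest neighbour is within 1% divergence
#' (identity at least `min_identity`, boundary inclusive) and which carry at
#' least `min_informative` polarized AT<->GC changes; pairs with fewer are
#' discarded to avoid extreme equilibrium-GC estimates.
#'
#' @param tbl Tibble containing `identity_focal_nearest` and `n_informative`
#'   columns (e.g. the output of [run_polymorphism()] before filtering).
#' @param min_identity Minimum focal-nearest identity (default 0.99).
#' @param min_informative Minimum informative changes (default 5).
#' @return The filtered tibble.
#' @export
apply_filters <- function(tbl, min_identity = 0.99, min_informative = 5L) {
  dplyr::filter(tbl,
                .data$identity_focal_nearest >= min_identity,
                .data$n_informative >= min_informative)
}

#' Mutational bias and equilibrium GC content from polarized counts
#'
#' Per-site rates are `v = n_at_to_gc / n_at_sites` (AT->GC) and
#' `u = n_gc_to_at / n_gc_sites` (GC->AT); the bias ratio is `m = u / v` and
#' the expected (equilibrium) GC content under mutation alone is
#' `v / (u + v) = 1 / (1 + m)`.
#'
#' @param counts Tibble with columns `n_at_to_gc`, `n_gc_to_at`,
#'   `n_at_sites`, `n_gc_sites` (one row per focal genome; vectorized).
#' @return `counts` with columns `v`, `u`, `m`, `expected_gc` and
#'   `bias_flag` (`"ok"`, `"no_at_to_gc"` or `"no_gc_to_at"`) appended.
#' @export
estimate_bias <- function(counts) {
  stopifnot(all(c("n_at_to_gc", "n_gc_to_at", "n_at_sites", "n_gc_sites")
                %in% names(counts)))
  if (any(counts$n_at_sites == 0 | counts$n_gc_sites == 0)) {
    stop("surveyed-site denominators must be positive")
  }
  dplyr::mutate(
    counts,
    v = .data$n_at_to_gc / .data$n_at_sites,
    u = .data$n_gc_to_at / .data$n_gc_sites,
    m = .data$u / .data$v,
    expected_gc = dplyr::if_else(.data$u + .data$v > 0,
                                 .data$v / (.data$u + .data$v), NA_real_),
    bias_flag = dplyr::case_when(
      .data$v == 0 ~ "no_at_to_gc",
      .data$u == 0 ~ "no_gc_to_at",
      TRUE ~ "ok"
    )
  )
}
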