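#' Run the polymorphism-polarization stage over a set of clusters
#'
#' For every cluster with at least three genomes, assigns
#' focal/nearest/outgroup triplets (every genome focal once), polarizes
#' polymorphisms, estimates mutational bias and expected GC, applies the
#' divergence and informative-site filters, and annotates each focal genome
#' with its observed core-gene GC content.
#'
#' @param clusters List of [cluster_alignments()] objects (e.g. from
#'   [read_cluster_dir()]).
#' @param ku_table Optional tibble `genome_id`, `ku` to annotate rows.
#' @param min_identity,min_informative Filter thresholds (defaults 0.99 and
#'   5); pass `-Inf`/`0` to disable.
#' @param fourfold_only Survey only fourfold degenerate sites.
#' @param denominator Passed to [polarize_polymorphisms()].
#' @return Tibble, one row per retained focal genome: triplet assignment,
#'   polarized counts, `v`, `u`, `m`, `expected_gc`, `observed_gc` (focal
#'   core-gene GC), and `ku` when supplied.
#' @export
run_polymorphism <- function(clusters, ku_table = NULL,
                             min_identity = 0.99, min_informative = 5L,
                             fourfold_only = FALSE,
                             denominator = "consistent") {
  if (length(clusters) == 0L) {
    message("no clusters supplied; returning empty table")
    return(tibble::tibble())
  }
  rows <- purrr::map(clusters, function(cl) {
    if (length(cl$genomes) < 3L) {
      message("cluster ", cl$cluster_id, ": fewer than 3 genomes, skipped")
      return(NULL)
    }
    trip <- assign_triplets(cl)
    counts <- purrr::pmap_dfr(
      trip[, c("focal", "nearest", "outgroup")],
      function(focal, nearest, outgroup) {
        polarize_polymorphisms(cl, focal, nearest, outgroup,
                               fourfold_only = fourfold_only,
                               denominator = denominator)
      }
    )
    obs_gc <- vapply(trip$focal, function(f) {
      row <- cl$core_concat[f, ]
      gc_content(paste(row[row %in% .ACGT], collapse = ""))
    }, numeric(1))
    dplyr::bind_cols(trip, counts, observed_gc = unname(obs_gc))
  })
  tbl <- dplyr::bind_rows(rows)
  if (nrow(tbl) == 0L) return(tbl)
  n_before <- nrow(tbl)
  tbl <- apply_filters(tbl, min_identity = min_identity,
                       min_informative = min_informative)
  message(n_before - nrow(tbl), " of ", n_before,
          " focal rows removed by divergence/informative-site filters")
  tbl <- estimate_bias(tbl)
  if (!is.null(ku_table)) {
    tbl <- dplyr::left_join(tbl, ku_table,
                            by = c(focal = "genome_id"))
  }
  tbl
}

#' Run the recombination-detection stage over a set of clusters
#'
#' Applies the PHI permutation test to every gene of every cluster, corrects
#' jointly across all cluster-gene pairs with Benjamini-Hochberg, and
#' computes the recombining vs non-recombining GC contrast.
#'
#' @inheritParams run_polymorphism
#' @param window,n_perm,fdr PHI test settings (defaults 100 informative
#'   sites, 1000 permutations, FDR 0.05; published analyses of this kind use
#'   10000 permutations).
#' @param seed Integer seed for the permutations.
#' @param ku_table Optional tibble `genome_id`, `ku` used to label clusters
#'   Ku-encoding (any member with Ku).
#' @return List: `genes` (tibble `cluster_id`, `gene_id`, `n_informative`,
#'   `phi`, `p`, `recombining`, `gene_gc`), `contrast` (a [gc_contrast()]
#'   object or `NULL`), `n_tested`, `n_excluded`.
#' @export
run_recombination <- function(clusters, window = 100L, n_perm = 1000L,
                              fdr = 0.05, seed = NULL, ku_table = NULL) {
  with_seed_if(seed, {
    genes <- purrr::map_dfr(clusters, function(cl) {
      purrr::imap_dfr(cl$gene_alignments, function(mat, gene) {
        res <- phi_permutation_test(informative_sites(mat),
                                    window = window, n_perm = n_perm)
        ungapped <- apply(mat, 1L, function(r) {
          paste(r[r %in% .ACGT], collapse = "")
        })
        gene_gc <- mean(vapply(ungapped[nzchar(ungapped)],
                               gc_content, numeric(1)))
        dplyr::bind_cols(
          tibble::tibble(cluster_id = cl$cluster_id, gene_id = gene),
          res, tibble::tibble(gene_gc = gene_gc)
        )
      })
    })
    n_excluded <- sum(is.na(genes$p_perm))
    if (n_excluded > 0L) {
      message(n_excluded, " gene(s) with insufficient informative sites ",
              "excluded from testing")
    }
    genes$recombining <- NA
    tested <- !is.na(genes$p_perm)
    genes$recombining[tested] <- bh_correct(genes$p_perm[tested], fdr = fdr)
    contrast <- NULL
    eligible <- genes |>
      dplyr::filter(!is.na(.data$recombining)) |>
      dplyr::rename(phi = "phi_observed", p = "p_perm")
    if (nrow(eligible) > 0L) {
      ku_cl <- NULL
      if (!is.null(ku_table)) {
        ku_cl <- purrr::map_dfr(clusters, function(cl) {
          tibble::tibble(cluster_id = cl$cluster_id,
                         genome_id = cl$genomes)
        }) |>
          dplyr::inner_join(ku_table, by = "genome_id")
      }
      contrast <- gc_contrast(eligible, ku_table = ku_cl)
    }
    list(genes = eligible, contrast = contrast,
         n_tested = sum(tested), n_excluded = n_excluded)
  })
}

#' Run the restriction-site flank analysis
#'
#' AT-rich filtering of recognition sequences, observed and permuted-null
#' flank profiles, cross-genome bootstrap CIs, and the motif-vs-background
#' GC comparison.
#'
#' @inheritParams flank_enrichment
#' @return List: `enrichment` (a `flank_enrichment` object),
#'   `motif_background` (tibble of per-genome motif GC vs genome GC).
#' @export
run_flanks <- function(genome_tbl, motif_tbl, max_distance = 200L,
                       n_null = 1L, n_boot = 1000L, at_threshold = 0.75,
                       seed = NULL) {
  enr <- flank_enrichment(genome_tbl, motif_tbl,
                          max_distance = max_distance, n_null = n_null,
                          n_boot = n_boot, at_threshold = at_threshold,
                          seed = seed)
  mb <- dplyr::inner_join(motif_tbl, genome_tbl, by = "genome_id") |>
    dplyr::rowwise() |>
    dplyr::mutate(motif_vs_background(.data$seq, .data$pattern)) |>
    dplyr::ungroup() |>
    dplyr::select("genome_id", dplyr::any_of("enzyme_id"), "pattern",
                  "motif_gc", "genome_gc", "difference")
  list(enrichment = enr, motif_background = mb)
}

#' Run the phylogenetic-regression stage
#'
#' Fits the Ku + log10 genome length + interaction model under the requested
#' covariance models and responses, optionally on the uniform-Ku subset,
#' reports AICs, Benjamini-Hochberg significance flags across all
#' coefficients, and the simple Ku-GC point-biserial correlation.
#'
#' @param traits Trait tibble (see [fit_pgls()]).
#' @param tree Rooted `phylo` tree.
#' @param models Covariance models to fit (subset of `c("BM", "OU")`).
#' @param responses Responses to fit (subset of
#'   `c("gc_logit", "gc4", "gc4_logit")`).
#' @param uniform_ku Also fit the genus-uniform-Ku subset.
#' @param alpha FDR for the significance flags.
#' @return List: `fits` (named list of `breakgc_pgls`), `table`
#'   (Table-1-style tibble: one row per fit with AIC and the Ku, length and
#'   interaction coefficients and p-values), `bh` (coefficient-level BH
#'   flags), `correlation` (from [ku_gc_correlation()]).
#' @export
run_regression <- function(traits, tree, models = c("BM", "OU"),
                           responses = "gc_logit", uniform_ku = FALSE,
                           alpha = 0.05) {
  datasets <- list(all = traits)
  if (uniform_ku) datasets$uniform_ku <- uniform_ku_filter(traits)
  fits <- list()
  for (dn in names(datasets)) {
    for (resp in responses) {
      for (mod in models) {
        fits[[paste(dn, resp, mod, sep = "/")]] <-
          fit_pgls(datasets[[dn]], tree, response = resp, model = mod)
      }
    }
  }
  table <- purrr::imap_dfr(fits, function(f, nm) {
    b <- f$beta; p <- f$p_values
    tibble::tibble(
      data = sub("/.*", "", nm), response = f$response, model = f$model,
      n = f$n, AIC = f$aic,
      beta_ku = b[["ku"]], p_ku = p[["ku"]],
      beta_length = b[["log10_length"]], p_length = p[["log10_length"]],
      beta_interaction = b[["ku:log10_length"]],
      p_interaction = p[["ku:log10_length"]]
    )
  })
  list(fits = fits, table = table, bh = bh_table(fits, alpha = alpha),
       correlation = ku_gc_correlation(traits))
}
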