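#' Expected AT and GC fractions of an IUPAC recognition sequence
#'
#' Each IUPAC letter contributes the fraction of its represented bases that
#' are A/T (resp. G/C): unambiguous bases contribute 0 or 1, `W` counts 1
#' toward AT, `S` 0, and fully/partially ambiguous codes their expected
#' fraction (`N` = 0.5, `D` = 2/3, ...).
#'
#' @param pattern Character vector of IUPAC motifs.
#' @return Numeric vector of fractions.
#' @examples
#' iupac_at_fraction("AATT")  # 1
#' iupac_gc_expected("GANTC") # (2 + 0.5) / 5
#' @export
iupac_at_fraction <- function(pattern) 1 - iupac_gc_expected(pattern)

#' @rdname iupac_at_fraction
#' @export
iupac_gc_expected <- function(pattern) {
  vapply(toupper(pattern), function(p) {
    letters <- strsplit(p, "", fixed = TRUE)[[1]]
    bad <- setdiff(letters, names(.IUPAC))
    if (length(bad) > 0L) stop("illegal IUPAC character(s): ",
                               paste(bad, collapse = ", "))
    if (length(letters) == 0L) stop("empty motif")
    mean(vapply(.IUPAC[letters],
                function(b) mean(b %in% .GC), numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Locate restriction recognition sites in a genome
#'
#' Finds every position (overlaps allowed) matching the IUPAC-expanded motif
#' on the forward strand or matching its reverse complement; palindromic
#' motifs yield one hit per position. On circular genomes matches may span
#' the origin.
#'
#' @param genome A single sequence (character or DNAString).
#' @param motif IUPAC recognition sequence.
#' @param topology `"linear"` or `"circular"`.
#' @return Tibble with 0-based half-open `start`, `end` and `strand`
#'   (`"+"`, `"-"`, or `"both"` for palindromes), sorted by `start`.
#' @export
find_sites <- function(genome, motif, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  genome <- as_sequence_chr(genome)
  if (length(genome) != 1L) stop("`genome` must be a single sequence")
  motif <- toupper(motif)
  bad <- setdiff(strsplit(motif, "", fixed = TRUE)[[1]], names(.IUPAC))
  if (length(bad) > 0L) stop("illegal IUPAC character(s) in motif: ",
                             paste(bad, collapse = ", "))
  len <- nchar(genome)
  w <- nchar(motif)
  if (len < w) stop("genome shorter than motif")
  subject <- genome
  if (topology == "circular" && w > 1L) {
    subject <- paste0(genome, substr(genome, 1L, w - 1L))
  }
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  hit_starts <- function(pat) {
    IRanges::start(Biostrings::matchPattern(pat, Biostrings::DNAString(subject),
                                            fixed = FALSE))
  }
  sf <- hit_starts(fwd)
  sr <- if (as.character(rev) == motif) integer(0) else hit_starts(rev)
  tbl <- tibble::tibble(
    start = c(sf, sr) - 1L,
    strand = rep(c(if (as.character(rev) == motif) "both" else "+", "-"),
                 c(length(sf), length(sr)))
  )
  if (topology == "circular") tbl$start <- tbl$start %% len
  tbl <- dplyr::distinct(tbl, .data$start, .data$strand)
  tbl |>
    dplyr::mutate(end = .data$start + w) |>
    dplyr::select("start", "end", "strand") |>
    dplyr::arrange(.data$start, .data$strand)
}

#' Keep genome-motif pairs with AT-rich recognition sequences
#'
#' Retains motifs whose expected AT fraction is at least `threshold`
#' (boundary inclusive; default 0.75). If a genome retains several enzymes a
#' message is emitted (multiplicity is unusual but all are kept).
#'
#' @param motif_tbl Tibble with columns `genome_id`, `enzyme_id`, `pattern`.
#' @param threshold Minimum AT fraction (default 0.75).
#' @return Filtered tibble with an `at_fraction` column appended.
#' @export
at_rich_filter <- function(motif_tbl, threshold = 0.75) {
  out <- motif_tbl |>
    dplyr::mutate(at_fraction = iupac_at_fraction(.data$pattern)) |>
    dplyr::filter(.data$at_fraction >= threshold)
  multi <- out |> dplyr::count(.data$genome_id) |> dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0L) {
    message(nrow(multi), " genome(s) retain multiple AT-rich enzymes; ",
            "all kept")
  }
  out
}

#' Mean flank GC at each distance from a set of sites
#'
#' For each distance `d` in `1..max_distance`, averages over all sites and
#' both sides the indicator that the base `d` positions outside the site
#' boundary is G or C. Left and right flanks are pooled. Circular genomes
#' wrap; on linear genomes out-of-range positions are skipped.
#'
#' @param genome A single sequence.
#' @param sites Tibble with 0-based half-open `start`, `end` columns (e.g.
#'   from [find_sites()]).
#' @param max_distance Largest flank distance surveyed (default 200).
#' @inheritParams find_sites
#' @return Tibble `distance`, `mean_gc`, `n_obs` (`mean_gc` is `NA` where no
#'   in-bounds flank base exists).
#' @export
flank_profile <- function(genome, sites, max_distance = 200L,
                          topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  genome <- as_sequence_chr(genome)
  if (nrow(sites) == 0L) stop("no sites supplied")
  chars <- strsplit(genome, "", fixed = TRUE)[[1]]
  len <- length(chars)
  is_gc <- chars %in% .GC
  left0 <- sites$start   # 0-based position just right of the left flank
  right0 <- sites$end - 1L
  purrr::map_dfr(seq_len(max_distance), function(d) {
    idx <- c(left0 - d, right0 + d)  # 0-based flank positions
    if (topology == "circular") {
      idx <- idx %% len
    } else {
      idx <- idx[idx >= 0L & idx < len]
    }
    tibble::tibble(
      distance = d,
      mean_gc = if (length(idx) == 0L) NA_real_ else mean(is_gc[idx + 1L]),
      n_obs = length(idx)
    )
  })
}

#' Random permutation of a recognition sequence
#'
#' Draws a uniform permutation of the motif's letters, redrawing until the
#' result differs from the input, so the null motif preserves base
#' composition exactly while scrambling the recognized word.
#'
#' @param motif IUPAC motif with at least two distinct letters.
#' @return A permuted motif string.
#' @export
permuted_null <- function(motif) {
  letters <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  if (length(unique(letters)) < 2L) {
    stop("motif has a single distinct letter; no distinct permutation exists")
  }
  repeat {
    perm <- paste(sample(letters), collapse = "")
    if (perm != toupper(motif)) return(perm)
  }
}

#' Motif GC content versus genomic background
#'
#' @param genome A single sequence.
#' @param motif IUPAC motif.
#' @return One-row tibble: `motif_gc` (ambiguity-weighted), `genome_gc`,
#'   `difference`.
#' @export
motif_vs_background <- function(genome, motif) {
  mg <- iupac_gc_expected(motif)
  gg <- gc_content(genome)
  tibble::tibble(motif_gc = mg, genome_gc = gg, difference = mg - gg)
}

#' Flank-GC enrichment at restriction sites against a permuted-motif null
#'
#' Per genome and flank distance, the difference between mean GC flanking
#' true recognition sites and mean GC flanking the sites of a
#' composition-preserving permuted motif (averaged over `n_null` permuted
#' motifs). The cross-genome mean difference at each distance is
#' percentile-bootstrapped (resampling genomes) for a 95% confidence
#' interval; genomes are weighted equally (one mean per genome).
#'
#' @param genome_tbl Tibble with columns `genome_id`, `seq` and optionally
#'   `topology` (default `"linear"`).
#' @param motif_tbl Tibble with columns `genome_id`, `enzyme_id`, `pattern`;
#'   filtered through [at_rich_filter()] unless `at_threshold` is `NULL`.
#' @param max_distance Largest flank distance (default 200).
#' @param n_null Permuted motifs averaged per genome (default 1).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param at_threshold AT-rich threshold passed to [at_rich_filter()], or
#'   `NULL` to skip filtering.
#' @param conf_level Bootstrap CI level (default 0.95).
#' @param seed Optional integer seed.
#' @return List of class `flank_enrichment`: `profile` (tibble `distance`,
#'   `mean_diff`, `ci_lo`, `ci_hi`, `n_genomes`), `per_genome` (genome x
#'   distance difference matrix), `excluded` (genome ids dropped for lack of
#'   sites).
#' @export
flank_enrichment <- function(genome_tbl, motif_tbl, max_distance = 200L,
                             n_null = 1L, n_boot = 1000L,
                             at_threshold = 0.75, conf_level = 0.95,
                             seed = NULL) {
  stopifnot(all(c("genome_id", "seq") %in% names(genome_tbl)),
            all(c("genome_id", "pattern") %in% names(motif_tbl)))
  if (!"topology" %in% names(genome_tbl)) genome_tbl$topology <- "linear"
  if (!is.null(at_threshold)) {
    motif_tbl <- at_rich_filter(motif_tbl, threshold = at_threshold)
  }
  pairs <- dplyr::inner_join(motif_tbl, genome_tbl, by = "genome_id")
  if (nrow(pairs) < 2L) stop("need at least two genome-motif pairs")
  with_seed_if(seed, {
    rows <- vector("list", nrow(pairs))
    excluded <- character(0)
    for (i in seq_len(nrow(pairs))) {
      g <- pairs$seq[i]
      topo <- pairs$topology[i]
      motif <- pairs$pattern[i]
      obs_sites <- find_sites(g, motif, topology = topo)
      if (nrow(obs_sites) == 0L) {
        excluded <- c(excluded, pairs$genome_id[i]); next
      }
      obs <- flank_profile(g, obs_sites, max_distance, topology = topo)
      null_acc <- matrix(NA_real_, n_null, max_distance)
      for (r in seq_len(n_null)) {
        null_motif <- permuted_null(motif)
        null_sites <- find_sites(g, null_motif, topology = topo)
        if (nrow(null_sites) == 0L) next  # replicate skipped, logged below
        null_acc[r, ] <-
          flank_profile(g, null_sites, max_distance, topology = topo)$mean_gc
      }
      if (all(is.na(null_acc))) {
        message("genome ", pairs$genome_id[i],
                ": no null-motif matches in any replicate; excluded")
        excluded <- c(excluded, pairs$genome_id[i]); next
      }
      rows[[i]] <- obs$mean_gc - colMeans(null_acc, na.rm = TRUE)
    }
    keep <- !vapply(rows, is.null, logical(1))
    diffs <- do.call(rbind, rows[keep])
    rownames(diffs) <- pairs$genome_id[keep]
    n_genomes <- nrow(diffs)
    boot_means <- matrix(NA_real_, n_boot, max_distance)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_genomes, replace = TRUE)
      boot_means[b, ] <- colMeans(diffs[idx, , drop = FALSE], na.rm = TRUE)
    }
    a <- (1 - conf_level) / 2
    profile <- tibble::tibble(
      distance = seq_len(max_distance),
      mean_diff = colMeans(diffs, na.rm = TRUE),
      ci_lo = apply(boot_means, 2L, quantile, probs = a, na.rm = TRUE),
      ci_hi = apply(boot_means, 2L, quantile, probs = 1 - a, na.rm = TRUE),
      n_genomes = n_genomes
    )
    if (n_genomes == 1L) {
      message("single genome: bootstrap CI degenerate at the point estimate")
    }
    structure(list(profile = profile, per_genome = diffs,
                   excluded = excluded),
              class = "flank_enrichment")
  })
}

#' @export
print.flank_enrichment <- function(x, ...) {
  cat("<flank_enrichment> ", x$profile$n_genomes[1], " genomes, distances 1-",
      max(x$profile$distance), "\n", sep = "")
  near <- dplyr::filter(x$profile, .data$distance <= 5)
  print(near)
  invisible(x)
}
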