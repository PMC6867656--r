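#' Simulate a closely related genome triplet with known mutational bias
#'
#' Generates a three-genome cluster (focal `F`, nearest `N`, outgroup `O`)
#' from a common ancestor drawn i.i.d. at GC content `gc0`. The root is the
#' F/N ancestor; each of F and N evolves along a branch of expected per-site
#' divergence `divergence_fn / 2`, and O along a branch of
#' `divergence_fo - divergence_fn / 2`, so pairwise F-N divergence is
#' `divergence_fn` and F-O divergence `divergence_fo`. Substitutions follow a
#' two-class process: per AT site the probability of an AT->GC change is
#' `v_b`, per GC site the probability of a GC->AT change is `m * v_b`, and a
#' small within-class rate (A<->T, G<->C; `within_frac` of the branch
#' divergence) exercises the non-informative code path. Events are planted
#' under an infinite-sites model: at most one change per column across the
#' whole triplet (each branch's per-site event probability is exact; only
#' the vanishing co-occurrence terms are suppressed), so the truth ledger
#' predicts every polarized count exactly and estimator properties are
#' measured free of homoplasy.
#'
#' @param n_sites Total alignment length (split into genes).
#' @param m GC->AT : AT->GC per-site rate ratio (the planted truth).
#' @param divergence_fn Expected focal-nearest pairwise divergence (< 0.01).
#' @param divergence_fo Expected focal-outgroup divergence (>= 0.01).
#' @param gc0 Ancestral GC content.
#' @param coding If `TRUE`, genes are stop-free CDSs of length divisible by
#'   3 and the ledger records fourfold-site positions.
#' @param n_genes Number of genes the sites are split into.
#' @param within_frac Fraction of each branch's divergence planted as
#'   within-class changes (default 0.05).
#' @param seed Integer seed (required for reproducibility).
#' @return List with `cluster` (a [cluster_alignments()] object over genomes
#'   `F`, `N`, `O`) and `ledger` (planted parameters plus an `events` tibble
#'   with branch, gene, column, from, to).
#' @export
gen_triplet_cluster <- function(n_sites, m, divergence_fn = 0.005,
                                divergence_fo = 0.05, gc0 = 0.4,
                                coding = FALSE, n_genes = NULL,
                                within_frac = 0.05, seed = NULL) {
  if (!(divergence_fn < 0.01 && 0.01 <= divergence_fo)) {
    stop("need divergence_fn < 0.01 <= divergence_fo")
  }
  if (m <= 0) stop("`m` must be positive")
  with_seed_if(seed, {
    if (is.null(n_genes)) n_genes <- max(1L, round(n_sites / 1000))
    gene_len <- n_sites %/% n_genes
    if (coding) gene_len <- (gene_len %/% 3L) * 3L
    root <- random_sequence(gene_len * n_genes, gc0, coding = coding)
    d_tip <- divergence_fn / 2
    d_out <- divergence_fo - d_tip
    branches <- c(focal = d_tip, nearest = d_tip, outgroup = d_out)
    ev <- evolve_triplet(root, branches, m, gc0, within_frac)
    seqs <- ev$seqs
    events <- ev$events
    if (nrow(events) > 0L) {
      events$gene <- paste0("gene", (events$column - 1L) %/% gene_len + 1L)
    }
    genes <- purrr::map(seq_len(n_genes), function(g) {
      idx <- ((g - 1L) * gene_len + 1L):(g * gene_len)
      c(F = paste(seqs$focal[idx], collapse = ""),
        N = paste(seqs$nearest[idx], collapse = ""),
        O = paste(seqs$outgroup[idx], collapse = ""))
    })
    names(genes) <- paste0("gene", seq_len(n_genes))
    list(
      cluster = cluster_alignments("synthetic_triplet", genes),
      ledger = list(
        generator = "gen_triplet_cluster", seed = seed, m = m,
        gc0 = gc0, divergence_fn = divergence_fn,
        divergence_fo = divergence_fo, coding = coding,
        gene_length = gene_len, n_genes = n_genes,
        root = paste(root, collapse = ""), events = events
      )
    )
  })
}

# i.i.d. sequence at a target GC; coding = stop-free codons, length %% 3 == 0
random_sequence <- function(n, gc, coding = FALSE) {
  draw <- function(k) {
    sample(.ACGT, k, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  }
  x <- draw(n)
  if (coding) {
    stopifnot(n %% 3L == 0L)
    stops <- c("TAA", "TAG", "TGA")
    repeat {
      starts <- seq.int(1L, n, by = 3L)
      cod <- paste0(x[starts], x[starts + 1L], x[starts + 2L])
      bad <- which(cod %in% stops)
      if (length(bad) == 0L) break
      for (b in bad) x[(3L * b - 2L):(3L * b)] <- draw(3L)
    }
  }
  x
}

# infinite-sites event planting: each column receives at most one event
# across the whole triplet. Branches are laid out in the order outgroup,
# nearest, focal, and each branch's event probability is defined per column
# still untouched by the earlier branches (slice widths carry the cascade
# factor), so the per-surveyed-site rates the polarization estimator reads
# out equal the planted v, u (ratio m) exactly. `d` values are per-branch
# expected per-site divergences; per-class change probabilities are solved
# from d, m and the root composition.
evolve_triplet <- function(root, branches, m, gc_comp, within_frac) {
  v <- branches * (1 - within_frac) / ((1 - gc_comp) + gc_comp * m)
  u <- m * v
  w <- branches * within_frac
  if (sum(u + w) > 1 || sum(v + w) > 1) {
    stop("divergences too large for the infinite-sites model")
  }
  n <- length(root)
  is_at <- root %in% .AT
  r <- runif(n)
  # per-column slice widths, cascade order outgroup -> nearest -> focal
  ord <- c("outgroup", "nearest", "focal")
  class_p <- function(b) ifelse(is_at, v[[b]], u[[b]])
  cuts <- matrix(0, n, 6L,
                 dimnames = list(NULL, c(rbind(paste0(ord, "_class"),
                                               paste0(ord, "_within")))))
  remaining <- rep(1, n)
  for (b in ord) {
    pc <- class_p(b)
    cuts[, paste0(b, "_class")] <- remaining * pc
    cuts[, paste0(b, "_within")] <- remaining * w[[b]]
    remaining <- remaining * (1 - pc - w[[b]])
  }
  upper <- t(apply(cuts, 1L, cumsum))
  slot <- rowSums(r >= cbind(0, upper[, -ncol(upper)])) *
    (r < upper[, ncol(upper)])
  seqs <- list(focal = root, nearest = root, outgroup = root)
  events <- NULL
  hit <- which(slot > 0)
  if (length(hit) > 0L) {
    kind <- colnames(cuts)[slot[hit]]
    branch <- sub("_(class|within)$", "", kind)
    within <- grepl("_within$", kind)
    from <- root[hit]
    to <- character(length(hit))
    to[within] <- chartr("ATGC", "TACG", from[within])
    cross <- !within
    to[cross] <- ifelse(from[cross] %in% .AT,
                        sample(.GC, sum(cross), replace = TRUE),
                        sample(.AT, sum(cross), replace = TRUE))
    cls <- ifelse(within, "within_class",
                  ifelse(from %in% .AT, "at_to_gc", "gc_to_at"))
    for (b in names(seqs)) {
      idx <- hit[branch == b]
      seqs[[b]][idx] <- to[branch == b]
    }
    events <- tibble::tibble(column = hit, branch = branch,
                             from = from, to = to, class = cls)
    events <- events[order(events$column), ]
  } else {
    events <- tibble::tibble(column = integer(0), branch = character(0),
                             from = character(0), to = character(0),
                             class = character(0))
  }
  list(seqs = seqs, events = events)
}

#' Simulate a tree with Ku states and (logit) GC responses
#'
#' Draws a pure-birth tree scaled to unit height, a binary Ku character
#' under a two-state Markov chain with stationary frequency `ku_prevalence`
#' (phylogenetically clumped but not confined to one clade), log10 genome
#' length by Brownian motion, and the response
#' `y = X beta + eps`, `eps ~ N(0, sigma_p2 V + sigma_e2 I)` with `V` the
#' covariance of the chosen trait model on the simulated tree.
#'
#' @param n_tips Number of tips (>= 10).
#' @param beta Coefficient 4-vector: intercept, Ku, log10 length,
#'   Ku-by-length interaction.
#' @param sigma_p2,sigma_e2 Phylogenetic and error variance (tree height is
#'   1, so heritability is `sigma_p2 / (sigma_p2 + sigma_e2)`).
#' @param ku_prevalence Stationary Ku frequency.
#' @param model `"BM"` or `"OU"` for the residual covariance.
#' @param ou_alpha OU selection strength (used when `model = "OU"`).
#' @param ku_rate Total switching rate of the Ku chain per unit tree height.
#' @param root_length,sigma_length Root value and BM standard deviation (per
#'   unit height) of log10 genome length.
#' @param star If `TRUE`, replaces the tree by a star tree with unit
#'   branches (PGLS = OLS check input).
#' @param n_genera Number of genus labels to assign by clustering the
#'   cophenetic distances (for the uniform-Ku filter); default
#'   `max(2, n_tips %/% 5)`.
#' @param seed Integer seed.
#' @return List: `tree` (`phylo`), `traits` (tibble `taxon`, `ku`,
#'   `log10_length`, `gc_logit`, `gc`, `genus`), `ledger` (planted
#'   parameters).
#' @export
gen_tree_traits <- function(n_tips, beta, sigma_p2, sigma_e2,
                            ku_prevalence = 0.3, model = c("BM", "OU"),
                            ou_alpha = 1, ku_rate = 20,
                            root_length = 6.5, sigma_length = 0.35,
                            star = FALSE, n_genera = NULL, seed = NULL) {
  model <- match.arg(model)
  if (n_tips < 10L) stop("`n_tips` must be at least 10")
  if (sigma_p2 <= 0 || sigma_e2 < 0) stop("variances must be positive")
  if (length(beta) != 4L) stop("`beta` must have length 4")
  with_seed_if(seed, {
    if (star) {
      tree <- ape::stree(n_tips, type = "star")
      tree$edge.length <- rep(1, nrow(tree$edge))
    } else {
      tree <- ape::rphylo(n_tips, birth = 1, death = 0)
      depth <- max(ape::node.depth.edgelength(tree))
      tree$edge.length <- tree$edge.length / depth
    }
    tree$tip.label <- sprintf("t%03d", seq_len(n_tips))
    ku <- sim_binary_markov(tree, prevalence = ku_prevalence,
                            rate = ku_rate)
    len <- sim_bm_trait(tree, root = root_length, sigma = sigma_length)
    V <- if (model == "BM") bm_covariance(tree)
         else ou_covariance(tree, ou_alpha)
    X <- cbind(1, ku, len, ku * len)
    Sigma <- sigma_p2 * V + diag(sigma_e2, n_tips)
    eps <- drop(crossprod(chol(Sigma), rnorm(n_tips)))
    y <- drop(X %*% beta) + eps
    genus <- assign_genera(tree, n_genera %||% max(2L, n_tips %/% 5L))
    traits <- tibble::tibble(
      taxon = tree$tip.label, ku = ku, log10_length = len,
      gc_logit = y, gc = inv_logit_gc(y), genus = genus
    )
    list(
      tree = tree, traits = traits,
      ledger = list(generator = "gen_tree_traits", seed = seed,
                    beta = beta, sigma_p2 = sigma_p2, sigma_e2 = sigma_e2,
                    ku_prevalence = ku_prevalence, model = model,
                    ou_alpha = if (model == "OU") ou_alpha else NA_real_,
                    ku_rate = ku_rate, sigma_length = sigma_length,
                    root_length = root_length)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two-state Markov chain down the tree; rates q01 = rate * prev,
# q10 = rate * (1 - prev), so the stationary frequency of state 1 is prev
sim_binary_markov <- function(tree, prevalence, rate) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  state <- integer(n_node)
  root <- n_tip + 1L
  state[root] <- stats::rbinom(1L, 1L, prevalence)
  q01 <- rate * prevalence
  q10 <- rate * (1 - prevalence)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    t_e <- ord$edge.length[e]
    decay <- exp(-(q01 + q10) * t_e)
    p1 <- prevalence + (state[par] - prevalence) * decay
    state[child] <- stats::rbinom(1L, 1L, p1)
  }
  state[seq_len(n_tip)]
}

# Brownian trait down the tree
sim_bm_trait <- function(tree, root, sigma) {
  n_tip <- length(tree$tip.label)
  val <- numeric(n_tip + tree$Nnode)
  val[n_tip + 1L] <- root
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    val[child] <- val[par] + rnorm(1L, 0, sigma * sqrt(ord$edge.length[e]))
  }
  val[seq_len(n_tip)]
}

# genus labels from average-linkage clustering of patristic distances
assign_genera <- function(tree, k) {
  D <- ape::cophenetic.phylo(tree)
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = "average"),
                      k = min(k, length(tree$tip.label)))
  paste0("genus", cl[tree$tip.label])
}

#' Simulate gene alignments with and without recombination
#'
#' Non-recombinant genes evolve all sites on one tree; recombinant genes are
#' mosaics whose left half evolves on that tree and right half on an
#' independently drawn (discordant) tree over the same taxa. Recombinant
#' genes may additionally have their equilibrium GC shifted by
#' `gc_shift_recomb`, planting the GC contrast the recombination analysis
#' looks for.
#'
#' @param n_genes Number of genes.
#' @param recomb_fraction Fraction of genes simulated as mosaics.
#' @param tree_depth Root-to-tip height of the simulated trees (expected
#'   substitutions per site).
#' @param gc_shift_recomb Additive GC shift for recombinant genes.
#' @param n_taxa Taxa per alignment.
#' @param gene_length Alignment length per gene.
#' @param base_gc Background equilibrium GC (default 0.5).
#' @param seed Integer seed.
#' @return List: `alignments` (named list of named character vectors),
#'   `ledger` (tibble `gene_id`, `recombinant`, `gc_target`, plus the two
#'   trees).
#' @export
gen_gene_alignments <- function(n_genes, recomb_fraction = 0,
                                tree_depth = 0.3, gc_shift_recomb = 0,
                                n_taxa = 10L, gene_length = 600L,
                                base_gc = 0.5, seed = NULL) {
  if (recomb_fraction < 0 || recomb_fraction > 1) {
    stop("`recomb_fraction` must lie in [0, 1]")
  }
  with_seed_if(seed, {
    scale_tree <- function(tr) {
      tr$edge.length <- tr$edge.length /
        max(ape::node.depth.edgelength(tr)) * tree_depth
      tr$tip.label <- sprintf("s%02d", seq_len(n_taxa))
      tr
    }
    tree_a <- scale_tree(ape::rphylo(n_taxa, 1, 0))
    tree_b <- scale_tree(ape::rphylo(n_taxa, 1, 0))
    n_rec <- round(n_genes * recomb_fraction)
    recombinant <- c(rep(TRUE, n_rec), rep(FALSE, n_genes - n_rec))
    alignments <- purrr::map(seq_len(n_genes), function(g) {
      gc <- base_gc + if (recombinant[g]) gc_shift_recomb else 0
      if (recombinant[g]) {
        half <- gene_length %/% 2L
        left <- sim_tree_sites(tree_a, half, gc)
        right <- sim_tree_sites(tree_b, gene_length - half, gc)
        mat <- cbind(left, right)
      } else {
        mat <- sim_tree_sites(tree_a, gene_length, gc)
      }
      setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat))
    })
    names(alignments) <- sprintf("gene%03d", seq_len(n_genes))
    list(
      alignments = alignments,
      ledger = list(
        generator = "gen_gene_alignments", seed = seed,
        genes = tibble::tibble(
          gene_id = names(alignments), recombinant = recombinant,
          gc_target = base_gc + ifelse(recombinant, gc_shift_recomb, 0)
        ),
        tree_a = tree_a, tree_b = tree_b, tree_depth = tree_depth
      )
    )
  })
}

# site-wise simulation down a tree under an F81-like model with GC-biased
# stationary frequencies; returns a taxa x sites character matrix
sim_tree_sites <- function(tree, n_sites, gc) {
  freqs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_node, n_sites)
  states[n_tip + 1L, ] <- sample.int(4L, n_sites, replace = TRUE,
                                     prob = freqs)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    p_change <- 1 - exp(-ord$edge.length[e])
    x <- states[par, ]
    hit <- runif(n_sites) < p_change
    if (any(hit)) {
      x[hit] <- sample.int(4L, sum(hit), replace = TRUE, prob = freqs)
    }
    states[child, ] <- x
  }
  mat <- matrix(.ACGT[states[seq_len(n_tip), ]], n_tip, n_sites)
  rownames(mat) <- tree$tip.label
  mat
}

#' Simulate a genome with planted recognition motifs and flank structure
#'
#' Builds an i.i.d. background at `background_gc`, guaranteed free of
#' spurious motif matches (offending background windows are redrawn), then
#' plants `n_sites` non-overlapping motif instances at well-separated
#' positions and writes their flanking bases out to
#' `length(flank_profile)` bp per side with per-distance GC probability
#' `flank_profile[d]`.
#'
#' @param length Genome length.
#' @param background_gc Background GC content.
#' @param motif IUPAC recognition sequence.
#' @param n_sites Number of planted instances.
#' @param flank_profile Numeric vector (length <= 200) of per-distance GC
#'   probabilities; default flat at `background_gc`.
#' @param topology `"circular"` (default) or `"linear"`.
#' @param seed Integer seed.
#' @return List: `seq` (character), `topology`, `ledger` (planted site
#'   tibble with 0-based half-open coordinates, parameters).
#' @export
gen_genome_with_motifs <- function(length, background_gc, motif, n_sites,
                                   flank_profile = NULL,
                                   topology = c("circular", "linear"),
                                   seed = NULL) {
  topology <- match.arg(topology)
  motif <- toupper(motif)
  w <- nchar(motif)
  flank_len <- if (is.null(flank_profile)) 200L else base::length(flank_profile)
  if (is.null(flank_profile)) flank_profile <- rep(background_gc, flank_len)
  if (n_sites * (w + 2L * flank_len) > length) stop("infeasible packing")
  with_seed_if(seed, {
    block <- length %/% n_sites
    margin <- flank_len
    if (block - w - 2L * margin < 1L) stop("infeasible packing")
    starts0 <- vapply(seq_len(n_sites) - 1L, function(b) {
      as.integer(b * block + margin +
                   sample.int(block - w - 2L * margin, 1L) - 1L)
    }, integer(1))
    draw_bg <- function(k) {
      sample(.ACGT, k, replace = TRUE,
             prob = c((1 - background_gc) / 2, background_gc / 2,
                      background_gc / 2, (1 - background_gc) / 2))
    }
    genome <- draw_bg(length)
    instances <- character(n_sites)
    for (i in seq_len(n_sites)) {
      inst <- vapply(strsplit(motif, "", fixed = TRUE)[[1]],
                     function(code) sample(.IUPAC[[code]], 1L),
                     character(1))
      instances[i] <- paste(inst, collapse = "")
      genome[(starts0[i] + 1L):(starts0[i] + w)] <- inst
      for (d in seq_len(flank_len)) {
        gc_here <- runif(2L) < flank_profile[d]
        pos <- c(starts0[i] - d, starts0[i] + w - 1L + d)
        if (topology == "circular") pos <- pos %% length
        ok <- pos >= 0L & pos < length
        pos <- pos[ok]; gh <- gc_here[ok]
        genome[pos + 1L] <- ifelse(gh, sample(.GC, base::length(pos),
                                              replace = TRUE),
                                   sample(.AT, base::length(pos),
                                          replace = TRUE))
      }
    }
    planted <- tibble::tibble(start = starts0, end = starts0 + w)
    # redraw background windows that spuriously match the motif (either
    # strand) until only the planted sites remain
    protected <- unlist(purrr::map2(starts0 + 1L, starts0 + w, seq))
    for (iter in seq_len(100L)) {
      hits <- find_sites(paste(genome, collapse = ""), motif,
                         topology = topology)
      spurious <- dplyr::anti_join(hits, planted, by = c("start", "end"))
      if (nrow(spurious) == 0L) break
      if (iter == 100L) stop("could not purge spurious motif matches")
      for (j in seq_len(nrow(spurious))) {
        idx <- (spurious$start[j] + 1L):(spurious$end[j])
        idx <- ((idx - 1L) %% length) + 1L
        idx <- setdiff(idx, protected)
        if (base::length(idx) == 0L) next
        genome[idx] <- draw_bg(base::length(idx))
      }
    }
    list(
      seq = paste(genome, collapse = ""),
      topology = topology,
      ledger = list(generator = "gen_genome_with_motifs", seed = seed,
                    motif = motif, background_gc = background_gc,
                    flank_profile = flank_profile, sites = planted,
                    instances = instances)
    )
  })
}
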