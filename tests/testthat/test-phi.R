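test_that("incompatibility score implements the four-gamete logic", {
  # 3 of 4 gametes -> compatible
  expect_equal(incompatibility_score(c("A", "A", "G", "G"),
                                     c("A", "G", "G", "G")), 0)
  # all 4 gametes -> one extra change needed
  expect_equal(incompatibility_score(c("A", "A", "G", "G"),
                                     c("A", "G", "A", "G")), 1)
  # missing data drops taxa pairwise: removing the fourth taxon breaks the
  # fourth gamete
  expect_equal(incompatibility_score(c("A", "A", "G", "G"),
                                     c("A", "G", "A", "-")), 0)
  # symmetry and invariance under state relabeling / taxon reordering
  withr::with_seed(42, {
    for (i in 1:30) {
      n <- sample(4:8, 1)
      a <- sample(c("A", "C", "G"), n, replace = TRUE)
      b <- sample(c("A", "C", "G"), n, replace = TRUE)
      s <- incompatibility_score(a, b)
      expect_equal(incompatibility_score(b, a), s)
      perm <- sample(n)
      expect_equal(incompatibility_score(a[perm], b[perm]), s)
      relab <- chartr("ACG", "GAC", a)
      expect_equal(incompatibility_score(relab, b), s)
    }
  })
})

test_that("incompatibility equals the exhaustive parsimony oracle", {
  withr::with_seed(13, {
    for (i in 1:40) {
      n <- sample(4:6, 1)
      k <- sample(2:3, 1)
      a <- sample(c("A", "C", "G")[1:k], n, replace = TRUE)
      b <- sample(c("A", "C", "G")[1:k], n, replace = TRUE)
      expect_equal(incompatibility_score(a, b),
                   incompat_parsimony_oracle(a, b),
                   info = paste(paste(a, collapse = ""),
                                paste(b, collapse = "")))
    }
  })
})

test_that("informative_sites retains exactly the parsimony-informative columns", {
  aln <- c(s1 = "AAGA", s2 = "ACGA", s3 = "GAGT", s4 = "GCGT")
  m <- informative_sites(aln)
  # column 1: A,A,G,G informative; column 2: A,C,A,C informative;
  # column 3 constant; column 4: A,A,T,T informative
  expect_equal(m$original_positions, c(1L, 2L, 4L))
  expect_equal(m$n_informative, 3L)
  # singleton states are not informative
  aln2 <- c(s1 = "A", s2 = "A", s3 = "A", s4 = "G")
  expect_equal(informative_sites(aln2)$n_informative, 0L)
})

test_that("phi statistic equals brute-force pair enumeration", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      n <- 8; k <- 12
      mat <- matrix(sample(c("A", "G"), n * k, replace = TRUE), n, k)
      rownames(mat) <- paste0("s", 1:n)
      # make all columns informative by construction
      mat[1:2, ] <- "A"; mat[3:4, ] <- "G"
      m <- informative_sites(mat)
      w <- sample(2:15, 1)
      got <- phi_statistic(m, window = w)
      k2 <- m$n_informative
      vals <- c()
      for (i in seq_len(k2 - 1)) for (j in (i + 1):k2) {
        if (j - i <= w)

          vals <- c(vals, incompatibility_score(m$codes[, i], m$codes[, j]))
      }
      expect_equal(got, mean(vals))
    }
  })
})

test_that("phi statistic is invariant under site-order reversal", {
  sim <- gen_gene_alignments(3, recomb_fraction = 1, tree_depth = 0.5,
                             seed = 8)
  for (aln in sim$alignments) {
    m <- informative_sites(aln)
    rev_m <- m
    rev_m$codes <- m$codes[, rev(seq_len(m$n_informative)), drop = FALSE]
    expect_equal(phi_statistic(m, window = 10),
                 phi_statistic(rev_m, window = 10))
  }
})

test_that("phi is zero on homoplasy-free alignments and positive on mosaics", {
  # two incompatible sites, window >= 1 -> statistic 1
  two <- matrix(c("A", "A", "G", "G",
                  "A", "G", "A", "G"), ncol = 2)
  rownames(two) <- paste0("s", 1:4)
  expect_equal(phi_statistic(informative_sites(two), window = 5), 1)
  # a perfectly tree-like (hierarchical, non-overlapping) character set
  clean <- matrix("A", 8, 6)
  clean[5:8, 1:3] <- "G"   # deep split, three identical supporting sites
  clean[1:2, 4:6] <- "C"   # nested split on the other side
  rownames(clean) <- paste0("s", 1:8)
  expect_equal(phi_statistic(informative_sites(clean), window = 10), 0)
})

test_that("permutation p-values hit the floor for strong mosaic signal", {
  sim <- gen_gene_alignments(2, recomb_fraction = 1, tree_depth = 1.5,
                             gene_length = 2000, seed = 31)
  res <- phi_permutation_test(informative_sites(sim$alignments[[1]]),
                              window = 20, n_perm = 199, seed = 1)
  expect_equal(res$p_perm, 1 / 200)
  expect_gt(res$n_informative, 20)
})

test_that("permutation test is reproducible under a seed and respects bounds", {
  sim <- gen_gene_alignments(1, recomb_fraction = 0, tree_depth = 0.4,
                             seed = 55)
  m <- informative_sites(sim$alignments[[1]])
  r1 <- phi_permutation_test(m, window = 10, n_perm = 99, seed = 7)
  r2 <- phi_permutation_test(m, window = 10, n_perm = 99, seed = 7)
  expect_identical(r1, r2)
  expect_gte(r1$p_perm, 1 / 100)
  expect_lte(r1$p_perm, 1)
  expect_error(phi_permutation_test(m, n_perm = 0), "at least 1")
  # degenerate input: fewer than two informative sites
  tiny <- informative_sites(c(a = "AA", b = "AA", c = "AA", d = "AA"))
  expect_true(is.na(phi_permutation_test(tiny, n_perm = 10)$p_perm))
})

test_that("BH correction matches hand-worked and oracle results", {
  expect_equal(bh_correct(c(0.001, 0.04, 0.9), fdr = 0.05),
               c(TRUE, FALSE, FALSE))
  expect_equal(bh_correct(rep(1, 5)), rep(FALSE, 5))
  expect_equal(bh_correct(numeric(0)), logical(0))
  expect_error(bh_correct(c(0.5, 1.2)), "0, 1")
  withr::with_seed(17, {
    for (i in 1:200) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      fdr <- sample(c(0.01, 0.05, 0.1), 1)
      expect_equal(bh_correct(p, fdr), bh_oracle(p, fdr))
    }
  })
})

test_that("gc_contrast detects a planted GC excess in recombining genes", {
  withr::with_seed(12, {
    n_cl <- 50
    tbl <- purrr::map_dfr(seq_len(n_cl), function(cl) {
      n_genes <- sample(6:12, 1)
      rec <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n_genes - 2, TRUE))
      tibble::tibble(
        cluster_id = paste0("cl", cl),
        gene_id = paste0("g", seq_len(n_genes)),
        recombining = rec,
        gene_gc = 0.5 + rnorm(n_genes, 0, 0.01) + ifelse(rec, 0.02, 0)
      )
    })
    res <- gc_contrast(tbl)
    expect_equal(nrow(res$clusters), n_cl)
    expect_equal(mean(res$clusters$gc_diff), 0.02, tolerance = 0.25)
    expect_lt(res$paired_test$p.value, 1e-6)
    expect_equal(unname(res$paired_test$parameter), n_cl - 1)
  })
})

test_that("gc_contrast classifies Ku clusters and runs the Welch contrast", {
  withr::with_seed(30, {
    genes <- purrr::map_dfr(1:12, function(cl) {
      ku <- cl <= 6
      tibble::tibble(
        cluster_id = paste0("cl", cl), gene_id = paste0("g", 1:6),
        recombining = rep(c(TRUE, FALSE), 3),
        gene_gc = 0.5 + rnorm(6, 0, 0.005) +
          ifelse(rep(c(TRUE, FALSE), 3), ifelse(ku, 0.03, 0.005), 0)
      )
    })
    # one Ku-positive member suffices to label a cluster Ku-encoding
    ku_tbl <- purrr::map_dfr(1:12, function(cl) {
      tibble::tibble(cluster_id = paste0("cl", cl),
                     genome_id = paste0("cl", cl, "_g", 1:5),
                     ku = if (cl <= 6) c(1, 0, 0, 0, 0) else 0)
    })
    res <- gc_contrast(genes, ku_table = ku_tbl)
    expect_equal(sum(res$clusters$ku_cluster), 6)
    expect_lt(res$welch_test$p.value, 0.01)
  })
})
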