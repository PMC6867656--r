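test_that("pairwise identity skips gaps and ambiguity and is symmetric", {
  cl <- make_cluster("ACGT", "ACGA", "AC-T")
  expect_equal(pairwise_identity(cl, "F", "N"), 0.75)
  expect_equal(pairwise_identity(cl, "F", "F"), 1)
  expect_equal(pairwise_identity(cl, "F", "O"), 1)  # gap column dropped
  expect_equal(pairwise_identity(cl, "N", "F"),
               pairwise_identity(cl, "F", "N"))
  cl2 <- make_cluster("ACGT", "ACGT", "NN--")
  expect_error(pairwise_identity(cl2, "F", "O"), "no comparable")
})

test_that("triplet assignment matches a brute-force identity search", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n_g <- 5
      base <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
      seqs <- sapply(1:n_g, function(i) {
        x <- base
        nmut <- sample(3:60, 1)
        pos <- sample(400, nmut)
        x[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
        paste(x, collapse = "")
      })
      names(seqs) <- paste0("g", 1:n_g)
      cl <- cluster_alignments("brute", list(gene1 = seqs))
      got <- assign_triplets(cl)
      idm <- sapply(names(seqs), function(a) {
        sapply(names(seqs), function(b) {
          if (a == b) NA else pairwise_identity(cl, a, b)
        })
      })
      for (r in seq_len(nrow(got))) {
        f <- got$focal[r]
        ident <- idm[, f]
        expect_equal(got$identity_focal_nearest[r], max(ident, na.rm = TRUE))
        expect_true(ident[got$nearest[r]] == max(ident, na.rm = TRUE))
        expect_true(ident[got$outgroup[r]] == min(ident, na.rm = TRUE))
      }
    }
  })
})

test_that("identity ties break to the lexicographically smallest id", {
  seqs <- c(b = "ACGTACGT", a = "ACGTACGA", c = "ACGTACGA", d = "TTTTACGT")
  cl <- cluster_alignments("tie", list(gene1 = seqs))
  got <- assign_triplets(cl)
  row <- got[got$focal == "b", ]
  expect_equal(row$nearest, "a")   # a and c tie at 7/8
  expect_equal(row$outgroup, "d")
})

test_that("clusters with fewer than three genomes are rejected", {
  expect_error(
    assign_triplets(cluster_alignments("c", list(g = c(a = "AC", b = "AC")))),
    "fewer than 3")
})

test_that("polarization counts follow the outgroup-consistency rules", {
  # one informative AT->GC event: F=G, N=A, O=A
  cl <- make_cluster("G", "A", "A")
  cnt <- polarize_polymorphisms(cl, "F", "N", "O")
  expect_equal(cnt$n_at_to_gc, 1)
  expect_equal(cnt$n_gc_to_at, 0)
  expect_equal(cnt$n_at_sites, 1)
  # GC<->GC change is surveyed but not informative
  cnt2 <- polarize_polymorphisms(make_cluster("C", "G", "G"), "F", "N", "O")
  expect_equal(cnt2$n_informative, 0)
  expect_equal(cnt2$n_gc_sites, 1)
  # outgroup matches neither -> column discarded entirely
  cnt3 <- polarize_polymorphisms(make_cluster("A", "C", "G"), "F", "N", "O")
  expect_equal(unlist(cnt3), c(n_at_to_gc = 0, n_gc_to_at = 0,
                               n_at_sites = 0, n_gc_sites = 0,
                               n_informative = 0))
  # gap or ambiguity in any member removes the column (only the first
  # column of this three-column gene survives)
  cnt4 <- polarize_polymorphisms(make_cluster("G-N", "A-A", "AAA"),
                                 "F", "N", "O")
  expect_equal(cnt4$n_at_sites, 1)
  expect_equal(cnt4$n_at_to_gc, 1)
  # nearest-derived column (O == F != N) is not a focal event and is not
  # in the consistent denominator
  cnt5 <- polarize_polymorphisms(make_cluster("A", "G", "A"), "F", "N", "O")
  expect_equal(cnt5$n_informative, 0)
  expect_equal(cnt5$n_at_sites, 0)
  cnt5b <- polarize_polymorphisms(make_cluster("A", "G", "A"), "F", "N", "O",
                                  denominator = "all")
  expect_equal(cnt5b$n_at_sites, 1)
})

test_that("polarized counts equal the generator event ledger", {
  sim <- gen_triplet_cluster(10000, m = 3, divergence_fn = 0.006,
                             divergence_fo = 0.04, gc0 = 0.45, seed = 101)
  cnt <- polarize_polymorphisms(sim$cluster, "F", "N", "O")
  ev <- sim$ledger$events
  # under the generator's infinite-sites planting the ledger predicts the
  # polarized counts exactly
  expect_equal(cnt$n_at_to_gc,
               sum(ev$branch == "focal" & ev$class == "at_to_gc"))
  expect_equal(cnt$n_gc_to_at,
               sum(ev$branch == "focal" & ev$class == "gc_to_at"))
  # denominators: columns with no event off the focal branch, by root class
  root <- strsplit(sim$ledger$root, "")[[1]]
  excluded <- unique(ev$column[ev$branch != "focal"])
  n_cols <- length(root)
  surveyed_at <- sum(root[setdiff(seq_len(n_cols), excluded)] %in% c("A", "T"))
  expect_equal(cnt$n_at_sites, surveyed_at)
})

test_that("swapping A<->G and T<->C labels swaps the event classes", {
  sim <- gen_triplet_cluster(5000, m = 2, divergence_fn = 0.008,
                             divergence_fo = 0.03, gc0 = 0.5, seed = 77)
  cnt <- polarize_polymorphisms(sim$cluster, "F", "N", "O")
  swapped <- purrr::map(sim$cluster$gene_alignments, function(mat) {
    sw <- chartr("AGTC", "GACT", mat)
    setNames(apply(sw, 1L, paste, collapse = ""), rownames(mat))
  })
  cl2 <- cluster_alignments("swapped", swapped)
  cnt2 <- polarize_polymorphisms(cl2, "F", "N", "O")
  expect_equal(cnt2$n_at_to_gc, cnt$n_gc_to_at)
  expect_equal(cnt2$n_gc_to_at, cnt$n_at_to_gc)
  expect_equal(cnt2$n_at_sites, cnt$n_gc_sites)
})

test_that("divergence and informative-site filters are boundary-inclusive", {
  tbl <- tibble::tibble(
    identity_focal_nearest = c(0.985, 0.99, 0.995, 0.995),
    n_informative = c(50, 5, 4, 5)
  )
  kept <- apply_filters(tbl)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$identity_focal_nearest >= 0.99))
  expect_true(all(kept$n_informative >= 5))
})

test_that("bias estimation implements u/v and v/(u+v)", {
  cnt <- tibble::tibble(n_at_to_gc = 10, n_gc_to_at = 10,
                        n_at_sites = 100, n_gc_sites = 100)
  est <- estimate_bias(cnt)
  expect_equal(est$m, 1)
  expect_equal(est$expected_gc, 0.5)
  # per-site rates in ratio 4.5 : 1
  est2 <- estimate_bias(tibble::tibble(n_at_to_gc = 10, n_gc_to_at = 45,
                                       n_at_sites = 100, n_gc_sites = 100))
  expect_equal(est2$m, 4.5)
  expect_equal(est2$expected_gc, 1 / (1 + 4.5), tolerance = 1e-12)
  # degenerate corners are flagged
  est3 <- estimate_bias(tibble::tibble(n_at_to_gc = 0, n_gc_to_at = 5,
                                       n_at_sites = 100, n_gc_sites = 100))
  expect_equal(est3$expected_gc, 0)
  expect_equal(est3$bias_flag, "no_at_to_gc")
  est4 <- estimate_bias(tibble::tibble(n_at_to_gc = 5, n_gc_to_at = 0,
                                       n_at_sites = 100, n_gc_sites = 100))
  expect_equal(est4$expected_gc, 1)
  expect_equal(est4$bias_flag, "no_gc_to_at")
  # expected_gc strictly decreasing in m
  ms <- c(0.5, 1, 2, 4, 8)
  egs <- 1 / (1 + ms)
  expect_true(all(diff(egs) < 0))
})

test_that("fourfold restriction surveys a subset of all columns", {
  sim <- gen_triplet_cluster(9000, m = 3, divergence_fn = 0.008,
                             divergence_fo = 0.04, gc0 = 0.5,
                             coding = TRUE, seed = 5)
  full <- polarize_polymorphisms(sim$cluster, "F", "N", "O")
  four <- fourfold_restrict(sim$cluster, "F", "N", "O")
  expect_lte(four$n_at_sites, full$n_at_sites)
  expect_lte(four$n_gc_sites, full$n_gc_sites)
  expect_lte(four$n_informative, full$n_informative)
  expect_gt(four$n_at_sites + four$n_gc_sites, 0)
  # a difference at a twofold (non-fourfold) third position is invisible
  # to the restricted scan: GAC/GAT both encode Asp
  cl <- make_cluster("GAC", "GAT", "GAT")
  expect_equal(polarize_polymorphisms(cl, "F", "N", "O")$n_informative, 1)
  expect_equal(fourfold_restrict(cl, "F", "N", "O")$n_informative, 0)
})
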