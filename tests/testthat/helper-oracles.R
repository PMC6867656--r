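# Independent oracles used across the suite. Each is a deliberately naive,
# definition-level implementation kept separate from the package code paths
# it checks.

# Benjamini-Hochberg step-up by direct threshold search
bh_oracle <- function(p, fdr) {
  n <- length(p)
  if (n == 0L) return(logical(0))
  ord <- order(p)
  sorted <- p[ord]
  below <- which(sorted <= (seq_len(n) / n) * fdr)
  out <- rep(FALSE, n)
  if (length(below) > 0L) out[ord[seq_len(max(below))]] <- TRUE
  out
}

# fourfold-site oracle: translate all four third-base variants of each codon
fourfold_oracle <- function(seq, frame = 0L) {
  code <- Biostrings::GENETIC_CODE
  chars <- strsplit(toupper(seq), "")[[1]]
  out <- integer(0)
  starts <- seq.int(frame + 1L, by = 3L,
                    length.out = (length(chars) - frame) %/% 3L)
  for (s in starts) {
    codon <- chars[s:(s + 2L)]
    if (!all(codon %in% c("A", "C", "G", "T"))) next
    aas <- sapply(c("A", "C", "G", "T"), function(b) {
      code[paste0(codon[1], codon[2], b)]
    })
    if (length(unique(aas)) == 1L) out <- c(out, s + 1L)  # 0-based third pos
  }
  out
}

# refined-incompatibility oracle: minimum extra parsimony steps over all
# unrooted topologies (phangorn Fitch), relative to the per-character minima
incompat_parsimony_oracle <- function(site_i, site_j) {
  keep <- site_i %in% c("A", "C", "G", "T") & site_j %in% c("A", "C", "G", "T")
  site_i <- site_i[keep]; site_j <- site_j[keep]
  n <- length(site_i)
  if (n < 4L) {
    # fewer than 4 taxa: any two characters fit on the (unique) tree
    return(0L)
  }
  taxa <- paste0("t", seq_len(n))
  mat <- cbind(site_i, site_j)
  rownames(mat) <- taxa
  dat <- phangorn::phyDat(mat, type = "DNA")
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  scores <- sapply(trees, function(tr) phangorn::parsimony(tr, dat))
  min_i <- length(unique(site_i)) - 1L
  min_j <- length(unique(site_j)) - 1L
  min(scores) - min_i - min_j
}

# closed-form point-biserial correlation
point_biserial_oracle <- function(gc, ku) {
  n1 <- sum(ku == 1); n0 <- sum(ku == 0); n <- length(ku)
  (mean(gc[ku == 1]) - mean(gc[ku == 0])) / sd(gc) *
    sqrt(n1 * n0 / (n * (n - 1)))
}

# small deterministic cluster builder for polarization unit tests: one gene,
# rows given explicitly
make_cluster <- function(F, N, O, cluster_id = "c1") {
  cluster_alignments(cluster_id, list(gene1 = c(F = F, N = N, O = O)))
}
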