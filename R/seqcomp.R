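#' Fractional GC content of a nucleotide sequence
#'
#' GC content is computed over unambiguous bases only: ambiguity codes
#' (including `N`) and gap characters contribute to neither the numerator nor
#' the denominator, so draft-genome N-runs cannot bias composition.
#'
#' @param seq Character vector of nucleotide sequences (case-insensitive), or
#'   a [Biostrings::DNAStringSet]/[Biostrings::DNAString].
#' @return Numeric vector of GC fractions in `[0, 1]`, one per sequence.
#' @examples
#' gc_content(c("GCGC", "ATAT", "GATCN"))
#' @export
gc_content <- function(seq) {
  seq <- as_sequence_chr(seq)
  counts <- base_counts(seq)
  denom <- rowSums(counts)
  if (any(denom == 0)) {
    stop("GC content undefined: sequence contains no unambiguous A/C/G/T")
  }
  unname((counts[, "G"] + counts[, "C"]) / denom)
}

# coerce supported sequence containers to an uppercase character vector
as_sequence_chr <- function(seq) {
  if (methods::is(seq, "DNAString")) seq <- Biostrings::DNAStringSet(seq)
  if (methods::is(seq, "XStringSet")) seq <- as.character(seq)
  if (!is.character(seq)) stop("`seq` must be character or DNAString(Set)")
  if (length(seq) < 1L || any(!nzchar(seq))) stop("sequences must be non-empty")
  toupper(seq)
}

# A/C/G/T counts per sequence, ambiguity excluded
base_counts <- function(seq) {
  x <- Biostrings::DNAStringSet(seq)
  Biostrings::letterFrequency(x, letters = .ACGT, OR = 0)[, , drop = FALSE]
}

#' Logit transform of GC content
#'
#' `logit_gc()` maps a GC fraction to the real line via `log(gc / (1 - gc))`;
#' `inv_logit_gc()` is its inverse. The transform makes a bounded composition
#' usable as the response of Gaussian trait models.
#'
#' @param gc Numeric vector of fractions strictly inside `(0, 1)`.
#' @param x Numeric vector on the logit scale.
#' @return Numeric vector.
#' @examples
#' logit_gc(0.75)
#' inv_logit_gc(logit_gc(0.42))
#' @export
logit_gc <- function(gc) {
  if (!is.numeric(gc)) stop("`gc` must be numeric")
  if (any(!is.finite(gc)) || any(gc <= 0) || any(gc >= 1)) {
    stop("`gc` must lie strictly inside (0, 1)")
  }
  qlogis(gc)
}

#' @rdname logit_gc
#' @export
inv_logit_gc <- function(x) plogis(x)

#' Fourfold degenerate site positions of a coding sequence
#'
#' Returns the third codon positions whose codon family is fourfold
#' degenerate, i.e. the first two bases determine the amino acid for every
#' choice of third base (standard code: GCx, CGx, GGx, CTx, CCx, TCx, ACx,
#' GTx). Codons containing ambiguity codes or gaps yield no site.
#'
#' @param seq A single coding sequence (character or DNAString).
#' @param frame Integer offset (0, 1 or 2) of the first complete codon.
#' @param code_table NCBI genetic code id as a string, passed to
#'   [Biostrings::getGeneticCode()]. Default `"1"` (standard code).
#' @return Integer vector of 0-based positions (third codon positions).
#' @examples
#' fourfold_sites("GGAATG") # glycine codon: position 2
#' @export
fourfold_sites <- function(seq, frame = 0L, code_table = "1") {
  seq <- as_sequence_chr(seq)
  if (length(seq) != 1L) stop("`seq` must be a single sequence")
  if (!frame %in% 0:2) stop("`frame` must be 0, 1 or 2")
  prefixes <- fourfold_prefixes(code_table)
  n <- nchar(seq)
  starts <- seq.int(frame + 1L, by = 3L, length.out = (n - frame) %/% 3L)
  if (length(starts) == 0L) return(integer(0))
  codons <- substring(seq, starts, starts + 2L)
  pre <- substr(codons, 1L, 2L)
  ok <- pre %in% prefixes & substr(codons, 3L, 3L) %in% .ACGT
  as.integer(starts[ok] + 1L)  # 0-based third position = start - 1 + 2
}

# dinucleotide prefixes whose codon family is fourfold degenerate
fourfold_prefixes <- function(code_table = "1") {
  code <- Biostrings::getGeneticCode(as.character(code_table))
  pre <- as.vector(outer(.ACGT, .ACGT, paste0))
  keep <- vapply(pre, function(p) {
    aa <- code[paste0(p, .ACGT)]
    length(unique(aa)) == 1L
  }, logical(1))
  pre[keep]
}

#' Composition summary of a sequence
#'
#' One-row tibble with overall GC content, its logit, and (when a reading
#' frame is supplied) GC content restricted to fourfold degenerate sites
#' (GC4), the weakly selected proxy for mutational input.
#'
#' @inheritParams fourfold_sites
#' @param frame `NULL` for non-coding input (GC4 columns are `NA`), otherwise
#'   the frame offset of the first complete codon.
#' @return Tibble with columns `gc`, `gc_logit`, `n_sites_counted`, `gc4`,
#'   `n_fourfold_sites`.
#' @export
gc_summary <- function(seq, frame = NULL, code_table = "1") {
  seq <- as_sequence_chr(seq)
  if (length(seq) != 1L) stop("`seq` must be a single sequence")
  counts <- base_counts(seq)
  n_counted <- sum(counts)
  gc <- gc_content(seq)
  gc4 <- NA_real_
  n4 <- 0L
  if (!is.null(frame)) {
    pos <- fourfold_sites(seq, frame = frame, code_table = code_table)
    n4 <- length(pos)
    if (n4 > 0L) {
      bases <- substring(seq, pos + 1L, pos + 1L)
      gc4 <- mean(bases %in% .GC)
    }
  }
  tibble::tibble(
    gc = gc,
    gc_logit = if (gc > 0 && gc < 1) logit_gc(gc) else NA_real_,
    n_sites_counted = n_counted,
    gc4 = gc4,
    n_fourfold_sites = n4
  )
}
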