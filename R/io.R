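#' Read a directory of per-cluster, per-gene aligned FASTA files
#'
#' Expects one subdirectory per cluster, each containing one FASTA file per
#' gene (`<gene_id>.fasta`/`.fa`); record ids are genome ids. Clusters whose
#' genes disagree on the genome set are skipped with a message.
#'
#' @param path Directory containing cluster subdirectories.
#' @return Named list of [cluster_alignments()] objects.
#' @export
read_cluster_dir <- function(path) {
  dirs <- list.dirs(path, recursive = FALSE)
  if (length(dirs) == 0L) stop("no cluster subdirectories under ", path)
  out <- list()
  for (d in dirs) {
    id <- basename(d)
    files <- list.files(d, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    if (length(files) == 0L) {
      message("cluster ", id, ": no FASTA files, skipped"); next
    }
    genes <- purrr::map(files, function(f) {
      x <- Biostrings::readDNAStringSet(f)
      setNames(as.character(x), names(x))
    })
    names(genes) <- sub("\\.(fa|fasta)$", "", basename(files))
    cl <- tryCatch(cluster_alignments(id, genes), error = function(e) {
      message("cluster ", id, ": ", conditionMessage(e), "; skipped")
      NULL
    })
    if (!is.null(cl)) out[[id]] <- cl
  }
  out
}

#' Write a cluster to per-gene FASTA files
#'
#' Inverse of [read_cluster_dir()] for one cluster: writes
#' `<path>/<cluster_id>/<gene_id>.fasta`.
#'
#' @param cluster A [cluster_alignments()] object.
#' @param path Output directory.
#' @return The cluster directory path, invisibly.
#' @export
write_cluster_dir <- function(cluster, path) {
  dir <- file.path(path, cluster$cluster_id)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gene in names(cluster$gene_alignments)) {
    mat <- cluster$gene_alignments[[gene]]
    seqs <- apply(mat, 1L, paste, collapse = "")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(seqs),
      file.path(dir, paste0(gene, ".fasta"))
    )
  }
  invisible(dir)
}

#' Read a tab-separated motif table
#'
#' Columns: `genome_id`, `enzyme_id`, `pattern` (IUPAC recognition
#' sequence).
#'
#' @param path TSV file path.
#' @return Tibble.
#' @export
read_motif_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "enzyme_id", "pattern")
  if (!all(need %in% names(tbl))) {
    stop("motif table must have columns ", paste(need, collapse = ", "))
  }
  tibble::as_tibble(tbl)
}

#' Read a tab-separated trait table
#'
#' Columns: `taxon`, `gc` (fraction), `ku` (0/1), `log10_length`; optional
#' `gc4`, `genus`.
#'
#' @param path TSV file path.
#' @return Tibble.
#' @export
read_trait_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon", "gc", "ku", "log10_length")
  if (!all(need %in% names(tbl))) {
    stop("trait table must have columns ", paste(need, collapse = ", "))
  }
  tibble::as_tibble(tbl)
}
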