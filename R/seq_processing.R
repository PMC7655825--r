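# Read-1 parsing, barcode/UMI error correction, poly(A) trimming, UMI
# collapse and molecule counting. Alignment is external: gene assignments
# arrive as a tag table (read_id, gene, species, chromosome) whose producer
# guarantees unique exonic mapping on the annotated strand.

#' Parse read 1 into observed barcodes and UMI
#'
#' Layout: NN (8-nt S barcode) NN (8-nt Q barcode) NNNN, where the N
#' positions concatenate to the 8-nt UMI. Reads shorter than 24 nt yield NA
#' in every field (dropped downstream).
#'
#' @param seq character vector of read-1 sequences.
#' @return data.frame with columns `s_obs`, `q_obs`, `umi_obs`.
#' @export
#' @examples
#' parse_read1(paste0("TT", "ACGTCAGT", "GA", "TGCATGCA", "AACG", "TT"))
parse_read1 <- function(seq) {
  ok <- !is.na(seq) & nchar(seq) >= 24
  out <- data.frame(
    s_obs = ifelse(ok, substr(seq, 3, 10), NA_character_),
    q_obs = ifelse(ok, substr(seq, 13, 20), NA_character_),
    umi_obs = ifelse(ok, paste0(substr(seq, 1, 2), substr(seq, 11, 12),
                                substr(seq, 21, 24)), NA_character_),
    stringsAsFactors = FALSE
  )
  out$umi_obs[!ok] <- NA_character_
  out
}

# Lookup table mapping every whitelist sequence and each of its 1-substitution
# neighbors to the whitelist sequence. Valid only when the whitelist has
# minimum pairwise Hamming distance >= 3 (neighborhoods then disjoint).
build_correction_map <- function(whitelist) {
  targets <- rep(whitelist, each = 1 + 3 * nchar(whitelist[1]))
  keys <- unlist(lapply(whitelist, function(w) c(w, hamming1_neighbors(w))))
  setNames(targets, keys)
}

#' Correct an observed barcode against a whitelist
#'
#' Exact match, else the unique Hamming-distance-1 neighbor, else NA
#' (rejected). Uniqueness of the neighbor is guaranteed by the whitelist's
#' minimum pairwise Hamming distance of 3. N bases match nothing.
#'
#' @param obs character vector of observed 8-nt barcodes.
#' @param whitelist character vector of designed barcodes.
#' @return character vector of corrected barcodes (NA where rejected).
#' @export
correct_barcode <- function(obs, whitelist) {
  map <- build_correction_map(whitelist)
  unname(map[obs])
}

#' Trim 3' poly(A) tails from read 2
#'
#' Removes the suffix starting at the first run of at least eight A's
#' (tracts of > 7 A's); fragments shorter than `min_len` after trimming are
#' discarded (NA).
#'
#' @param seq character vector of read-2 sequences.
#' @param min_len minimum fragment length kept (default 24).
#' @return character vector of trimmed fragments, NA where discarded.
#' @export
trim_polyA <- function(seq, min_len = 24L) {
  hit <- regexpr("AAAAAAAA", seq, fixed = TRUE)
  out <- ifelse(hit > 0, substr(seq, 1, hit - 1), seq)
  out[is.na(seq) | nchar(out) < min_len] <- NA_character_
  out
}

# Number of connected components of the Hamming-distance-1 graph over a set
# of (not necessarily unique) UMIs; one molecule per component. Union-find.
count_umi_components <- function(umis) {
  u <- unique(umis)
  m <- length(u)
  if (m <= 1) return(m)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  chars <- do.call(rbind, strsplit(u, "", fixed = TRUE))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (sum(chars[i, ] != chars[j, ]) == 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(m), find, integer(1))))
}

#' Collapse reads into unique molecules
#'
#' Reads sharing a cell barcode and gene whose UMIs are connected through
#' single-substitution (Hamming-1) edges are considered one cDNA molecule.
#'
#' @param records data.frame with columns `cell`, `gene`, `umi` (one row per
#'   kept read).
#' @return data.table with columns `cell`, `gene`, `molecules`.
#' @export
collapse_umis <- function(records) {
  dt <- data.table::as.data.table(records[, c("cell", "gene", "umi")])
  dt[, list(molecules = count_umi_components(umi)), by = c("cell", "gene")]
}

#' Call cell species from species-split read counts
#'
#' A cell is assigned the species claiming strictly more than `threshold` of
#' its reads; otherwise it is "mixed". Cells with zero reads are
#' "unclassified".
#'
#' @param counts numeric matrix, cells x species (column names = species).
#' @param threshold winning fraction, strict (default 0.90).
#' @return character vector of species calls, one per row.
#' @export
species_call <- function(counts, threshold = 0.90) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  frac <- counts / ifelse(tot == 0, 1, tot)
  top <- max.col(frac, ties.method = "first")
  call <- ifelse(frac[cbind(seq_len(nrow(counts)), top)] > threshold,
                 colnames(counts)[top], "mixed")
  call[tot == 0] <- "unclassified"
  call
}

#' Build the molecule count matrix from reads
#'
#' Full read-processing pipeline: parse read 1, correct both barcodes against
#' the whitelists (keeping only reads where both resolve), trim read-2
#' poly(A) tails and drop short fragments, join external gene tags by read
#' id, collapse UMIs, and count molecules per (cell, gene). If the tag table
#' has a `region` column, counting is per region and cell barcodes are
#' suffixed with "-<region>".
#'
#' @param r1,r2 character vectors of read sequences (names = read ids), or
#'   paths to FASTQ files.
#' @param tags data.frame with columns `read_id`, `gene`, and optionally
#'   `species`, `chromosome`, `region`.
#' @param s_whitelist,q_whitelist designed barcode sequences per role.
#' @return list with `counts` (sparse genes x cells dgCMatrix), `gene_info`
#'   (data.frame gene/species/chromosome where available) and `summary`
#'   (reads kept/dropped by reason).
#' @export
count_molecules <- function(r1, r2, tags, s_whitelist, q_whitelist) {
  read_fq <- function(x) {
    if (length(x) == 1 && file.exists(x)) {
      ss <- Biostrings::readDNAStringSet(x, format = "fastq")
      setNames(as.character(ss), sub(" .*", "", names(ss)))
    } else x
  }
  r1 <- read_fq(r1)
  r2 <- read_fq(r2)
  stopifnot(length(r1) == length(r2))
  ids <- names(r1)
  if (is.null(ids)) ids <- as.character(seq_along(r1))

  n_total <- length(r1)
  parsed <- parse_read1(r1)
  short1 <- is.na(parsed$s_obs)

  frag <- trim_polyA(r2)
  short2 <- !short1 & is.na(frag)

  s_cor <- correct_barcode(parsed$s_obs, s_whitelist)
  q_cor <- correct_barcode(parsed$q_obs, q_whitelist)
  bad_bc <- !short1 & !short2 & (is.na(s_cor) | is.na(q_cor))

  keep <- !short1 & !short2 & !bad_bc
  tagged <- match(ids, tags$read_id)
  unaligned <- keep & is.na(tagged)
  keep <- keep & !is.na(tagged)

  cell <- paste0(s_cor[keep], q_cor[keep])
  trow <- tagged[keep]
  if ("region" %in% names(tags)) {
    cell <- paste0(cell, "-", tags$region[trow])
  }
  records <- data.frame(
    cell = cell,
    gene = tags$gene[trow],
    umi = parsed$umi_obs[keep],
    stringsAsFactors = FALSE
  )
  mol <- collapse_umis(records)

  cells <- sort(unique(mol$cell))
  genes <- sort(unique(tags$gene))
  counts <- Matrix::sparseMatrix(
    i = match(mol$gene, genes), j = match(mol$cell, cells),
    x = mol$molecules, dims = c(length(genes), length(cells)),
    dimnames = list(genes, cells)
  )
  gene_info <- unique(tags[, intersect(c("gene", "species", "chromosome"),
                                       names(tags)), drop = FALSE])
  gene_info <- gene_info[match(genes, gene_info$gene), , drop = FALSE]
  rownames(gene_info) <- NULL
  list(
    counts = counts,
    gene_info = gene_info,
    summary = list(
      total_reads = n_total,
      dropped_short_read1 = sum(short1),
      dropped_short_fragment = sum(short2),
      dropped_incomplete_barcode = sum(bad_bc),
      dropped_unaligned = sum(unaligned),
      reads_kept = sum(keep),
      molecules = sum(mol$molecules)
    )
  )
}

#' Write / read a molecule count matrix directory
#'
#' MatrixMarket `matrix.mtx` (genes x cells) with `barcodes.tsv`,
#' `genes.tsv` (gene, species, chromosome) and `summary.json`.
#'
#' @param result output of [count_molecules()] (or a list with `counts` and
#'   optionally `gene_info`, `summary`).
#' @param dir output directory.
#' @return `dir` (write) or a list mirroring [count_molecules()] (read).
#' @export
write_count_matrix <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(result$counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(result$counts), file.path(dir, "barcodes.tsv"))
  gi <- result$gene_info
  if (is.null(gi)) gi <- data.frame(gene = rownames(result$counts))
  utils::write.table(gi, file.path(dir, "genes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(result$summary)) {
    jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  gene_info <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
  dimnames(counts) <- list(gene_info$gene,
                           readLines(file.path(dir, "barcodes.tsv")))
  summary_path <- file.path(dir, "summary.json")
  list(
    counts = counts, gene_info = gene_info,
    summary = if (file.exists(summary_path)) jsonlite::read_json(summary_path)
  )
}
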