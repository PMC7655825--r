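# Synthetic-data generators for every input the pipeline consumes, each
# emitting ground truth alongside. Defaults describe a desk-scale experiment:
# 20x on/off bead fluorescence with lognormal CV 0.3 and a per-bead Cy3
# autofluorescence offset large enough (sd = on_mean / 4) that the Cy3 on/off
# populations genuinely overlap while Cy5 stays clean, 10x10 microwell grids,
# ~20 expected counts per gene, and Chr7-gain / Chr10-loss at 1.5x / 0.5x.

rlnorm_mean <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Per-base substitutions at a fixed rate (errors never reproduce the
# original base).
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1),
                        character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate bead intensity tables
#'
#' Each bead carries a random (S, Q) barcode pair; its 8 x 2 intensities are
#' lognormal around `on_mean` or `off_mean` according to the code bits, and
#' a per-bead autofluorescence offset (half-normal, sd `autofluor_sd`) is
#' added to all Cy3 cycles, emulating the poorer on/off separation of the
#' shorter-wavelength channel.
#'
#' @param n_beads number of beads.
#' @param s_codes,q_codes named code maps (sequence -> 8-bit code).
#' @param on_mean,off_mean mean intensity of the 1 and 0 bit states (a.u.).
#' @param cv lognormal coefficient of variation.
#' @param autofluor_sd sd of the per-bead Cy3 offset (0 disables it).
#' @param pitch bead grid pitch in px (positions only).
#' @param seed integer seed.
#' @return list with `table` (bead intensity table) and `truth`
#'   (bead_id, s_barcode, q_barcode, s_code, q_code).
#' @export
simulate_bead_intensities <- function(n_beads, s_codes, q_codes,
                                      on_mean = 2000, off_mean = 100,
                                      cv = 0.3, autofluor_sd = 500,
                                      pitch = 30, seed = 1L) {
  if (!(on_mean > off_mean && off_mean > 0)) {
    stop("need on_mean > off_mean > 0")
  }
  if (cv < 0 || autofluor_sd < 0) stop("cv and autofluor_sd must be >= 0")
  empty <- data.frame(bead_id = integer(0), x = numeric(0), y = numeric(0))
  if (n_beads == 0) {
    for (cn in c(ch_cols("5"), ch_cols("3"))) empty[[cn]] <- numeric(0)
    return(list(table = empty,
                truth = data.frame(bead_id = integer(0), s_barcode = character(0),
                                   q_barcode = character(0), s_code = character(0),
                                   q_code = character(0))))
  }
  with_seed(seed, {
    s_bc <- sample(names(s_codes), n_beads, replace = TRUE)
    q_bc <- sample(names(q_codes), n_beads, replace = TRUE)
    s_code <- unname(s_codes[s_bc])
    q_code <- unname(q_codes[q_bc])
    offset <- if (autofluor_sd > 0) abs(rnorm(n_beads, 0, autofluor_sd)) else 0
    ncol_grid <- ceiling(sqrt(n_beads))
    tab <- data.frame(
      bead_id = seq_len(n_beads),
      x = ((seq_len(n_beads) - 1) %% ncol_grid) * pitch + pitch / 2,
      y = ((seq_len(n_beads) - 1) %/% ncol_grid) * pitch + pitch / 2
    )
    for (k in 1:8) {
      bit5 <- substr(s_code, k, k) == "1"
      bit3 <- substr(q_code, k, k) == "1"
      tab[[ch_cols("5")[k]]] <-
        rlnorm_mean(n_beads, 1, cv) * ifelse(bit5, on_mean, off_mean)
      tab[[ch_cols("3")[k]]] <-
        rlnorm_mean(n_beads, 1, cv) * ifelse(bit3, on_mean, off_mean) + offset
    }
    list(table = tab,
         truth = data.frame(bead_id = tab$bead_id, s_barcode = s_bc,
                            q_barcode = q_bc, s_code = s_code, q_code = q_code))
  })
}

add_disk <- function(img, x, y, r, value) {
  rows <- pmax(1, floor(y + 1 - r)):pmin(nrow(img), ceiling(y + 1 + r))
  cols <- pmax(1, floor(x + 1 - r)):pmin(ncol(img), ceiling(x + 1 + r))
  dy <- (rows - 1) - y
  dx <- (cols - 1) - x
  inside <- outer(dy^2, dx^2, `+`) <= r^2
  img[rows, cols][inside] <- value
  img
}

#' Simulate microwell device images
#'
#' Bright-field: dark well disks on a bright background. Fluorescence
#' (green/magenta = two live-stain species): cell disks inside occupied
#' wells. Per-well cell number is Poisson-loaded with occupancy
#' P(n >= 1) = `occupancy`.
#'
#' @param n_rows,n_cols microwell grid shape.
#' @param pitch well pitch (px); images are (n_rows x pitch) tall.
#' @param well_radius,cell_radius radii in px.
#' @param occupancy fraction of wells containing at least one cell.
#' @param species_mix named probabilities over c("human", "mouse"); human
#'   cells appear in the green channel, mouse in magenta.
#' @param cell_intensity peak cell intensity (images are in [0, 1]).
#' @param noise_sd additive Gaussian pixel noise.
#' @param seed integer seed.
#' @return list: `brightfield`, `green`, `magenta` image matrices, `truth`
#'   (per well: center, n_green, n_magenta, occupied, multiplet label).
#' @export
simulate_device_images <- function(n_rows = 10, n_cols = 10, pitch = 30,
                                   well_radius = 10, cell_radius = 4,
                                   occupancy = 0.3,
                                   species_mix = c(human = 1),
                                   cell_intensity = 0.6, noise_sd = 0.005,
                                   seed = 1L) {
  if (2 * well_radius >= pitch) stop("overlapping wells: 2*well_radius >= pitch")
  with_seed(seed, {
    h <- n_rows * pitch; w <- n_cols * pitch
    bf <- matrix(0.8, h, w)
    green <- magenta <- matrix(0.02, h, w)
    wells <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
    wx <- (wells$col - 0.5) * pitch
    wy <- (wells$row - 0.5) * pitch
    nw <- nrow(wells)
    lambda <- -log(1 - occupancy)
    n_cells <- rpois(nw, lambda)
    ng <- nm <- integer(nw)
    for (i in seq_len(nw)) {
      bf <- add_disk(bf, wx[i], wy[i], well_radius, 0.2)
      if (n_cells[i] == 0) next
      for (j in seq_len(n_cells[i])) {
        sp <- sample(names(species_mix), 1, prob = species_mix)
        ang <- runif(1, 0, 2 * pi)
        rad <- runif(1, 0, well_radius - cell_radius - 1)
        cx <- wx[i] + rad * cos(ang); cy <- wy[i] + rad * sin(ang)
        val <- cell_intensity * runif(1, 0.8, 1.2)
        if (sp == "human") {
          green <- add_disk(green, cx, cy, cell_radius, val)
          ng[i] <- ng[i] + 1L
        } else {
          magenta <- add_disk(magenta, cx, cy, cell_radius, val)
          nm[i] <- nm[i] + 1L
        }
      }
    }
    if (noise_sd > 0) {
      bf <- pmin(pmax(bf + rnorm(length(bf), 0, noise_sd), 0), 1)
      green <- pmin(pmax(green + rnorm(length(green), 0, noise_sd), 0), 1)
      magenta <- pmin(pmax(magenta + rnorm(length(magenta), 0, noise_sd), 0), 1)
    }
    label <- ifelse(ng >= 1 & nm >= 1, "mixed_multiplet",
             ifelse(ng >= 2 | nm >= 2, "single_multiplet",
             ifelse(ng + nm == 1, "singlet", "empty")))
    list(
      brightfield = bf, green = green, magenta = magenta,
      truth = data.frame(well_id = seq_len(nw), x = wx, y = wy,
                         n_green = ng, n_magenta = nm,
                         occupied = n_cells > 0, label = label),
      params = list(pitch = pitch, well_radius = well_radius)
    )
  })
}

#' Simulate barcoded paired-end reads
#'
#' Builds read 1 per the bead oligo layout (UMI-interleaved S and Q
#' barcodes, 26 nt) with per-base substitution errors, and read 2 as a
#' gene-identifying fragment with an optional poly(A) suffix. The gene-tag
#' table gives the true gene (and species/chromosome, when `gene_info` is
#' supplied) per read id, standing in for an external aligner.
#'
#' @param cells data.frame with `cell_id`, `s`, `q` (designed barcodes).
#' @param counts genes x cells integer matrix of true molecules
#'   (dimnames required; columns match `cells$cell_id`).
#' @param gene_info optional data.frame `gene`, `species`, `chromosome`.
#' @param reads_per_molecule mean reads per molecule (>= 1).
#' @param error_rate per-base substitution probability on both reads.
#' @param polyA_rate fraction of fragments carrying a poly(A) tail.
#' @param fragment_length read-2 fragment length before the tail.
#' @param seed integer seed.
#' @return list: `r1`, `r2` (named sequence vectors), `tags` (read_id, gene,
#'   species, chromosome), `truth` (the input counts), `molecules`
#'   (per-molecule table).
#' @export
simulate_reads <- function(cells, counts, gene_info = NULL,
                           reads_per_molecule = 3, error_rate = 0.005,
                           polyA_rate = 0.5, fragment_length = 40,
                           seed = 1L) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(colnames(counts) %in% cells$cell_id))
  with_seed(seed, {
    genes <- rownames(counts)
    frags <- random_dna(length(genes), fragment_length)
    names(frags) <- genes
    nz <- which(counts > 0, arr.ind = TRUE)
    mol <- data.frame(
      gene = genes[rep(nz[, 1], counts[nz])],
      cell_id = colnames(counts)[rep(nz[, 2], counts[nz])]
    )
    n_mol <- nrow(mol)
    mol$umi <- random_dna(n_mol, 8)
    # UMIs within one (cell, gene) group are redrawn until pairwise Hamming
    # distance >= 2, so every emitted molecule is identifiable and the true
    # count is recoverable exactly at zero sequencing error
    grp <- paste(mol$cell_id, mol$gene)
    for (g in unique(grp[duplicated(grp)])) {
      idx <- which(grp == g)
      for (j in seq_along(idx)[-1]) {
        repeat {
          prev <- mol$umi[idx[seq_len(j - 1)]]
          if (all(hamming(rep(mol$umi[idx[j]], length(prev)), prev) >= 2)) break
          mol$umi[idx[j]] <- random_dna(1, 8)
        }
      }
    }
    mol$n_reads <- 1L + rpois(n_mol, max(reads_per_molecule - 1, 0))
    ridx <- rep(seq_len(n_mol), mol$n_reads)
    ci <- match(mol$cell_id[ridx], cells$cell_id)
    umi <- mol$umi[ridx]
    r1 <- paste0(substr(umi, 1, 2), cells$s[ci], substr(umi, 3, 4),
                 cells$q[ci], substr(umi, 5, 8), "TT")
    tail <- ifelse(runif(length(ridx)) < polyA_rate, strrep("A", 12), "")
    r2 <- paste0(frags[mol$gene[ridx]], tail)
    r1 <- mutate_seqs(r1, error_rate)
    r2 <- mutate_seqs(r2, error_rate)
    ids <- sprintf("read%07d", seq_along(ridx))
    names(r1) <- names(r2) <- ids
    tags <- data.frame(read_id = ids, gene = mol$gene[ridx])
    if (!is.null(gene_info)) {
      gi <- gene_info[match(tags$gene, gene_info$gene), ]
      tags$species <- gi$species
      tags$chromosome <- gi$chromosome
    }
    list(r1 = r1, r2 = r2, tags = tags, truth = counts,
         molecules = mol[, c("cell_id", "gene", "umi", "n_reads")])
  })
}

#' Simulate expression counts from a gamma factor model
#'
#' Counts are gamma-Poisson: cell weights theta (K factors, gamma, scaled by
#' a per-cell depth factor) times gene weights beta give the expected counts;
#' malignant cells additionally scale Chr7 genes by `chr7_factor` and Chr10
#' genes by `chr10_factor` (the GBM Chr7-gain / Chr10-loss aneuploidy).
#' The returned factor model is augmented (3K factors) so that
#' `theta %*% t(beta)` reproduces the expected counts exactly, including the
#' chromosome scaling — imputation from the emitted model is exact.
#'
#' With `species_mix`, cells are assigned a species and express only genes
#' annotated to their species (for barnyard-style simulations).
#'
#' @param n_cells,n_genes problem size (default 1000 x 1100).
#' @param malignant_frac fraction of malignant cells (default 0.4).
#' @param chr7_factor,chr10_factor aneuploid scaling (defaults 1.5, 0.5).
#' @param K latent factors (default 5).
#' @param mean_counts_per_gene expected counts per gene per cell.
#' @param theta_shape,beta_shape,depth_shape gamma shapes for cell weights,
#'   gene weights, and the per-cell depth factor.
#' @param n_chromosomes autosomes to spread genes over (round-robin).
#' @param species_mix optional named probabilities, e.g.
#'   c(human = .5, mouse = .5); disables the aneuploidy scenario.
#' @param seed integer seed.
#' @return list: `counts` (genes x cells), `gene_info` (gene, species,
#'   chromosome), `theta` (cells x 3K), `beta` (genes x 3K), `truth`
#'   (cell_id, malignant, species), `expected` (cells x genes rate matrix).
#' @export
simulate_expression <- function(n_cells = 1000, n_genes = 1100,
                                malignant_frac = 0.4, chr7_factor = 1.5,
                                chr10_factor = 0.5, K = 5,
                                mean_counts_per_gene = 20,
                                theta_shape = 4, beta_shape = 4,
                                depth_shape = 16, n_chromosomes = 22,
                                species_mix = NULL, seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("gene%05d", seq_len(n_genes))
    chrom <- paste0("chr", rep_len(seq_len(n_chromosomes), n_genes))
    cell_id <- sprintf("cell%05d", seq_len(n_cells))
    if (is.null(species_mix)) {
      species_cell <- rep("human", n_cells)
      species_gene <- rep("human", n_genes)
      malignant <- runif(n_cells) < malignant_frac
    } else {
      species_cell <- sample(names(species_mix), n_cells, replace = TRUE,
                             prob = species_mix)
      species_gene <- rep_len(names(species_mix), n_genes)
      malignant <- rep(FALSE, n_cells)
    }
    theta0 <- matrix(rgamma(n_cells * K, theta_shape, theta_shape), n_cells) *
      rgamma(n_cells, depth_shape, depth_shape)
    beta0 <- matrix(rgamma(n_genes * K, beta_shape, beta_shape), n_genes) *
      (mean_counts_per_gene / K)
    s7 <- ifelse(malignant, chr7_factor, 1)
    s10 <- ifelse(malignant, chr10_factor, 1)
    in7 <- chrom == "chr7"
    in10 <- chrom == "chr10"
    theta <- cbind(theta0, theta0 * s7, theta0 * s10)
    beta <- cbind(beta0 * !(in7 | in10), beta0 * in7, beta0 * in10)
    expected <- theta %*% t(beta)
    if (!is.null(species_mix)) {
      expected <- expected *
        outer(species_cell, species_gene, `==`)
    }
    counts <- matrix(rpois(length(expected), t(expected)), n_genes,
                     dimnames = list(genes, cell_id))
    rownames(theta) <- cell_id
    rownames(beta) <- genes
    list(
      counts = counts,
      gene_info = data.frame(gene = genes, species = species_gene,
                             chromosome = chrom),
      theta = theta, beta = beta,
      truth = data.frame(cell_id = cell_id, malignant = malignant,
                         species = species_cell),
      expected = expected
    )
  })
}

#' Write a FASTQ file
#'
#' @param seqs named character vector of sequences (names = read ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  out <- character(4 * length(seqs))
  out[seq(1, length(out), 4)] <- paste0("@", ids)
  out[seq(2, length(out), 4)] <- seqs
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- strrep("I", nchar(seqs))
  writeLines(out, path)
  invisible(path)
}
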