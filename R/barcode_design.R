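# Design of the two 96-member 8-nt cell barcode pools, the full-length
# capture-oligo layout, the 8-bit binary code tables, and the two-color
# hybridization probe pools.

BASES <- c("A", "C", "G", "T")

#' Full-length capture-oligo template
#'
#' Layout of the bead oligo: a fixed 32-nt PCR anchor, then the 8-nt UMI
#' dispersed as NN / NN / NNNN spacers around the two 8-nt barcode slots
#' (S then Q), then a 30-nt oligo(dT) tail for mRNA capture. Total length 86.
#'
#' @return list with elements `anchor`, `umi_lengths` (c(2, 2, 4)),
#'   `tail_length` (30) and `full_length` (86).
#' @export
oligo_template <- function() {
  list(
    anchor = "TTTTTTTAAGCAGTGGTATCAACGCAGAGTAC",
    umi_lengths = c(2L, 2L, 4L),
    barcode_length = 8L,
    tail_length = 30L,
    full_length = 32L + 2L + 8L + 2L + 8L + 4L + 30L
  )
}

# Internal oligo assembly; allow_n permits N placeholders (used when scoring
# candidate barcodes, where the UMI is unknown).
assemble_oligo <- function(s, q, umi, template, allow_n = FALSE) {
  ok <- if (allow_n) "[ACGTN]+" else "[ACGT]+"
  for (piece in c(s = s, q = q, umi = umi)) {
    if (!grepl(paste0("^", ok, "$"), piece)) {
      stop("oligo segment contains invalid characters: ", piece)
    }
  }
  if (nchar(s) != template$barcode_length || nchar(q) != template$barcode_length) {
    stop("barcode segments must be ", template$barcode_length, " nt")
  }
  if (nchar(umi) != sum(template$umi_lengths)) {
    stop("UMI must be ", sum(template$umi_lengths), " nt")
  }
  paste0(
    template$anchor,
    substr(umi, 1, 2), s,
    substr(umi, 3, 4), q,
    substr(umi, 5, 8),
    strrep("T", template$tail_length)
  )
}

#' Build a full-length capture oligo
#'
#' Concatenates `anchor + umi[1:2] + s + umi[3:4] + q + umi[5:8]` + 30 T's.
#'
#' @param s,q 8-nt barcode sequences (S and Q slots).
#' @param umi 8-nt random sequence (A/C/G/T only).
#' @param template layout from [oligo_template()].
#' @return single 86-nt sequence string.
#' @export
#' @examples
#' nchar(build_full_length_oligo("ACGTCAGT", "TGCATGCA", "TTGAAACG"))
build_full_length_oligo <- function(s, q, umi, template = oligo_template()) {
  out <- assemble_oligo(s, q, umi, template, allow_n = FALSE)
  stopifnot(nchar(out) == template$full_length)
  out
}

#' Generate filtered 8-nt barcode candidates
#'
#' Draws 8-mers in a seeded random order from the exhaustive pool passing the
#' composition filters, greedily keeping each candidate that stays at
#' Levenshtein distance >= `min_lev` from everything already kept. Filters:
#' homopolymer runs <= `max_homopolymer`, GC content within `gc_range`
#' percent, and no sequence equal to its own reverse complement.
#'
#' @param n number of candidates to return.
#' @param seed integer seed fixing the scan order (and hence the result).
#' @param min_lev minimum pairwise Levenshtein distance (default 3).
#' @param max_homopolymer longest allowed single-base run (default 2).
#' @param gc_range allowed GC percentage window (default c(40, 60)).
#' @param max_iter cap on the number of pool sequences examined before
#'   declaring the request infeasible (default: the whole pool).
#' @return data.frame with columns `sequence`, `gc_percent`,
#'   `max_homopolymer`.
#' @export
generate_candidates <- function(n, seed = 1L, min_lev = 3L,
                                max_homopolymer = 2L, gc_range = c(40, 60),
                                max_iter = NULL) {
  stopifnot(n >= 1)
  grid <- expand.grid(rep(list(1:4), 8), KEEP.OUT.ATTRS = FALSE)
  seqs <- do.call(paste0, lapply(grid, function(col) BASES[col]))
  keep <- max_homopolymer(seqs) <= max_homopolymer
  gcp <- gc_percent(seqs)
  keep <- keep & gcp >= gc_range[1] & gcp <= gc_range[2]
  keep <- keep & seqs != revcomp(seqs)
  pool <- seqs[keep]
  if (is.null(max_iter)) max_iter <- length(pool)
  pool <- with_seed(seed, sample(pool))
  accepted <- character(0)
  examined <- 0L
  for (s in pool) {
    examined <- examined + 1L
    if (examined > max_iter) break
    if (length(accepted) == 0 || cpp_lev_clear(s, accepted, as.integer(min_lev))) {
      accepted <- c(accepted, s)
      if (length(accepted) == n) break
    }
  }
  if (length(accepted) < n) {
    stop(sprintf(
      "cannot reach %d candidates under the constraints: %d found after examining %d of %d pool sequences (budget max_iter = %d)",
      n, length(accepted), min(examined, max_iter), length(pool), max_iter
    ))
  }
  data.frame(
    sequence = accepted,
    gc_percent = gc_percent(accepted),
    max_homopolymer = max_homopolymer(accepted),
    stringsAsFactors = FALSE
  )
}

#' Self-complementarity score of a candidate barcode
#'
#' The score is the weighted length of the longest contiguous stretch of
#' Watson-Crick pairs formed when a full-length oligo containing the barcode
#' is aligned antiparallel against itself at any offset, maximized over all
#' full-length oligos containing the barcode (the barcode in the S slot with
#' every partner in the Q slot, and vice versa; UMI positions are N and pair
#' with any base). A-T pairs weigh 2/3 and C-G pairs 1, reflecting their
#' relative binding affinity; N pairs weigh 2/3.
#'
#' @param barcode 8-nt sequence to score.
#' @param partner_set character vector of partner barcodes (non-empty).
#' @param template layout from [oligo_template()].
#' @return numeric score (dimensionless weighted stretch length).
#' @export
self_complementarity_score <- function(barcode, partner_set,
                                       template = oligo_template()) {
  if (length(partner_set) == 0) stop("partner_set must be non-empty")
  umi <- strrep("N", sum(template$umi_lengths))
  oligos <- c(
    vapply(partner_set, function(p) assemble_oligo(barcode, p, umi, template, TRUE),
           character(1)),
    vapply(partner_set, function(p) assemble_oligo(p, barcode, umi, template, TRUE),
           character(1))
  )
  max(cpp_selfdimer_scores(oligos))
}

# Score every candidate against the whole candidate pool in one pass over the
# n x n ordered-pair oligo matrix (candidate score = max over oligos in which
# it occupies either slot).
score_candidate_pool <- function(sequences, template = oligo_template()) {
  n <- length(sequences)
  umi <- strrep("N", sum(template$umi_lengths))
  pre <- paste0(template$anchor, substr(umi, 1, 2))
  mid <- substr(umi, 3, 4)
  post <- paste0(substr(umi, 5, 8), strrep("T", template$tail_length))
  s_part <- paste0(pre, sequences, mid)       # length n
  oligos <- as.vector(outer(s_part, paste0(sequences, post), paste0))
  sc <- matrix(cpp_selfdimer_scores(oligos), nrow = n)  # [s_idx, q_idx]
  pmax(apply(sc, 1, max), apply(sc, 2, max))
}

#' Retain the half of the candidates with the lowest scores
#'
#' Keeps exactly `floor(n/2)` candidates with the smallest
#' self-complementarity scores; ties at the cutoff are broken
#' lexicographically by sequence.
#'
#' @param candidates data.frame with columns `sequence` and `selfcomp_score`.
#' @return the retained subset, ordered by (score, sequence).
#' @export
select_barcodes <- function(candidates) {
  stopifnot(nrow(candidates) >= 2,
            all(c("sequence", "selfcomp_score") %in% names(candidates)))
  ord <- order(candidates$selfcomp_score, candidates$sequence)
  candidates[ord[seq_len(nrow(candidates) %/% 2)], , drop = FALSE]
}

#' Assign 8-bit binary codes to a barcode set
#'
#' Draws an injective seeded-random mapping from the 96 sequences onto the
#' 254 usable 8-bit codes; 00000000 (indistinguishable from hybridization
#' failure) and 11111111 (indistinguishable from a stuck-bright artifact)
#' are excluded.
#'
#' @param sequences character vector of distinct barcode sequences.
#' @param seed integer seed.
#' @return named character vector mapping sequence -> 8-character 0/1 code.
#' @export
assign_binary_codes <- function(sequences, seed = 1L) {
  if (anyDuplicated(sequences)) stop("duplicate sequences in barcode set")
  usable <- vapply(1:254, function(i) {
    paste(rev(as.integer(intToBits(i))[1:8]), collapse = "")
  }, character(1))
  if (length(sequences) > length(usable)) {
    stop("more sequences than usable 8-bit codes (254)")
  }
  codes <- with_seed(seed, sample(usable, length(sequences)))
  setNames(codes, sequences)
}

#' Build the per-cycle hybridization probe pools
#'
#' For each decoding cycle A..H, the pool contains the reverse complements of
#' all S barcodes (labeled Cy5) and all Q barcodes (labeled Cy3) whose binary
#' code has bit 1 at that cycle.
#'
#' @param s_set,q_set barcode sets as returned by [design_barcode_sets()]
#'   (lists with `role`, `sequences`, `code_map`).
#' @return data.frame with columns `cycle` (A..H), `channel` (Cy5/Cy3),
#'   `role`, `barcode`, `probe`.
#' @export
build_probe_pools <- function(s_set, q_set) {
  one_role <- function(set, channel) {
    if (is.null(set$code_map)) stop("barcode set has no code map")
    codes <- set$code_map[set$sequences]
    out <- list()
    for (k in 1:8) {
      hot <- substr(codes, k, k) == "1"
      if (!any(hot)) next
      out[[k]] <- data.frame(
        cycle = LETTERS[k], channel = channel, role = set$role,
        barcode = set$sequences[hot], probe = revcomp(set$sequences[hot]),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  }
  rbind(one_role(s_set, "Cy5"), one_role(q_set, "Cy3"))
}

#' Design the S and Q barcode sets end to end
#'
#' Runs the whole design procedure: generate `4 * n_per_role` filtered
#' candidates, score their self-complementarity combinatorially over the full
#' candidate pool, retain the bottom-scoring half, split the retained
#' sequences alternately (by score rank) into the S and Q roles, and assign
#' each role a seeded injective 8-bit binary code table.
#'
#' @param n_per_role barcodes per role (default 96).
#' @param seed integer seed controlling candidate order and code assignment.
#' @param template layout from [oligo_template()].
#' @return object of class `barcode_design`: list with `s_set`, `q_set`
#'   (each: `role`, `sequences`, `code_map`), `candidates` (scored
#'   data.frame), and `template`.
#' @export
design_barcode_sets <- function(n_per_role = 96L, seed = 1L,
                                template = oligo_template()) {
  cand <- generate_candidates(4L * n_per_role, seed = seed)
  cand$selfcomp_score <- score_candidate_pool(cand$sequence, template)
  sel <- select_barcodes(cand)
  s_idx <- seq(1, nrow(sel), by = 2)
  q_idx <- seq(2, nrow(sel), by = 2)
  s_set <- list(role = "S", sequences = sel$sequence[s_idx],
                code_map = assign_binary_codes(sel$sequence[s_idx], seed = seed))
  q_set <- list(role = "Q", sequences = sel$sequence[q_idx],
                code_map = assign_binary_codes(sel$sequence[q_idx], seed = seed + 1L))
  structure(
    list(s_set = s_set, q_set = q_set, candidates = cand, template = template),
    class = "barcode_design"
  )
}

#' @export
print.barcode_design <- function(x, ...) {
  cat("barcode_design:",
      length(x$s_set$sequences), "S +",
      length(x$q_set$sequences), "Q barcodes;",
      nrow(x$candidates), "scored candidates\n")
  invisible(x)
}

#' Write design outputs to a directory
#'
#' Writes per-role whitelists (one sequence per line), a combined code table
#' CSV (`sequence,role,code`) and the probe pools as FASTA
#' (id = cycle_channel_index).
#'
#' @param design a `barcode_design` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_barcode_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(design$s_set$sequences, file.path(dir, "whitelist_S.txt"))
  writeLines(design$q_set$sequences, file.path(dir, "whitelist_Q.txt"))
  tab <- rbind(
    data.frame(sequence = design$s_set$sequences, role = "S",
               code = unname(design$s_set$code_map[design$s_set$sequences])),
    data.frame(sequence = design$q_set$sequences, role = "Q",
               code = unname(design$q_set$code_map[design$q_set$sequences]))
  )
  utils::write.csv(tab, file.path(dir, "code_table.csv"), row.names = FALSE,
                   quote = FALSE)
  pools <- build_probe_pools(design$s_set, design$q_set)
  probes <- Biostrings::DNAStringSet(pools$probe)
  names(probes) <- sprintf("%s_%s_%03d", pools$cycle, pools$channel,
                           seq_len(nrow(pools)))
  Biostrings::writeXStringSet(probes, file.path(dir, "probe_pools.fasta"))
  invisible(dir)
}

#' Read a code table CSV back into S and Q code maps
#'
#' @param path CSV written by [write_barcode_design()].
#' @return list with `s_codes` and `q_codes`, each a named character vector
#'   mapping sequence -> 8-bit code.
#' @export
read_code_table <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  list(
    s_codes = setNames(tab$code[tab$role == "S"], tab$sequence[tab$role == "S"]),
    q_codes = setNames(tab$code[tab$role == "Q"], tab$sequence[tab$role == "Q"])
  )
}
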