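# Calling each bead's two 8-bit binary codes from its 8-cycle x 2-channel
# fluorescence intensities, and mapping codes to barcode sequences. Two
# algorithms: a population-level threshold per cycle ("cycle-by-cycle") and a
# per-bead sorted fold-change split ("bead-by-bead").

CYCLES <- LETTERS[1:8]

ch_cols <- function(channel) paste0("ch", channel, "_cycle", CYCLES)

# n x 8 intensity matrix for one channel ("5" = Cy5/S, "3" = Cy3/Q).
intensity_matrix <- function(table, channel) {
  cols <- ch_cols(channel)
  if (!all(cols %in% names(table))) {
    stop("intensity table is missing columns: ",
         paste(setdiff(cols, names(table)), collapse = ", "))
  }
  m <- as.matrix(table[, cols])
  if (any(m < 0)) stop("negative intensities in table")
  m
}

#' Map an 8-bit binary code to its barcode sequence
#'
#' Exact lookup with no error tolerance; codes absent from the table
#' (including the excluded all-zero and all-one codes) are unmappable.
#'
#' @param code 8-character 0/1 string (vectorized).
#' @param code_map named character vector sequence -> code.
#' @return barcode sequence, or `NA_character_` if unmappable.
#' @export
map_code_to_barcode <- function(code, code_map) {
  rev_map <- setNames(names(code_map), unname(code_map))
  unname(rev_map[code])
}

# Decode one channel of one bead by sorted relative fold change, with retry
# over split points in descending fold-change order until a mappable code is
# found. Returns list(code, barcode).
bead_split_call <- function(vals, rev_map, floor_eps = 1) {
  x <- pmax(vals, floor_eps)
  ord <- order(x)
  y <- x[ord]
  f <- (y[2:8] - y[1:7]) / y[1:7]
  tries <- order(f, decreasing = TRUE)  # ties: smallest split index first
  first_code <- NULL
  for (n_split in tries) {
    bits <- integer(8)
    bits[ord[seq_len(n_split)]] <- 0L
    bits[ord[(n_split + 1):8]] <- 1L
    code <- paste(bits, collapse = "")
    if (is.null(first_code)) first_code <- code
    bc <- rev_map[code]
    if (!is.na(bc)) return(list(code = code, barcode = unname(bc)))
  }
  list(code = first_code, barcode = NA_character_)
}

#' Decode beads by per-bead sorted fold change
#'
#' For each bead and channel, the eight intensities are sorted ascending,
#' relative fold changes between neighbors are computed, and the largest fold
#' change splits the values into 0s (below) and 1s (above). If the resulting
#' code is not in the code table, the next largest fold change is tried,
#' until a mappable code is found or the split points are exhausted.
#' Intensities are floored at `floor_eps` before fold-change computation.
#'
#' @param table bead intensity table: data.frame with `bead_id`, `x`, `y` and
#'   columns `ch5_cycleA..H`, `ch3_cycleA..H`.
#' @param s_codes,q_codes named code maps (sequence -> 8-bit code) for the
#'   Cy5/S and Cy3/Q channels.
#' @param floor_eps positive floor applied to intensities (default 1 a.u.).
#' @return data.frame `bead_id`, `s_code`, `q_code`, `s_barcode`,
#'   `q_barcode`, `status` ("decoded" iff both channels mapped).
#' @export
decode_bead_by_bead <- function(table, s_codes, q_codes, floor_eps = 1) {
  m5 <- intensity_matrix(table, "5")
  m3 <- intensity_matrix(table, "3")
  rev_s <- setNames(names(s_codes), unname(s_codes))
  rev_q <- setNames(names(q_codes), unname(q_codes))
  n <- nrow(table)
  s_code <- q_code <- s_bc <- q_bc <- character(n)
  for (i in seq_len(n)) {
    cs <- bead_split_call(m5[i, ], rev_s, floor_eps)
    cq <- bead_split_call(m3[i, ], rev_q, floor_eps)
    s_code[i] <- cs$code; s_bc[i] <- cs$barcode
    q_code[i] <- cq$code; q_bc[i] <- cq$barcode
  }
  data.frame(
    bead_id = table$bead_id, s_code = s_code, q_code = q_code,
    s_barcode = s_bc, q_barcode = q_bc,
    status = ifelse(!is.na(s_bc) & !is.na(q_bc), "decoded", "unmappable"),
    stringsAsFactors = FALSE
  )
}

# Population threshold for one cycle/channel: log intensities, 50-bin
# histogram, B1/B2 = most-populated bins below/above the median, threshold =
# center of the least-populated bin strictly between them (ties: middle tied
# bin). Returns NA when the histogram is degenerate.
cycle_threshold <- function(v, bins = 50) {
  if (diff(range(v)) == 0) return(NA_real_)
  breaks <- seq(min(v), max(v), length.out = bins + 1)
  counts <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), bins),
    nbins = bins
  )
  centers <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  M <- median(v)
  m_bin <- pmin(pmax(findInterval(M, breaks, rightmost.closed = TRUE), 1L), bins)
  below <- which(seq_len(bins) <= m_bin & counts > 0)
  above <- which(seq_len(bins) > m_bin & counts > 0)
  if (length(above) == 0 && m_bin > 1) {
    # median sits in the topmost populated bin; split just below it
    m_bin <- m_bin - 1L
    below <- which(seq_len(bins) <= m_bin & counts > 0)
    above <- which(seq_len(bins) > m_bin & counts > 0)
  }
  if (length(below) == 0 || length(above) == 0) return(NA_real_)
  b1 <- below[which.max(counts[below])]
  b2 <- above[which.max(counts[above])]
  between <- seq_len(bins)
  between <- between[between > b1 & between < b2]
  if (length(between) == 0) {
    message("cycle threshold: no bins between the two modes; ",
            "falling back to their midpoint")
    return((centers[b1] + centers[b2]) / 2)
  }
  mins <- between[counts[between] == min(counts[between])]
  b3 <- mins[ceiling(length(mins) / 2)]
  centers[b3]
}

#' Decode beads by population thresholds per cycle
#'
#' For each cycle and channel, all bead intensities are log-transformed and a
#' 50-bin histogram is formed; the threshold is the center of the
#' least-populated bin lying between the most-populated bins below and above
#' the median. Bits are 1 where the log intensity exceeds the threshold.
#' There is no retry for unmappable codes.
#'
#' @inheritParams decode_bead_by_bead
#' @param bins histogram bin count (default 50).
#' @return same shape as [decode_bead_by_bead()].
#' @export
decode_cycle_by_cycle <- function(table, s_codes, q_codes, bins = 50) {
  if (nrow(table) < 100) {
    stop("cycle-by-cycle decoding is a population method; >= 100 beads required")
  }
  call_channel <- function(m, code_map) {
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop("non-positive intensity for bead ",
           table$bead_id[bad[1, 1]], "; log transform undefined")
    }
    lm <- log(m)
    bits <- matrix(NA_integer_, nrow(m), 8)
    for (k in 1:8) {
      thr <- cycle_threshold(lm[, k], bins)
      if (is.na(thr)) {
        message("cycle ", CYCLES[k], ": degenerate intensity histogram; ",
                "bit calls undefined")
        next
      }
      bits[, k] <- as.integer(lm[, k] > thr)
    }
    codes <- apply(bits, 1, function(b) {
      if (anyNA(b)) NA_character_ else paste(b, collapse = "")
    })
    list(codes = codes, barcodes = map_code_to_barcode(codes, code_map))
  }
  s <- call_channel(intensity_matrix(table, "5"), s_codes)
  q <- call_channel(intensity_matrix(table, "3"), q_codes)
  data.frame(
    bead_id = table$bead_id,
    s_code = s$codes, q_code = q$codes,
    s_barcode = s$barcodes, q_barcode = q$barcodes,
    status = ifelse(!is.na(s$barcodes) & !is.na(q$barcodes),
                    "decoded", "unmappable"),
    stringsAsFactors = FALSE
  )
}

#' Tally decoding outcomes against the sequenced barcode set
#'
#' Outcome 1: the bead was assigned an unmappable binary code. Outcome 2: the
#' code maps to a barcode that is absent from the sequencing data. The
#' remainder are linked (correct links plus the rare wrong-profile links).
#' Fractions are over all beads in `results` (beads paired with cells).
#'
#' @param results output of a decoder.
#' @param sequenced_barcodes character vector of 16-nt (S+Q) barcodes
#'   observed in sequencing.
#' @return list with `counts` and `fractions` (named: `outcome1`, `outcome2`,
#'   `linked`); fractions sum to 1.
#' @export
classify_outcomes <- function(results, sequenced_barcodes) {
  if (length(sequenced_barcodes) == 0) stop("empty sequenced barcode set")
  full <- paste0(results$s_barcode, results$q_barcode)
  unmappable <- results$status != "decoded"
  absent <- !unmappable & !(full %in% sequenced_barcodes)
  counts <- c(
    outcome1 = sum(unmappable),
    outcome2 = sum(absent),
    linked = sum(!unmappable & !absent)
  )
  list(counts = counts, fractions = counts / nrow(results))
}

#' Read / write bead intensity tables
#'
#' CSV with columns `bead_id`, `x`, `y`, `ch5_cycleA..H`, `ch3_cycleA..H`.
#'
#' @param table bead intensity data.frame.
#' @param path CSV file path.
#' @return `read_bead_intensities` returns the data.frame;
#'   `write_bead_intensities` returns `path` invisibly.
#' @export
write_bead_intensities <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bead_intensities
#' @export
read_bead_intensities <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
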