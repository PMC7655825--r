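# Independent oracles, deliberately written without reference to the package
# implementations they check.

# Brute-force self-dimer score: align the sequence against itself antiparallel
# at every offset and scan runs of complementary pairs character by character.
oracle_selfdimer <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  w <- function(a, b) {
    if (a == "N" || b == "N") return(2 / 3)
    if ((a == "A" && b == "T") || (a == "T" && b == "A")) return(2 / 3)
    if ((a == "C" && b == "G") || (a == "G" && b == "C")) return(1)
    0
  }
  best <- 0
  for (cc in 0:(2 * L - 2)) {
    run <- 0
    for (i in max(0, cc - L + 1):min(L - 1, cc)) {
      wi <- w(ch[i + 1], ch[cc - i + 1])
      if (wi > 0) {
        run <- run + wi
        best <- max(best, run)
      } else {
        run <- 0
      }
    }
  }
  best
}

# Brute-force bead-by-bead oracle: evaluate all 7 split points of the sorted
# intensities, and among split points whose induced code is mappable pick the
# one with the largest relative gap. Returns the barcode or NA.
oracle_split_decode <- function(vals, code_map, floor_eps = 1) {
  x <- pmax(vals, floor_eps)
  ord <- order(x)
  y <- x[ord]
  f <- (y[2:8] - y[1:7]) / y[1:7]
  codes <- vapply(1:7, function(n) {
    bits <- integer(8)
    bits[ord[(n + 1):8]] <- 1L
    paste(bits, collapse = "")
  }, character(1))
  mappable <- codes %in% unname(code_map)
  if (!any(mappable)) return(NA_character_)
  best <- which(mappable)[which.max(f[mappable])]
  names(code_map)[match(codes[best], unname(code_map))]
}

# Adjusted Rand index between two labelings.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Paint a filled disk into an image matrix (0-based center coordinates).
paint_disk <- function(img, x, y, r, value) {
  for (row in seq_len(nrow(img))) {
    for (col in seq_len(ncol(img))) {
      if ((col - 1 - x)^2 + (row - 1 - y)^2 <= r^2) img[row, col] <- value
    }
  }
  img
}

# Paint a filled axis-aligned ellipse (semi-axes a horizontal, b vertical).
paint_ellipse <- function(img, x, y, a, b, value) {
  for (row in seq_len(nrow(img))) {
    for (col in seq_len(ncol(img))) {
      if (((col - 1 - x) / a)^2 + ((row - 1 - y) / b)^2 <= 1) {
        img[row, col] <- value
      }
    }
  }
  img
}
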