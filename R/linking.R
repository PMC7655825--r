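# Registration of decoding-round images onto live-imaging coordinates,
# cell-bead pairing, and the join from decoded barcodes to sequenced
# expression profiles.

#' Similarity transform from two anchor point pairs
#'
#' Two point correspondences (the upper-left and bottom-right microwells)
#' determine a translation + isotropic scale + rotation mapping the source
#' anchors exactly onto the destination anchors.
#'
#' @param anchor_src,anchor_dst 2 x 2 numeric matrices; rows = the two anchor
#'   points, columns = (x, y).
#' @return object of class `similarity_transform`.
#' @export
register_images <- function(anchor_src, anchor_dst) {
  anchor_src <- as.matrix(anchor_src)
  anchor_dst <- as.matrix(anchor_dst)
  stopifnot(all(dim(anchor_src) == c(2, 2)), all(dim(anchor_dst) == c(2, 2)))
  zs <- complex(real = anchor_src[, 1], imaginary = anchor_src[, 2])
  zd <- complex(real = anchor_dst[, 1], imaginary = anchor_dst[, 2])
  if (zs[1] == zs[2]) stop("coincident source anchors")
  a <- (zd[2] - zd[1]) / (zs[2] - zs[1])
  b <- zd[1] - a * zs[1]
  structure(
    list(a = a, b = b, scale = Mod(a), rotation = Arg(a),
         translation = c(Re(b), Im(b))),
    class = "similarity_transform"
  )
}

#' Apply a similarity transform to points
#'
#' @param transform a `similarity_transform`.
#' @param xy data.frame or matrix with columns (x, y).
#' @return data.frame with transformed `x`, `y`.
#' @export
apply_transform <- function(transform, xy) {
  xy <- as.data.frame(xy)
  z <- complex(real = xy[[1]], imaginary = xy[[2]]) * transform$a + transform$b
  data.frame(x = Re(z), y = Im(z))
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity_transform: scale %.4f, rotation %.4f rad, translation (%.2f, %.2f)\n",
              x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

#' Pair imaged cells with mapped beads
#'
#' Each cell pairs with its nearest bead when the distance is within
#' `radius`. A bead may claim at most one cell: when two cells share a
#' nearest bead, the closest cell wins (ties broken by cell id) and the
#' loser stays unpaired.
#'
#' @param cells data.frame with `cell_id`, `x`, `y`.
#' @param beads data.frame with `bead_id`, `x`, `y` (already mapped into the
#'   live-imaging frame).
#' @param radius pairing radius in px (typically one microwell radius).
#' @return data.frame `cell_id`, `bead_id` (NA when unpaired), `distance`.
#' @export
assign_cells_to_beads <- function(cells, beads, radius) {
  stopifnot(radius > 0)
  d2 <- outer(cells$x, beads$x, `-`)^2 + outer(cells$y, beads$y, `-`)^2
  nearest <- max.col(-d2, ties.method = "first")
  dist <- sqrt(d2[cbind(seq_len(nrow(cells)), nearest)])
  bead_id <- rep(NA, nrow(cells))
  ord <- order(dist, cells$cell_id)
  taken <- rep(FALSE, nrow(beads))
  for (i in ord) {
    if (dist[i] <= radius && !taken[nearest[i]]) {
      taken[nearest[i]] <- TRUE
      bead_id[i] <- beads$bead_id[nearest[i]]
    }
  }
  data.frame(cell_id = cells$cell_id, bead_id = bead_id,
             distance = ifelse(is.na(bead_id), NA_real_, dist))
}

#' Join paired beads to sequenced expression profiles
#'
#' A cell links to a profile iff its bead decoded to a barcode that occurs
#' exactly once among the sequenced profiles. Beads sharing a decoded
#' barcode within one region are ambiguous and both are excluded.
#'
#' @param pairs output of [assign_cells_to_beads()].
#' @param decoded decoder output (see [decode_bead_by_bead()]).
#' @param sequenced_barcodes character vector of 16-nt barcodes with
#'   sequenced profiles (duplicates mean ambiguous profiles).
#' @return link table: data.frame `cell_id`, `bead_id`, `barcode`,
#'   `profile_id` (NA unless linked), `outcome` in {"linked", "outcome1",
#'   "outcome2", "ambiguous", "unpaired"}.
#' @export
link_profiles <- function(pairs, decoded, sequenced_barcodes) {
  if (length(sequenced_barcodes) == 0) stop("empty sequenced barcode set")
  m <- match(pairs$bead_id, decoded$bead_id)
  barcode <- ifelse(decoded$status[m] == "decoded",
                    paste0(decoded$s_barcode[m], decoded$q_barcode[m]),
                    NA_character_)
  outcome <- rep("unpaired", nrow(pairs))
  has_bead <- !is.na(pairs$bead_id)
  outcome[has_bead & is.na(barcode)] <- "outcome1"
  dup <- barcode %in% barcode[duplicated(barcode)] & !is.na(barcode)
  if (any(dup)) {
    message(sum(dup), " beads share a decoded barcode; excluded as ambiguous")
  }
  outcome[has_bead & dup] <- "ambiguous"
  seq_tab <- table(sequenced_barcodes)
  candid <- has_bead & !dup & !is.na(barcode)
  n_prof <- as.integer(seq_tab[barcode])
  n_prof[is.na(n_prof)] <- 0L
  outcome[candid & n_prof == 0] <- "outcome2"
  outcome[candid & n_prof > 1] <- "ambiguous"
  outcome[candid & n_prof == 1] <- "linked"
  data.frame(
    cell_id = pairs$cell_id, bead_id = pairs$bead_id, barcode = barcode,
    profile_id = ifelse(outcome == "linked", barcode, NA_character_),
    outcome = outcome
  )
}

#' Class-balanced accuracy
#'
#' Unweighted mean of per-class agreement rates between a reference labeling
#' and a test labeling, insensitive to class size imbalance. Classes with no
#' members are excluded with a warning.
#'
#' @param reference,test character vectors of per-cell class labels.
#' @return percentage in [0, 100].
#' @export
#' @examples
#' class_balanced_accuracy(c(rep("h", 250), rep("m", 250)),
#'                         c(rep("h", 247), rep("m", 253)))
class_balanced_accuracy <- function(reference, test) {
  stopifnot(length(reference) == length(test))
  classes <- unique(reference)
  rates <- vapply(classes, function(cl) {
    sel <- reference == cl
    if (!any(sel)) return(NA_real_)
    mean(test[sel] == cl)
  }, numeric(1))
  if (anyNA(rates)) {
    warning("classes with zero members excluded: ",
            paste(classes[is.na(rates)], collapse = ", "))
  }
  100 * mean(rates, na.rm = TRUE)
}

#' Multiplet detection sensitivity and specificity
#'
#' Sequencing-based mixed-species calls are the reference; imaging-based
#' multiplet calls are the test. Sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP).
#'
#' @param image_multiplet,seq_multiplet logical vectors per linked cell.
#' @return list with `sensitivity` and `specificity` (percent; NA with a
#'   warning when a reference class is empty) and the 2 x 2 `table`.
#' @export
multiplet_metrics <- function(image_multiplet, seq_multiplet) {
  stopifnot(length(image_multiplet) == length(seq_multiplet))
  tp <- sum(image_multiplet & seq_multiplet)
  fn <- sum(!image_multiplet & seq_multiplet)
  tn <- sum(!image_multiplet & !seq_multiplet)
  fp <- sum(image_multiplet & !seq_multiplet)
  sens <- if (tp + fn == 0) {
    warning("no reference multiplets; sensitivity undefined")
    NA_real_
  } else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no reference singlets; specificity undefined")
    NA_real_
  } else 100 * tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       table = matrix(c(tp, fp, fn, tn), 2, 2,
                      dimnames = list(image = c("multiplet", "singlet"),
                                      sequencing = c("multiplet", "singlet"))))
}
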