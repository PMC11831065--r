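#' Electrode montages
#'
#' A montage is a tibble with one row per channel and columns `label`
#' (unique channel identifier), `x`, `y` (schematic 2-D head-plane
#' coordinates, nose up, arbitrary units in \[-1, 1\]) and `region`
#' (one of the eight scalp region tags used for topographic summaries).
#'
#' @param label Character vector of unique channel labels.
#' @param x,y Numeric head-plane coordinates, same length as `label`.
#' @param region Character region tag per channel; must be one of
#'   [montage_regions()].
#' @return A tibble with class `"montage"` prepended.
#' @examples
#' montage(c("A", "B"), x = c(-0.5, 0.5), y = c(0, 0),
#'         region = c("frontal-left", "frontal-right"))
#' @export
montage <- function(label, x, y, region) {
  if (length(label) < 2) abort("A montage needs at least 2 channels.")
  if (anyDuplicated(label)) abort("Montage labels must be unique.")
  if (length(x) != length(label) || length(y) != length(label) ||
      length(region) != length(label)) {
    abort("`x`, `y` and `region` must have one entry per label.")
  }
  bad <- setdiff(unique(region), montage_regions())
  if (length(bad)) {
    abort(paste0("Unknown region tag(s): ", paste(bad, collapse = ", ")))
  }
  out <- tibble::tibble(label = as.character(label),
                        x = as.numeric(x), y = as.numeric(y),
                        region = as.character(region))
  class(out) <- c("montage", class(out))
  out
}

#' @rdname montage
#' @export
montage_regions <- function() {
  c("frontal-left", "frontal-right", "midline", "central",
    "parietal", "occipital", "temporal-left", "temporal-right")
}

#' Schematic 32-channel 10-20-style montage
#'
#' The package's fixture montage: 32 channels laid out on a schematic
#' 10-20-like grid with region tags. It preserves the frontal / midline
#' topology needed for region summaries while keeping the pair count at
#' a desk-scale 496.
#'
#' @return A [montage()] tibble with 32 rows.
#' @export
fixture_montage <- function() {
  def <- list(
    # label,          x,     y,    region
    list("Fp1", -0.30,  0.95, "frontal-left"),
    list("Fp2",  0.30,  0.95, "frontal-right"),
    list("AF3", -0.35,  0.80, "frontal-left"),
    list("AF4",  0.35,  0.80, "frontal-right"),
    list("F7",  -0.70,  0.60, "frontal-left"),
    list("F3",  -0.40,  0.60, "frontal-left"),
    list("Fz",   0.00,  0.60, "midline"),
    list("F4",   0.40,  0.60, "frontal-right"),
    list("F8",   0.70,  0.60, "frontal-right"),
    list("FC5", -0.65,  0.30, "frontal-left"),
    list("FC1", -0.25,  0.30, "central"),
    list("FC2",  0.25,  0.30, "central"),
    list("FC6",  0.65,  0.30, "frontal-right"),
    list("T7",  -0.90,  0.00, "temporal-left"),
    list("C3",  -0.45,  0.00, "central"),
    list("Cz",   0.00,  0.00, "midline"),
    list("C4",   0.45,  0.00, "central"),
    list("T8",   0.90,  0.00, "temporal-right"),
    list("CP5", -0.65, -0.30, "parietal"),
    list("CP1", -0.25, -0.30, "parietal"),
    list("CP2",  0.25, -0.30, "parietal"),
    list("CP6",  0.65, -0.30, "parietal"),
    list("P7",  -0.70, -0.60, "parietal"),
    list("P3",  -0.40, -0.60, "parietal"),
    list("Pz",   0.00, -0.60, "midline"),
    list("P4",   0.40, -0.60, "parietal"),
    list("P8",   0.70, -0.60, "parietal"),
    list("PO3", -0.35, -0.80, "occipital"),
    list("PO4",  0.35, -0.80, "occipital"),
    list("O1",  -0.30, -0.95, "occipital"),
    list("Oz",   0.00, -0.95, "midline"),
    list("O2",   0.30, -0.95, "occipital"))
  montage(label  = vapply(def, `[[`, "", 1),
          x      = vapply(def, `[[`, 0, 2),
          y      = vapply(def, `[[`, 0, 3),
          region = vapply(def, `[[`, "", 4))
}

#' Schematic dense montage of arbitrary size
#'
#' Builds a synthetic regular-grid montage with `n` channels for scaling
#' experiments (e.g. checking pair counts at the 224-channel scale of a
#' dense geodesic net). Channels are labelled `E001`, `E002`, ... and
#' region tags are assigned by grid position.
#'
#' @param n Number of channels (>= 2).
#' @return A [montage()] tibble with `n` rows.
#' @export
schematic_montage <- function(n) {
  stopifnot(n >= 2)
  side <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  gx <- (idx %% side) / max(side - 1, 1) * 2 - 1
  gy <- 1 - (idx %/% side) / max(side - 1, 1) * 2
  region <- ifelse(gy > 0.33,
                   ifelse(abs(gx) < 0.15, "midline",
                          ifelse(gx < 0, "frontal-left", "frontal-right")),
            ifelse(gy < -0.33,
                   ifelse(abs(gx) < 0.15, "midline",
                          ifelse(abs(gx) > 0.6, "parietal", "occipital")),
                   ifelse(abs(gx) > 0.75,
                          ifelse(gx < 0, "temporal-left", "temporal-right"),
                          ifelse(abs(gx) < 0.15, "midline", "central"))))
  montage(sprintf("E%03d", seq_len(n)), gx, gy, region)
}

#' Enumerate unordered channel pairs
#'
#' All unordered channel pairs `(i, j)` with `i` before `j` in montage
#' order. This pair enumeration defines the edge set used everywhere
#' downstream (coherence profiles, edge-wise tests, graphs); its size is
#' `choose(n, 2)` -- 496 for the 32-channel fixture montage, 24976 for a
#' 224-channel net.
#'
#' @param x A montage tibble or a character vector of channel labels.
#' @return Tibble with columns `chan_i`, `chan_j`.
#' @examples
#' nrow(channel_pairs(fixture_montage()))  # 496
#' @export
channel_pairs <- function(x) {
  labels <- if (is.data.frame(x)) x$label else as.character(x)
  if (length(labels) < 2) abort("Need at least 2 channels to form pairs.")
  idx <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  tibble::tibble(chan_i = labels[idx[, "row"]], chan_j = labels[idx[, "col"]])
}
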