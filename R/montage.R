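#' Standard 64-channel scalp montage
#'
#' Builds the idealized 64-channel 10-20/10-10 montage used throughout the
#' package: unit-sphere electrode positions constructed from the standard
#' nasion-inion and preauricular arcs (midline electrodes at 18-degree steps
#' from the vertex, the outer 10% ring at 72 degrees inclination, and
#' intermediate electrodes placed by spherical interpolation between the
#' midline and the ring). FCz is the recording reference and is not part of
#' the montage.
#'
#' Each electrode carries a region tag used by the topographic machinery:
#' `"left-parieto-occipital"`, `"right-parieto-occipital"`,
#' `"frontocentral"` or `"other"`. The three analysis clusters
#' (P7/PO7/O1/TP9, P8/PO8/O2/TP10, Fz/FC1/FC2/Cz) are always members of
#' their region. TP9/TP10, although temporal by name, are assigned to the
#' parieto-occipital regions because they belong to those analysis clusters.
#'
#' @return An object of class `fpvs_montage`: a list with `labels`
#'   (character, length 64), `positions` (64 x 3 matrix of unit vectors,
#'   +y towards the nasion, +x towards the right ear, +z up) and `region`
#'   (named character vector, label -> region).
#' @examples
#' m <- make_montage()
#' m$region[c("PO7", "PO8", "Cz", "Oz")]
#' @export
make_montage <- function() {
  # inclination from vertex (deg), azimuth (deg, 90 = nasion, 0 = right ear)
  sph <- function(incl, az) {
    ir <- incl * pi / 180; ar <- az * pi / 180
    c(sin(ir) * cos(ar), sin(ir) * sin(ar), cos(ir))
  }
  # great-circle interpolation between two unit vectors
  slerp <- function(p, q, t) {
    om <- acos(max(-1, min(1, sum(p * q))))
    if (om < 1e-12) return(p)
    (sin((1 - t) * om) * p + sin(t * om) * q) / sin(om)
  }

  pos <- list()
  # midline (Fpz/FCz absent from the cap but used as construction anchors)
  mid <- list(Fpz = sph(72, 90), AFz = sph(54, 90), Fz = sph(36, 90),
              FCz = sph(18, 90), Cz = sph(0, 90), CPz = sph(18, 270),
              Pz = sph(36, 270), POz = sph(54, 270), Oz = sph(72, 270),
              Iz = sph(90, 270))
  # outer 10% ring at 72 deg inclination, 18 deg azimuthal steps
  ring <- list(
    Fp1 = sph(72, 108), AF7 = sph(72, 126), F7 = sph(72, 144),
    FT7 = sph(72, 162), T7 = sph(72, 180), TP7 = sph(72, 198),
    P7 = sph(72, 216), PO7 = sph(72, 234), O1 = sph(72, 252),
    Fp2 = sph(72, 72), AF8 = sph(72, 54), F8 = sph(72, 36),
    FT8 = sph(72, 18), T8 = sph(72, 0), TP8 = sph(72, 342),
    P8 = sph(72, 324), PO8 = sph(72, 306), O2 = sph(72, 288))
  pos <- c(mid[c("AFz", "Fz", "Cz", "CPz", "Pz", "POz", "Oz", "Iz")], ring)
  # sub-ring electrodes below the FT/TP meridians (at the equator)
  pos$FT9 <- sph(90, 162); pos$TP9 <- sph(90, 198)
  pos$FT10 <- sph(90, 18); pos$TP10 <- sph(90, 342)
  # intermediate rows: interpolate along the arc midline -> outer ring
  rows <- list(
    list(m = "AFz", r = "AF7", lab = c("AF3"), fr = 0.5),
    list(m = "AFz", r = "AF8", lab = c("AF4"), fr = 0.5),
    list(m = "Fz",  r = "F7",  lab = c("F1", "F3", "F5"), fr = c(.25, .5, .75)),
    list(m = "Fz",  r = "F8",  lab = c("F2", "F4", "F6"), fr = c(.25, .5, .75)),
    list(m = "FCz", r = "FT7", lab = c("FC1", "FC3", "FC5"), fr = c(.25, .5, .75)),
    list(m = "FCz", r = "FT8", lab = c("FC2", "FC4", "FC6"), fr = c(.25, .5, .75)),
    list(m = "Cz",  r = "T7",  lab = c("C1", "C3", "C5"), fr = c(.25, .5, .75)),
    list(m = "Cz",  r = "T8",  lab = c("C2", "C4", "C6"), fr = c(.25, .5, .75)),
    list(m = "CPz", r = "TP7", lab = c("CP1", "CP3", "CP5"), fr = c(.25, .5, .75)),
    list(m = "CPz", r = "TP8", lab = c("CP2", "CP4", "CP6"), fr = c(.25, .5, .75)),
    list(m = "Pz",  r = "P7",  lab = c("P1", "P3", "P5"), fr = c(.25, .5, .75)),
    list(m = "Pz",  r = "P8",  lab = c("P2", "P4", "P6"), fr = c(.25, .5, .75)),
    list(m = "POz", r = "PO7", lab = c("PO3"), fr = 0.5),
    list(m = "POz", r = "PO8", lab = c("PO4"), fr = 0.5))
  anchors <- c(mid, ring)
  for (rw in rows)
    for (i in seq_along(rw$lab))
      pos[[rw$lab[i]]] <- slerp(anchors[[rw$m]], anchors[[rw$r]], rw$fr[i])

  labels <- names(pos)
  stopifnot(length(labels) == 64L, !anyDuplicated(labels))
  positions <- do.call(rbind, pos)
  positions <- positions / sqrt(rowSums(positions^2))
  rownames(positions) <- labels

  region <- rep("other", 64L)
  names(region) <- labels
  region[c("P7", "PO7", "O1", "TP9", "P5", "P3", "P1", "PO3", "TP7")] <-
    "left-parieto-occipital"
  region[c("P8", "PO8", "O2", "TP10", "P6", "P4", "P2", "PO4", "TP8")] <-
    "right-parieto-occipital"
  region[c("Fz", "FC1", "FC2", "Cz", "F1", "F2", "FC3", "FC4", "C1", "C2")] <-
    "frontocentral"

  structure(list(labels = labels, positions = positions, region = region),
            class = "fpvs_montage")
}

#' @export
print.fpvs_montage <- function(x, ...) {
  cat("<fpvs_montage> ", length(x$labels), " electrodes\n", sep = "")
  cat("regions:", paste(sprintf("%s (%d)", names(table(x$region)),
                                table(x$region)), collapse = ", "), "\n")
  invisible(x)
}

#' Fixed analysis clusters
#'
#' The three predeclared regions of interest used for the group statistics:
#' left and right parieto-occipital clusters and a frontocentral cluster,
#' four electrodes each.
#'
#' @return A list of three `fpvs_roi` objects, each a list with `name`
#'   (`"left-PO"`, `"right-PO"`, `"frontocentral"`), `electrodes`
#'   (4 labels) and `laterality` (`"left"`, `"right"` or `"n/a"`).
#' @examples
#' fixed_rois()[["left-PO"]]$electrodes
#' @export
fixed_rois <- function() {
  roi <- function(name, el, lat)
    structure(list(name = name, electrodes = el, laterality = lat),
              class = "fpvs_roi")
  list(
    `left-PO` = roi("left-PO", c("P7", "PO7", "O1", "TP9"), "left"),
    `right-PO` = roi("right-PO", c("P8", "PO8", "O2", "TP10"), "right"),
    frontocentral = roi("frontocentral", c("Fz", "FC1", "FC2", "Cz"), "n/a"))
}

#' @export
print.fpvs_roi <- function(x, ...) {
  cat("<fpvs_roi> ", x$name, ": ", paste(x$electrodes, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# region -> ROI name mapping used by the localizer and summaries
.roi_region <- c(`left-PO` = "left-parieto-occipital",
                 `right-PO` = "right-parieto-occipital",
                 frontocentral = "frontocentral")
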