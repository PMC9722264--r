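#' Construct a cortical field-of-view geometry
#'
#' The default field spans AP +1.5 to -6.5 mm and ML -1.0 to +5.0 mm at a
#' 0.1-mm pixel pitch (80 x 60 pixels), a window over one dorsal hemisphere
#' large enough to contain both fiber sites and the evoked footprints. The
#' fiber/electrode sites follow the stereotaxic coordinates used throughout:
#' S1 at (AP -0.2, ML 2.5) and V1 at (AP -3.8, ML 2.0).
#'
#' @param apLim numeric(2): AP coordinates (mm) of the anterior and posterior
#'   field edges, `apLim[1] > apLim[2]`.
#' @param mlLim numeric(2): ML coordinates (mm) of the medial and lateral
#'   field edges, increasing.
#' @param pixelPitchMm pixel size in mm.
#' @param sites matrix with columns `ap`, `ml`, rownames = site labels.
#' @return A [FieldGeometry-class] object.
#' @examples
#' geom <- fieldGeometry()
#' fieldDim(geom)
#' @export
fieldGeometry <- function(apLim = c(1.5, -6.5), mlLim = c(-1.0, 5.0),
                          pixelPitchMm = 0.1, sites = defaultSites()) {
  new("FieldGeometry", apLim = as.numeric(apLim), mlLim = as.numeric(mlLim),
      pixelPitchMm = as.numeric(pixelPitchMm), sites = sites)
}

#' Default recording sites
#'
#' @return matrix of stereotaxic coordinates (mm) for the S1 and V1 sites.
#' @export
defaultSites <- function() {
  m <- rbind(S1 = c(ap = -0.2, ml = 2.5), V1 = c(ap = -3.8, ml = 2.0))
  colnames(m) <- c("ap", "ml")
  m
}

#' Field dimensions in pixels
#'
#' @param geom a [FieldGeometry-class].
#' @return integer(2): rows (AP extent) and columns (ML extent).
#' @export
fieldDim <- function(geom) {
  c(rows = as.integer(round((geom@apLim[1] - geom@apLim[2]) / geom@pixelPitchMm)),
    cols = as.integer(round((geom@mlLim[2] - geom@mlLim[1]) / geom@pixelPitchMm)))
}

#' Field area in mm^2
#'
#' @param geom a [FieldGeometry-class].
#' @return numeric scalar, field area.
#' @export
fieldAreaMm2 <- function(geom) {
  hw <- fieldDim(geom)
  hw[["rows"]] * hw[["cols"]] * geom@pixelPitchMm^2
}

#' Pixel-centre coordinates
#'
#' Rows run anterior to posterior (decreasing stereotaxic AP), columns medial
#' to lateral.
#'
#' @param geom a [FieldGeometry-class].
#' @return list with `ap` (length rows) and `ml` (length cols) centre
#'   coordinates (mm).
#' @export
pixelCenters <- function(geom) {
  hw <- fieldDim(geom)
  list(ap = geom@apLim[1] - (seq_len(hw[1]) - 0.5) * geom@pixelPitchMm,
       ml = geom@mlLim[1] + (seq_len(hw[2]) - 0.5) * geom@pixelPitchMm)
}

#' Site coordinates
#'
#' @param geom a [FieldGeometry-class].
#' @param site site label, e.g. "S1".
#' @return numeric(2): `ap`, `ml` in mm.
#' @export
siteCoords <- function(geom, site) {
  if (!site %in% rownames(geom@sites))
    stop("unknown site: ", site)
  geom@sites[site, c("ap", "ml")]
}

## unit vector of a propagation direction (0 = anterior, +pi/2 = lateral)
directionUnit <- function(thetaRad) {
  cbind(ap = cos(thetaRad), ml = sin(thetaRad))
}

## signed travel time (s) from an origin to points, along direction theta
travelTimeS <- function(ap, ml, originAp, originMl, thetaRad, speedMmS) {
  u <- directionUnit(thetaRad)
  ((ap - originAp) * u[, "ap"] + (ml - originMl) * u[, "ml"]) / speedMmS
}

## wrap angles to (-pi, pi]
wrapAngle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}
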