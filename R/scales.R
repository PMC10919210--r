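#' @include AllClasses.R
NULL

# Built-in ramps as explicit control-point tables, interpolated linearly in
# sRGB — backend independent and bit-stable.
.RAMPS <- list(
  "viridis-like" = c("#440154", "#472d7b", "#3b528b", "#2c728e", "#21918c",
                     "#28ae80", "#5ec962", "#addc30", "#fde725"),
  "jet-like"     = c("#00007f", "#0000ff", "#00ffff", "#ffff00", "#ff0000", "#7f0000"),
  "turbo-like"   = c("#30123b", "#4669db", "#26bce1", "#3ef48c", "#e1dd37",
                     "#fa7d20", "#7a0403"),
  "greys"        = c("#ffffff", "#000000"),
  "bwr"          = c("#0000ff", "#ffffff", "#ff0000"))

#' Names of the built-in continuous color ramps
#' @return character vector of ramp names
#' @export
rampNames <- function() names(.RAMPS)

# any R color -> 8-digit lowercase hex rgba
.norm_color <- function(x) {
  rgba <- grDevices::col2rgb(x, alpha = TRUE)
  tolower(grDevices::rgb(rgba[1L, ], rgba[2L, ], rgba[3L, ], rgba[4L, ],
                         maxColorValue = 255))
}

# evaluate ramp at t in [0,1]; piecewise-linear between control points
.ramp_eval <- function(ramp_name, t) {
  pts <- .RAMPS[[ramp_name]]
  if (is.null(pts)) stop(sprintf("unknown ramp '%s'", ramp_name))
  rgb <- grDevices::col2rgb(pts)
  m <- length(pts)
  t <- pmin(pmax(t, 0), 1)
  pos <- t * (m - 1L)
  lo <- pmin(floor(pos), m - 2L)
  frac <- pos - lo
  mix <- function(ch) rgb[ch, lo + 1L] * (1 - frac) + rgb[ch, lo + 2L] * frac
  tolower(grDevices::rgb(mix(1L), mix(2L), mix(3L), 255, maxColorValue = 255))
}

# fixed default categorical palette (10 colors, tab10-like)
.DEFAULT_PALETTE <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
                      "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf")

#' Default categorical palette
#' @return character vector of 10 hex RGBA colors
#' @export
defaultPalette <- function() .norm_color(.DEFAULT_PALETTE)

# fixed marker vocabulary; hue levels map to markers by first appearance
.MARKERS <- c("circle", "square", "triangle", "diamond", "cross", "star")

#' Marker shape vocabulary
#' @return character vector of the marker shape names, assignment order
#' @export
markerShapes <- function() .MARKERS

#' Construct a categorical color specification
#'
#' @param mapping named character vector, category -> color; colors may be
#'   any R color and are normalized to 8-digit hex RGBA.
#' @param categories optional categories to pre-assign from the fallback
#'   palette, in order.
#' @param fallback palette used for categories absent from the mapping;
#'   set to \code{character(0)} to make unmapped categories an error.
#' @param missingColor color for missing values.
#' @param title legend title.
#' @return a \linkS4class{ColorSpec}
#' @export
colorSpecCategorical <- function(mapping = NULL, categories = NULL,
                                 fallback = defaultPalette(),
                                 missingColor = "#bdbdbdff", title = "category") {
  map <- character(0)
  if (!is.null(mapping)) {
    map <- .norm_color(as.character(mapping))
    names(map) <- names(mapping)
  }
  if (!is.null(categories)) {
    todo <- setdiff(as.character(categories), names(map))
    if (length(todo)) {
      if (!length(fallback)) stop("no fallback palette to assign categories from")
      add <- .norm_color(rep_len(fallback, length(todo)))
      names(add) <- todo
      map <- c(map, add)
    }
  }
  new("ColorSpec", mode = "categorical", mapping = map,
      fallback = if (length(fallback)) .norm_color(fallback) else character(0),
      missingColor = .norm_color(missingColor), title = title)
}

#' Construct a continuous color specification
#'
#' Values map affinely from [vmin, vmax] into the ramp; out-of-range values
#' are clipped. Leave vmin/vmax as NA to resolve them from the data (min and
#' max, or the 1st/99th percentiles with \code{robust = TRUE}).
#'
#' @param ramp ramp name, see \code{\link{rampNames}}.
#' @param vmin,vmax numeric range or NA.
#' @param missingColor color for missing values.
#' @param title legend title.
#' @param robust use q01/q99 instead of min/max when resolving from data.
#' @return a \linkS4class{ColorSpec}
#' @export
colorSpecContinuous <- function(ramp = "viridis-like", vmin = NA_real_,
                                vmax = NA_real_, missingColor = "#bdbdbdff",
                                title = "value", robust = FALSE) {
  if (!ramp %in% names(.RAMPS)) stop(sprintf("unknown ramp '%s'", ramp))
  sp <- new("ColorSpec", mode = "continuous", ramp = ramp,
            vmin = as.numeric(vmin), vmax = as.numeric(vmax),
            missingColor = .norm_color(missingColor), title = title)
  attr(sp, "robust") <- isTRUE(robust)
  sp
}

#' Resolve a color specification against observed data
#'
#' Completes a categorical mapping over the observed categories (assigning
#' fallback colors in first-appearance order) and fills an unresolved
#' continuous range from the data. Resolution is idempotent.
#'
#' @param spec a \linkS4class{ColorSpec}
#' @param values the data the spec will be applied to.
#' @return the resolved \linkS4class{ColorSpec}
#' @export
resolveColorSpec <- function(spec, values) {
  stopifnot(is(spec, "ColorSpec"))
  if (spec@mode == "categorical") {
    obs <- unique(as.character(values))
    obs <- obs[!is.na(obs)]
    todo <- setdiff(obs, names(spec@mapping))
    if (length(todo)) {
      if (!length(spec@fallback))
        stop(sprintf("no color mapped for category '%s'", todo[1L]))
      used <- length(spec@mapping)
      add <- rep_len(spec@fallback, used + length(todo))[used + seq_along(todo)]
      names(add) <- todo
      spec@mapping <- c(spec@mapping, add)
    }
  } else {
    v <- suppressWarnings(as.numeric(values))
    v <- v[is.finite(v)]
    if (is.na(spec@vmin) || is.na(spec@vmax)) {
      if (!length(v)) stop("cannot resolve a continuous range from all-missing data")
      if (isTRUE(attr(spec, "robust"))) {
        q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
        if (is.na(spec@vmin)) spec@vmin <- q[1L]
        if (is.na(spec@vmax)) spec@vmax <- q[2L]
      } else {
        if (is.na(spec@vmin)) spec@vmin <- min(v)
        if (is.na(spec@vmax)) spec@vmax <- max(v)
      }
    }
  }
  spec
}

#' Map values to colors
#'
#' Element-wise color lookup. Categorical: direct mapping (fallback colors
#' assigned to unmapped categories, error when no fallback is declared).
#' Continuous: affine to [0, 1] then ramp lookup, with out-of-range values
#' clipped; a constant vector (vmin == vmax) maps to the ramp midpoint.
#' Missing values map to the spec's missing color.
#'
#' @param values character (categorical) or numeric (continuous) vector.
#' @param spec a \linkS4class{ColorSpec}
#' @return character vector of 8-digit hex RGBA colors, same length
#' @export
mapColors <- function(values, spec) {
  spec <- resolveColorSpec(spec, values)
  if (spec@mode == "categorical") {
    v <- as.character(values)
    out <- unname(spec@mapping[v])
    out[is.na(v)] <- spec@missingColor
  } else {
    v <- as.numeric(values)
    out <- rep(spec@missingColor, length(v))
    ok <- is.finite(v)
    if (any(ok)) {
      if (spec@vmin == spec@vmax) t <- rep(0.5, sum(ok))
      else t <- (pmin(pmax(v[ok], spec@vmin), spec@vmax) - spec@vmin) /
        (spec@vmax - spec@vmin)
      out[ok] <- .ramp_eval(spec@ramp, t)
    }
  }
  out
}

#' Map values to dot radii
#'
#' Radius = rMax * sqrt((clip(v, vmin, vmax) - vmin) / (vmax - vmin)), so
#' dot area is linear in value; v = vmin gives radius 0 (no dot drawn) and
#' v = vmax gives rMax.
#'
#' @param values finite numeric vector.
#' @param scale a \linkS4class{SizeScale}
#' @return numeric radii (fractions of the cell half-extent)
#' @export
mapSizes <- function(values, scale) {
  stopifnot(is(scale, "SizeScale"))
  v <- as.numeric(values)
  if (any(!is.finite(v))) stop("size values must be finite")
  scale@rMax * sqrt((pmin(pmax(v, scale@vmin), scale@vmax) - scale@vmin) /
                      (scale@vmax - scale@vmin))
}

# relative luminance of a color (linearized sRGB)
.rel_luminance <- function(color) {
  rgb <- grDevices::col2rgb(color) / 255
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  as.numeric(c(0.2126, 0.7152, 0.0722) %*% lin)
}

#' Black-or-white text color for contrast against a fill
#'
#' White when the fill's relative luminance is below 0.5, black otherwise —
#' deterministic, used by add_text on simple annotations.
#'
#' @param fill background color(s)
#' @return "#ffffffff" or "#000000ff" per element
#' @export
textContrastColor <- function(fill) {
  vapply(fill, function(col)
    if (.rel_luminance(col) < 0.5) "#ffffffff" else "#000000ff",
    character(1), USE.NAMES = FALSE)
}
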