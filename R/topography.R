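# Anatomical assignment of imaged cells and gradients of coding properties
# along stereotaxic axes.

#' Approximate stereotaxic coordinates of imaged cells
#'
#' Each cell inherits the implant-lens center coordinates plus its planar
#' offset within the field of view, converted to mm. The imaging plane is
#' single, so DV is the lens-center DV for all cells. Offsets are validated
#' against the lens radius.
#'
#' @param lens_center_mm named numeric vector with `AP`, `ML`, `DV` (mm,
#'   stereotaxic).
#' @param offsets n x 2 matrix of in-plane cell offsets; first column maps
#'   onto AP, second onto ML.
#' @param units `"um"` (default) or `"px"`.
#' @param um_per_pixel calibration factor, used when `units = "px"`.
#' @param lens_radius_um maximum admissible offset norm (250 um for a 0.5 mm
#'   lens).
#' @return data frame with columns `cell`, `AP`, `ML`, `DV` (mm),
#'   `offset_um_x`, `offset_um_y`.
#' @export
assign_coordinates <- function(lens_center_mm, offsets, units = c("um", "px"),
                               um_per_pixel = 1, lens_radius_um = 250) {
  units <- match.arg(units)
  stopifnot_scalar_pos(um_per_pixel, "um_per_pixel")
  offsets <- as.matrix(offsets)
  if (units == "px") offsets <- offsets * um_per_pixel
  r <- sqrt(rowSums(offsets^2))
  if (any(r > lens_radius_um + 1e-9))
    stop("cell offset beyond the lens radius")
  need <- c("AP", "ML", "DV")
  if (!all(need %in% names(lens_center_mm)))
    stop("lens_center_mm needs named entries AP, ML, DV")
  data.frame(cell = seq_len(nrow(offsets)),
             AP = lens_center_mm[["AP"]] + offsets[, 1] / 1000,
             ML = lens_center_mm[["ML"]] + offsets[, 2] / 1000,
             DV = lens_center_mm[["DV"]],
             offset_um_x = offsets[, 1], offset_um_y = offsets[, 2])
}

#' Regression of a coding property along an anatomical axis
#'
#' Bins cell coordinates along the chosen axis (0.2 mm bins), computes per
#' animal per bin the proportion of flagged cells (e.g. stable spatially
#' modulated), and fits an ordinary least-squares line of proportion on bin
#' center. Bins holding fewer than `min_cells` recorded cells for an animal
#' are dropped to avoid degenerate 0/1 proportions.
#'
#' @param coords data frame with columns `animal`, and the axis column
#'   (`AP`, `ML` or `DV`, in mm; e.g. rbind of [assign_coordinates()]
#'   results with an `animal` column added).
#' @param flags logical vector, one per row of `coords`: does the cell carry
#'   the property?
#' @param axis `"AP"`, `"ML"` or `"DV"`.
#' @param bin_width_mm anatomical bin width.
#' @param min_cells minimum cells per (animal, bin) point.
#' @return list with `points` (data frame `animal`, `bin_center`,
#'   `proportion`, `n_cells`), `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_points`, `n_animals`.
#' @export
gradient_regression <- function(coords, flags, axis = c("AP", "DV", "ML"),
                                bin_width_mm = 0.2, min_cells = 5) {
  axis <- match.arg(axis)
  stopifnot(nrow(coords) == length(flags))
  x <- coords[[axis]]
  bin <- floor(x / bin_width_mm)
  key <- interaction(coords$animal, bin, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_along(x), key), function(idx) {
    data.frame(animal = coords$animal[idx[1]],
               bin_center = (bin[idx[1]] + 0.5) * bin_width_mm,
               proportion = mean(flags[idx]), n_cells = length(idx))
  }))
  agg <- agg[agg$n_cells >= min_cells, , drop = FALSE]
  if (nrow(agg) < 3L) stop("fewer than 3 (animal, bin) points")
  if (length(unique(agg$bin_center)) < 2L)
    stop("all points share one bin; no gradient estimable")
  if (sd(agg$proportion) == 0)
    return(list(points = agg, slope = 0, intercept = agg$proportion[1],
                r_squared = 0, p_value = 1, n_points = nrow(agg),
                n_animals = length(unique(agg$animal)), axis = axis))
  fit <- lm(proportion ~ bin_center, data = agg)
  sm <- summary(fit)
  list(points = agg, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients["bin_center", "Pr(>|t|)"],
       n_points = nrow(agg), n_animals = length(unique(agg$animal)),
       axis = axis)
}
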