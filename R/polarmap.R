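## AHA 17-segment polar-map data model.
##
## The left ventricle is divided into 6 basal (1-6), 6 mid-cavity (7-12) and
## 4 apical (13-16) segments plus the apex (17). Tracer uptake is expressed
## as percent of the hottest segment, transmurality as the transmural extent
## of late gadolinium enhancement, and contractility as percent systolic wall
## thickening (negative values = dyskinesis, floored at -50).

AHA_SECTORS <- c(
  "basal anterior", "basal anteroseptal", "basal inferoseptal",
  "basal inferior", "basal inferolateral", "basal anterolateral",
  "mid anterior", "mid anteroseptal", "mid inferoseptal",
  "mid inferior", "mid inferolateral", "mid anterolateral",
  "apical anterior", "apical septal", "apical inferior", "apical lateral",
  "apex")

AHA_RINGS <- c(rep("basal", 6), rep("mid", 6), rep("apical", 4), "apex")

#' AHA 17-segment layout
#'
#' @return data.frame with `segment_id`, `ring`
#'   (basal/mid/apical/apex) and anatomical `sector_label`.
#' @export
aha_segments <- function() {
  data.frame(segment_id = 1:17, ring = AHA_RINGS, sector_label = AHA_SECTORS,
             stringsAsFactors = FALSE)
}

#' Segmental imaging profile of one animal at one timepoint
#'
#' Bundles the per-segment transmurality, raw and peak-normalised FDG uptake
#' and contractility vectors of the 17-segment model, plus the extent of
#' microvascular obstruction (MVO). If `uptake_norm` is omitted it is
#' computed from `uptake_raw` via [normalize_uptake()].
#'
#' @param animal_id identifier (coerced to character).
#' @param timepoint `"day3"` or `"month1"`.
#' @param transmurality length-17 percent vector in \[0, 100\].
#' @param uptake_raw length-17 nonnegative vector (arbitrary units).
#' @param uptake_norm optional length-17 percent vector; must have max 100.
#' @param contractility length-17 percent systolic wall thickening,
#'   \[-50, 100\].
#' @param mvo_extent MVO as percent of LV mass.
#' @return object of class `segment_profile`.
#' @export
segment_profile <- function(animal_id, timepoint = c("day3", "month1"),
                            transmurality, uptake_raw = NULL,
                            uptake_norm = NULL, contractility = rep(0, 17),
                            mvo_extent = 0) {
  timepoint <- match.arg(timepoint)
  check_percent17(transmurality, "transmurality")
  check_percent17(contractility, "contractility", lower = -50, upper = 100)
  check_number(mvo_extent, "mvo_extent", lower = 0, upper = 100)
  if (is.null(uptake_raw) && is.null(uptake_norm)) {
    stop_input("one of 'uptake_raw' or 'uptake_norm' is required")
  }
  if (is.null(uptake_norm)) {
    uptake_norm <- normalize_uptake(uptake_raw, animal_id = animal_id)
  } else {
    check_percent17(uptake_norm, "uptake_norm")
    if (abs(max(uptake_norm) - 100) > 1e-8) {
      stop_input("'uptake_norm' must be peak-normalised (max = 100)")
    }
  }
  if (is.null(uptake_raw)) uptake_raw <- uptake_norm
  check_percent17(uptake_raw, "uptake_raw", lower = 0, upper = Inf)
  structure(list(animal_id = as.character(animal_id), timepoint = timepoint,
                 transmurality = as.numeric(transmurality),
                 uptake_raw = as.numeric(uptake_raw),
                 uptake_norm = as.numeric(uptake_norm),
                 contractility = as.numeric(contractility),
                 mvo_extent = as.numeric(mvo_extent)),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("<segment_profile> animal %s, %s\n", x$animal_id, x$timepoint))
  cat(sprintf("  uptake_norm : %s\n", paste(round(x$uptake_norm, 1), collapse = " ")))
  cat(sprintf("  transmurality: %s\n", paste(round(x$transmurality, 1), collapse = " ")))
  cat(sprintf("  MVO extent  : %.1f%% of LV\n", x$mvo_extent))
  invisible(x)
}

#' Myocardial territory
#'
#' A named subset of the 17 AHA segments.
#'
#' @param name territory label.
#' @param segment_ids unique integers in 1..17, nonempty.
#' @return object of class `territory`.
#' @export
territory <- function(name, segment_ids) {
  segment_ids <- as.integer(segment_ids)
  if (length(segment_ids) == 0L || anyNA(segment_ids) ||
      any(segment_ids < 1L) || any(segment_ids > 17L) ||
      anyDuplicated(segment_ids)) {
    stop_input("'segment_ids' must be unique integers in 1..17 (nonempty)")
  }
  structure(list(name = as.character(name), segment_ids = sort(segment_ids)),
            class = "territory")
}

#' @export
print.territory <- function(x, ...) {
  cat(sprintf("<territory> %s: segments %s\n", x$name,
              paste(x$segment_ids, collapse = ", ")))
  invisible(x)
}

#' Default LAD infarct territory
#'
#' Mid-LAD occlusion infarcts the apical and mid anterior and apical and mid
#' septal wall: AHA segments 7 (mid anterior), 8 (mid anteroseptal),
#' 9 (mid inferoseptal), 13 (apical anterior) and 14 (apical septal).
#'
#' @return a [territory()].
#' @export
lad_territory <- function() territory("LAD infarct", c(7L, 8L, 9L, 13L, 14L))

#' Peak-normalise segmental tracer uptake
#'
#' Rescales raw FDG uptake so the hottest segment reads 100%:
#' `out_i = 100 * raw_i / max(raw)`.
#'
#' @param uptake_raw length-17 nonnegative vector.
#' @param animal_id optional identifier used in error messages.
#' @return length-17 percent vector with maximum exactly 100.
#' @export
#' @examples
#' normalize_uptake(c(80, 40, 20, rep(0, 14)))[1:3]
normalize_uptake <- function(uptake_raw, animal_id = NULL) {
  if (!is.numeric(uptake_raw) || length(uptake_raw) != 17L || anyNA(uptake_raw)) {
    stop_input("'uptake_raw' must be a length-17 numeric vector with no NA")
  }
  if (any(uptake_raw < 0)) stop_input("'uptake_raw' must be nonnegative")
  mx <- max(uptake_raw)
  if (mx <= 0) {
    who <- if (is.null(animal_id)) "" else sprintf(" (animal %s)", animal_id)
    stop_input("degenerate uptake vector: all segments zero", who)
  }
  100 * uptake_raw / mx
}

#' Mean imaging quantities over a territory
#'
#' Unweighted arithmetic means of normalised uptake, transmurality and
#' contractility over the territory's segments.
#'
#' @param profile a [segment_profile()].
#' @param territory a [territory()].
#' @return list with `mean_uptake`, `mean_transmurality`, `mean_contractility`.
#' @export
territory_summary <- function(profile, territory) {
  stopifnot(inherits(profile, "segment_profile"), inherits(territory, "territory"))
  ids <- territory$segment_ids
  list(mean_uptake = mean(profile$uptake_norm[ids]),
       mean_transmurality = mean(profile$transmurality[ids]),
       mean_contractility = mean(profile$contractility[ids]))
}

#' Tabular polar map
#'
#' Lays one per-segment quantity out as the standard AHA polar-map table.
#'
#' @param profile a [segment_profile()].
#' @param quantity `"transmurality"`, `"uptake_norm"` or `"contractility"`.
#' @return data.frame with columns `segment_id`, `ring`, `sector_label`,
#'   `value` (17 rows, segment order preserved).
#' @export
polar_table <- function(profile,
                        quantity = c("transmurality", "uptake_norm", "contractility")) {
  stopifnot(inherits(profile, "segment_profile"))
  quantity <- match.arg(quantity)
  out <- aha_segments()
  out$value <- profile[[quantity]]
  out
}

#' Reassemble a 17-vector from a polar-map table
#'
#' Inverse of [polar_table()]: rows may come in any order.
#'
#' @param tab data.frame with `segment_id` and `value` columns.
#' @return numeric length-17 vector indexed by segment id.
#' @export
polar_table_to_vector <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("segment_id", "value") %in% names(tab)))
  if (nrow(tab) != 17L || !setequal(tab$segment_id, 1:17)) {
    stop_input("polar table must contain each segment 1..17 exactly once")
  }
  v <- numeric(17)
  v[tab$segment_id] <- tab$value
  v
}

#' Render a polar map
#'
#' Base-graphics bull's-eye display of one segmental quantity (basal ring
#' outermost, apex in the centre), coloured on a white-to-red ramp over the
#' value range.
#'
#' @param x a [segment_profile()].
#' @param quantity quantity to draw (see [polar_table()]).
#' @param ... ignored.
#' @return the polar table, invisibly.
#' @export
plot.segment_profile <- function(x, quantity = "uptake_norm", ...) {
  tab <- polar_table(x, quantity)
  rng <- range(tab$value)
  if (diff(rng) == 0) rng <- rng + c(-1, 1)
  ramp <- grDevices::colorRamp(c("white", "firebrick"))
  col_of <- function(v) {
    z <- (v - rng[1]) / diff(rng)
    grDevices::rgb(ramp(z), maxColorValue = 255)
  }
  graphics::plot.new()
  graphics::plot.window(c(-1.1, 1.1), c(-1.1, 1.1), asp = 1)
  rings <- list(basal = c(0.75, 1), mid = c(0.5, 0.75), apical = c(0.25, 0.5),
                apex = c(0, 0.25))
  ## 6 sectors for basal/mid starting at 60 deg (anterior on top), 4 apical
  starts <- list(basal = 90 + seq(0, 300, by = 60),
                 mid = 90 + seq(0, 300, by = 60),
                 apical = 45 + seq(0, 270, by = 90))
  seg_arc <- function(r0, r1, a0, a1, col) {
    th <- seq(a0, a1, length.out = 40) * pi / 180
    graphics::polygon(c(r1 * cos(th), rev(r0 * cos(th))),
                      c(r1 * sin(th), rev(r0 * sin(th))),
                      col = col, border = "grey30")
  }
  for (i in 1:17) {
    ring <- tab$ring[i]
    col <- col_of(tab$value[i])
    if (ring == "apex") {
      th <- seq(0, 2 * pi, length.out = 80)
      graphics::polygon(0.25 * cos(th), 0.25 * sin(th), col = col,
                        border = "grey30")
    } else {
      idx <- i - switch(ring, basal = 0L, mid = 6L, apical = 12L)
      width <- if (ring == "apical") 90 else 60
      a0 <- starts[[ring]][idx]
      seg_arc(rings[[ring]][1], rings[[ring]][2], a0, a0 + width, col)
    }
  }
  graphics::title(main = sprintf("%s - %s (%s)", x$animal_id, quantity, x$timepoint))
  invisible(tab)
}
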