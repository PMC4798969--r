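#' Neural-tube section outline
#'
#' Closed polygon of the NT boundary in a transverse section, with the
#' dorsal-midline and ventral-midline anchor points that parameterise the
#' perimeter score (0% = dorsal right extreme, 50% = ventral, 100% =
#' dorsal left extreme).
#'
#' @param points Matrix or data frame of boundary points with columns
#'   (y, x), ordered along the boundary; the polygon closes implicitly
#'   from the last point back to the first.
#' @param dorsal_index,ventral_index Indices (into `points`) of the dorsal
#'   and ventral midline anchors; must be distinct.
#' @param context Section context label: "axis" or "tail_bud".
#' @return Object of class `section_outline`.
#' @export
section_outline <- function(points, dorsal_index, ventral_index,
                            context = c("axis", "tail_bud")) {
  context <- match.arg(context)
  pts <- as.matrix(as.data.frame(points)[, c("y", "x")])
  n <- nrow(pts)
  if (n < 3L)
    nmp_error("invalid_outline", "an outline needs at least 3 points")
  if (dorsal_index < 1L || dorsal_index > n ||
      ventral_index < 1L || ventral_index > n)
    nmp_error("invalid_outline", "anchor indices must address outline points")
  if (dorsal_index == ventral_index)
    nmp_error("invalid_outline", "anchors must be distinct")
  if (any(rowSums((pts - pts[c(2:n, 1L), ])^2) == 0))
    nmp_error("invalid_outline", "consecutive outline points must be distinct")
  if (n <= 2000L && !polygon_is_simple(pts))
    nmp_error("invalid_outline", "outline polygon must be simple (no self-intersection)")
  structure(list(points = pts, dorsal_index = as.integer(dorsal_index),
                 ventral_index = as.integer(ventral_index),
                 context = context),
            class = "section_outline")
}

# segment intersection test for non-adjacent edges (proper crossings only)
polygon_is_simple <- function(pts) {
  n <- nrow(pts)
  seg_a <- pts
  seg_b <- pts[c(2:n, 1L), ]
  orient <- function(p, q, r)
    sign((q[, 2] - p[, 2]) * (r[, 1] - p[, 1]) -
         (q[, 1] - p[, 1]) * (r[, 2] - p[, 2]))
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]   # skip edges adjacent to i
    if (!length(js)) next
    p1 <- matrix(seg_a[i, ], length(js), 2, byrow = TRUE)
    q1 <- matrix(seg_b[i, ], length(js), 2, byrow = TRUE)
    p2 <- seg_a[js, , drop = FALSE]
    q2 <- seg_b[js, , drop = FALSE]
    d1 <- orient(p1, q1, p2); d2 <- orient(p1, q1, q2)
    d3 <- orient(p2, q2, p1); d4 <- orient(p2, q2, q1)
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Donor-cell mark on a section
#'
#' @param y,x Mark position in the section plane.
#' @param section Optional section reference (outline id or label).
#' @return Object of class `donor_cell_mark`.
#' @export
donor_cell_mark <- function(y, x, section = NA) {
  structure(list(y = y, x = x, section = section),
            class = "donor_cell_mark")
}

# cumulative arc lengths of the closed polygon visited in the order `ord`
# (vertex indices); returns per-vertex arc coordinate and total perimeter.
arc_coordinates <- function(pts, ord) {
  p <- pts[ord, , drop = FALSE]
  seg <- sqrt(rowSums((p[c(2:nrow(p), 1L), , drop = FALSE] - p)^2))
  list(at_vertex = c(0, cumsum(seg[-length(seg)])), total = sum(seg))
}

#' Score a donor-cell position on the NT perimeter
#'
#' Projects the mark onto the nearest point of the outline (error beyond
#' `snap_tolerance`) and expresses its position as a percentage of the NT
#' perimeter: 0% at the dorsal anchor approached from the right, 50% at
#' the ventral anchor, 100% back at the dorsal anchor from the left. Arc
#' length is rescaled piecewise (dorsal-to-ventral spans 0-50, ventral-to-
#' dorsal spans 50-100) so the ventral anchor maps to exactly 50 for any
#' outline shape. The travel direction from the dorsal anchor is chosen to
#' enter the observer's right side of the dorsoventral axis first, which
#' makes the score invariant to rigid rotation and translation.
#'
#' @param outline A [section_outline()].
#' @param mark A [donor_cell_mark()] or a length-2 numeric (y, x).
#' @param snap_tolerance Maximum distance from the outline (length units);
#'   marks further away raise a not-on-outline error. Marks inside the
#'   lumen are projected to the nearest boundary point.
#' @return List of class `perimeter_score`: percentage in [0, 100] and
#'   side flag ("right" below 50, "left" above, "midline" at 0/50/100).
#' @export
score_nt_position <- function(outline, mark, snap_tolerance = 3) {
  if (inherits(mark, "donor_cell_mark")) mark <- c(mark$y, mark$x)
  pts <- outline$points
  n <- nrow(pts)

  # traversal order starting at the dorsal anchor, right side first
  a <- pts[outline$dorsal_index, ]
  v <- pts[outline$ventral_index, ]
  d <- v - a                                    # dorsoventral axis (y, x)
  fwd <- c(outline$dorsal_index:n, seq_len(outline$dorsal_index - 1L))
  nxt <- pts[fwd[2L], ] - a
  prv <- pts[rev(fwd)[1L], ] - a
  # image-coordinate handedness (y down, x right): positive = right side
  cross_z <- function(u, w) u[1] * w[2] - u[2] * w[1]
  ord <- if (cross_z(d, nxt) >= cross_z(d, prv)) fwd else
    c(outline$dorsal_index, rev(fwd[-1L]))

  arc <- arc_coordinates(pts, ord)
  s_v <- arc$at_vertex[match(outline$ventral_index, ord)]
  total <- arc$total

  # project the mark on every edge of the traversal
  p1 <- pts[ord, , drop = FALSE]
  p2 <- pts[c(ord[-1L], ord[1L]), , drop = FALSE]
  e <- p2 - p1
  len2 <- rowSums(e^2)
  tpar <- pmin(pmax(((mark[1] - p1[, 1]) * e[, 1] +
                     (mark[2] - p1[, 2]) * e[, 2]) / len2, 0), 1)
  proj <- p1 + e * tpar
  d2 <- (mark[1] - proj[, 1])^2 + (mark[2] - proj[, 2])^2
  k <- which.min(d2)
  if (sqrt(d2[k]) > snap_tolerance)
    nmp_error("not_on_outline", sprintf(
      "mark is %.2f length-units from the outline (snap tolerance %.2f)",
      sqrt(d2[k]), snap_tolerance))
  s_m <- arc$at_vertex[k] + sqrt(len2[k]) * tpar[k]
  if (s_m >= total) s_m <- s_m - total

  pct <- if (s_m <= s_v) 50 * s_m / s_v else
    50 + 50 * (s_m - s_v) / (total - s_v)
  side <- if (pct %in% c(0, 50, 100)) "midline" else
    if (pct < 50) "right" else "left"
  structure(list(percentage = pct, side = side), class = "perimeter_score")
}

#' Positional histogram of perimeter scores
#'
#' Counts scored marks in positional bins along the NT perimeter, split by
#' section context (axis sections vs tail-bud sections reported
#' separately).
#'
#' @param scores Data frame with columns `percentage` (0-100) and
#'   `context` ("axis"/"tail_bud"), or a list of `perimeter_score`
#'   objects (context then defaults to "axis").
#' @param bin_width Bin width in percent; must divide 100.
#' @return Integer matrix, bins x contexts; counts sum to the number of
#'   marks.
#' @export
section_histogram <- function(scores, bin_width = 10) {
  if (100 %% bin_width != 0)
    nmp_error("invalid_params", "bin_width must divide 100")
  if (!is.data.frame(scores)) {
    scores <- data.frame(
      percentage = vapply(scores, function(s) s$percentage, numeric(1)),
      context = "axis", stringsAsFactors = FALSE)
  }
  nb <- 100 %/% bin_width
  labs <- sprintf("[%d,%d%s", bin_width * (seq_len(nb) - 1L),
                  bin_width * seq_len(nb),
                  c(rep(")", nb - 1L), "]"))
  contexts <- c("axis", "tail_bud")
  h <- matrix(0L, nb, length(contexts), dimnames = list(labs, contexts))
  if (nrow(scores)) {
    bin <- pmin(floor(scores$percentage / bin_width) + 1L, nb)
    tab <- table(factor(bin, levels = seq_len(nb)),
                 factor(scores$context, levels = contexts))
    h[] <- as.integer(tab)
  }
  h
}

#' Cohort tissue-contribution percentages
#'
#' For each tissue category (neural, paraxial mesoderm, lateral/ventral
#' mesoderm, axial mesoderm, endoderm, surface ectoderm, ...), the
#' percentage of scorable sections containing donor cells in that tissue,
#' plus (when an `embryo` column is present) the percentage of embryos
#' with any positive section per category.
#'
#' @param per_section_flags Data frame, one row per scorable section:
#'   logical columns per tissue category, optional `embryo` id column.
#' @return List: `section_pct` (named percentages per category over
#'   sections), `embryo_pct` (per-embryo presence percentages, or NULL),
#'   `n_sections`.
#' @export
cohort_contribution <- function(per_section_flags) {
  flags <- as.data.frame(per_section_flags)
  embryo <- flags$embryo
  flags$embryo <- NULL
  if (nrow(flags) < 1L)
    nmp_error("invalid_params", "no scorable sections")
  keep <- vapply(flags, is.logical, logical(1))
  flags <- flags[, keep, drop = FALSE]
  section_pct <- 100 * colSums(flags) / nrow(flags)
  embryo_pct <- NULL
  if (!is.null(embryo)) {
    by_emb <- rowsum((flags) * 1, group = embryo) > 0
    embryo_pct <- 100 * colSums(by_emb) / nrow(by_emb)
  }
  list(section_pct = section_pct, embryo_pct = embryo_pct,
       n_sections = nrow(flags))
}
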