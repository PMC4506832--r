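#' Cochlear duct length from the large diameter of the basal turn
#'
#' Estimates cochlear duct length (CDL) from the cochlea's large diameter
#' `A` using Escude's spiral arc-length relation
#' \deqn{CDL = 2.62 \, A \, \ln(1 + \theta / 235)}
#' where `theta` is the total coil angle in degrees. For a cochlea coiled on
#' 2.75 turns (990 degrees) the ratio CDL/A equals 4.3259.
#'
#' @param diameter_A Large diameter of the cochlea in mm (distance from the
#'   round window through the modiolus to the lateral wall), positive.
#' @param total_angle Total coil angle in degrees; defaults to 990
#'   (2.75 turns).
#' @return Length in mm along the organ of Corti.
#' @examples
#' cdl_from_diameter(8.1)           # ~35.0 mm, an average adult cochlea
#' cdl_from_diameter(1, 990)        # the 4.3259 constant
#' @export
cdl_from_diameter <- function(diameter_A, total_angle = 990) {
  if (!is.numeric(diameter_A) || any(!is.finite(diameter_A)) ||
      any(diameter_A < 0)) {
    stop("'diameter_A' must be a non-negative finite number (mm)")
  }
  if (!is.numeric(total_angle) || any(!is.finite(total_angle)) ||
      any(total_angle <= 0)) {
    stop("'total_angle' must be a positive angle in degrees")
  }
  2.62 * diameter_A * log(1 + total_angle / 235)
}

#' Cochlear geometry specification
#'
#' Bundles a subject's cochlear measurements: the large diameter `A`, the
#' total coil angle, and the derived cochlear duct length.
#'
#' @param diameter_A Large diameter in mm, positive.
#' @param total_angle Total coil angle in degrees (default 990 = 2.75 turns).
#' @return An object of class `"cochlea_spec"`: list with `diameter_A`,
#'   `total_angle`, `cdl`.
#' @export
cochlea_spec <- function(diameter_A, total_angle = 990) {
  if (length(diameter_A) != 1L || !is.numeric(diameter_A) ||
      !is.finite(diameter_A) || diameter_A <= 0) {
    stop("'diameter_A' must be a single positive length in mm")
  }
  if (length(total_angle) != 1L || !is.numeric(total_angle) ||
      !is.finite(total_angle) || total_angle <= 0) {
    stop("'total_angle' must be a single positive angle in degrees")
  }
  structure(
    list(diameter_A = diameter_A, total_angle = total_angle,
         cdl = cdl_from_diameter(diameter_A, total_angle)),
    class = "cochlea_spec"
  )
}

#' @export
print.cochlea_spec <- function(x, ...) {
  cat(sprintf("Cochlea: A = %.2f mm, coil = %.0f deg, CDL = %.2f mm\n",
              x$diameter_A, x$total_angle, x$cdl))
  invisible(x)
}

#' Electrode array geometry registry
#'
#' Contact spacings for the supported Nucleus electrode arrays: perimodiolar
#' (PMA, CI24RE CA Contour Advance), straight (SA, CI24RE ST) and slim
#' straight (SSA, CI422). Spacings are arc distances in mm from electrode 1
#' (the most apical contact) to electrode n, so the first entry is 0.
#'
#' The registry ships with placeholder layouts: 22 contacts uniformly spaced
#' over a nominal contact span per design (PMA 14.0 mm, SA 15.0 mm, SSA
#' 16.0 mm). The spans are placeholders, not manufacturer data: they are
#' the arc lengths the contact run covers along the organ-of-Corti path,
#' chosen to be geometrically consistent with the per-array insertion-angle
#' distributions over the observed range of cochlear sizes (a longer span
#' than the arc of the most apical contact would put basal contacts outside
#' the cochlea). Exact manufacturer spacings can be supplied via a
#' YAML file with one entry per array type:
#' \preformatted{
#' PMA:
#'   n_contacts: 22
#'   span_mm: 15.0          # uniform layout, or
#'   spacings_mm: [0, ...]  # explicit arc distances from electrode 1
#' }
#'
#' @param file Optional path to a YAML registry overriding the defaults.
#' @return Named list (by array type) of lists with `array_type`,
#'   `n_contacts` and `spacings_mm` (non-decreasing, starting at 0).
#' @export
array_registry <- function(file = NULL) {
  defaults <- list(PMA = 14.0, SA = 15.0, SSA = 16.0)
  reg <- lapply(names(defaults), function(a) {
    list(array_type = a, n_contacts = 22L,
         spacings_mm = seq(0, defaults[[a]], length.out = 22L))
  })
  names(reg) <- names(defaults)
  if (!is.null(file)) {
    user <- yaml::read_yaml(file)
    for (a in names(user)) {
      ent <- user[[a]]
      n <- if (!is.null(ent$n_contacts)) as.integer(ent$n_contacts) else 22L
      sp <- if (!is.null(ent$spacings_mm)) {
        as.numeric(ent$spacings_mm)
      } else if (!is.null(ent$span_mm)) {
        seq(0, as.numeric(ent$span_mm), length.out = n)
      } else {
        stop("array '", a, "': need 'spacings_mm' or 'span_mm'")
      }
      if (length(sp) != n || sp[1] != 0 || any(diff(sp) <= 0)) {
        stop("array '", a,
             "': spacings must start at 0 and be strictly increasing")
      }
      reg[[a]] <- list(array_type = a, n_contacts = n, spacings_mm = sp)
    }
  }
  reg
}

#' Relative electrode positions along the cochlear duct
#'
#' Computes, for each contact of an inserted array, its position along the
#' organ of Corti as a fraction of cochlear duct length measured from the
#' round window (base). Electrode 1 is the most apical contact; its arc
#' length from the round window follows from its insertion angle by the same
#' spiral relation used for the CDL, and more basal contacts sit closer to
#' the round window by the manufacturer arc spacings `Y_n`:
#' \deqn{x_{e1} = 2.62 A \ln(1 + \theta_{e1}/235) / CDL, \quad
#'       x_{en} = (2.62 A \ln(1 + \theta_{e1}/235) - Y_n) / CDL.}
#'
#' @param cochlea A [cochlea_spec()] object.
#' @param insertion_angle_e1 Insertion angle of electrode 1 from the round
#'   window, degrees; must lie in (0, total coil angle].
#' @param spacings_Y Numeric vector of arc distances (mm) from electrode 1
#'   to each contact, starting at 0, strictly increasing.
#' @return Numeric vector of fractions in \[0, 1\], one per contact,
#'   strictly decreasing (apical contact deepest).
#' @export
electrode_arc_positions <- function(cochlea, insertion_angle_e1, spacings_Y) {
  stopifnot(inherits(cochlea, "cochlea_spec"))
  if (length(insertion_angle_e1) != 1L || !is.finite(insertion_angle_e1) ||
      insertion_angle_e1 <= 0 || insertion_angle_e1 > cochlea$total_angle) {
    stop("'insertion_angle_e1' must lie in (0, total_angle] degrees")
  }
  if (any(!is.finite(spacings_Y)) || any(spacings_Y < 0)) {
    stop("'spacings_Y' must be non-negative arc distances in mm")
  }
  arc_e1 <- 2.62 * cochlea$diameter_A * log(1 + insertion_angle_e1 / 235)
  if (max(spacings_Y) > arc_e1 + 1e-9) {
    stop("array extends outside the cochlea basally: contact spacing ",
         sprintf("%.2f", max(spacings_Y)),
         " mm exceeds the arc length of electrode 1 (",
         sprintf("%.2f", arc_e1), " mm); check A, insertion angle and Y_n")
  }
  pmin(pmax((arc_e1 - spacings_Y) / cochlea$cdl, 0), 1)
}

#' Organ-of-Corti to spiral-ganglion position map
#'
#' Maps a relative organ-of-Corti position to the relative position of the
#' spiral-ganglion neurons innervating it. The two reference paths have
#' different lengths, so the correspondence is nonlinear; published fits
#' exist but the closed form is device- and study-dependent, and the map is
#' therefore pluggable.
#'
#' Two variants are provided. `"identity"` (the default) passes positions
#' through unchanged. `"printed"` evaluates
#' \deqn{Z = 100\,[1 + (23/x - x/0.0099 + 0.76)^2]^{-1}}
#' on the percent scale and rescales to a fraction; this form is shipped for
#' fidelity to its printed source but is not monotone over (0, 1] and is not
#' recommended for downstream statistics.
#'
#' @param x_en Relative organ-of-Corti position(s), fraction in (0, 1]
#'   (0 allowed for the identity variant).
#' @param variant `"identity"` or `"printed"`.
#' @return Relative spiral-ganglion position(s), fraction in \[0, 1\].
#' @export
oc_to_sg <- function(x_en, variant = c("identity", "printed")) {
  variant <- match.arg(variant)
  if (any(!is.finite(x_en)) || any(x_en < 0) || any(x_en > 1)) {
    stop("'x_en' must be fractions in [0, 1]")
  }
  if (variant == "identity") {
    return(x_en)
  }
  if (any(x_en == 0)) {
    stop("printed OC->SG map is singular at x = 0 (division by zero)")
  }
  z_pct <- 100 / (1 + (23 / x_en - x_en / 0.0099 + 0.76)^2)
  z_pct / 100
}

#' Greenwood place-frequency function
#'
#' Characteristic frequency of spiral-ganglion neurons at a relative
#' position along the cochlea, using the human Greenwood parameters:
#' \deqn{CF(z) = 165.4\,(10^{2.1 z} - 0.88)}
#' with `z` the fraction of spiral-ganglion length measured *from the apex*
#' (z = 0 apex, ~19.8 Hz; z = 1 base, ~20677 Hz). Positions elsewhere in
#' this package are stored as from-base fractions; callers flip with
#' `1 - z` before evaluating (see [map_cohort_cnf()]).
#'
#' @param z_en Fraction(s) in \[0, 1\] of spiral-ganglion length from the
#'   apex.
#' @return Characteristic frequency in Hz, strictly increasing in `z_en`.
#' @export
greenwood_cf <- function(z_en) {
  if (any(!is.finite(z_en)) || any(z_en < 0) || any(z_en > 1)) {
    stop("'z_en' must be fractions in [0, 1] (from the apex)")
  }
  165.4 * (10^(2.1 * z_en) - 0.88)
}

#' Map a cohort table to characteristic neuron frequencies
#'
#' End-to-end tonotopic mapping: for every electrode row, derives the
#' relative organ-of-Corti position from the subject's cochlear diameter,
#' insertion angle and array layout, converts to a spiral-ganglion position,
#' and evaluates the Greenwood function. Positions are computed as from-base
#' fractions; the Greenwood argument is the from-apex complement `1 - z`,
#' so deeper (more apical) contacts map to lower frequencies.
#'
#' @param table Data frame with one row per (subject, electrode) carrying
#'   columns `subject_id`, `array_type`, `diameter_A_mm`,
#'   `insertion_angle_deg`, `electrode` (1 = most apical). An optional
#'   `spacing_Y_mm` column overrides the registry layout.
#' @param sg_map OC-to-SG variant passed to [oc_to_sg()].
#' @param arrays Array geometry registry, see [array_registry()].
#' @param total_angle Total cochlear coil angle in degrees (default 990).
#' @return The input table with columns `x_oc_frac`, `z_sg_frac`, `cnf_hz`
#'   appended (replaced if already present, so the operation is idempotent).
#' @export
map_cohort_cnf <- function(table, sg_map = "identity",
                           arrays = array_registry(), total_angle = 990) {
  need <- c("subject_id", "array_type", "diameter_A_mm",
            "insertion_angle_deg", "electrode")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(as.character(table$array_type)), names(arrays))
  if (length(bad)) {
    stop("unknown array_type '", paste(bad, collapse = "', '"),
         "'; supported types: ", paste(names(arrays), collapse = ", "))
  }
  out <- table
  n <- nrow(table)
  x_frac <- rep(NA_real_, n)
  spacing <- if (!is.null(table$spacing_Y_mm)) {
    as.numeric(table$spacing_Y_mm)
  } else {
    rep(NA_real_, n)
  }
  atype_all <- as.character(table$array_type)
  electrode_all <- as.integer(table$electrode)
  split_idx <- split(seq_len(n),
                     factor(table$subject_id,
                            levels = unique(table$subject_id)))
  for (sid in names(split_idx)) {
    idx <- split_idx[[sid]]
    spec <- arrays[[atype_all[idx[1]]]]
    coch <- cochlea_spec(table$diameter_A_mm[idx[1]], total_angle)
    el <- electrode_all[idx]
    if (any(el < 1L | el > spec$n_contacts)) {
      stop("subject ", sid, ": electrode numbers outside 1..",
           spec$n_contacts)
    }
    if (is.null(table$spacing_Y_mm)) {
      spacing[idx] <- spec$spacings_mm[el]
    }
    x_frac[idx] <- electrode_arc_positions(
      coch, table$insertion_angle_deg[idx[1]], spacing[idx]
    )
  }
  out$spacing_Y_mm <- spacing
  out$x_oc_frac <- x_frac
  out$z_sg_frac <- oc_to_sg(x_frac, variant = sg_map)
  out$cnf_hz <- greenwood_cf(1 - out$z_sg_frac)
  out
}
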