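# Orchestration: per-specimen records, species aggregation, and the
# transformer summary assembled from the default parameter sets.

#' Process one specimen into a flat record of measurements
#'
#' Accepts in-memory objects or file paths.  The mask route computes volume
#' and inertial properties; landmarks add characteristic lengths; patches
#' add stapes-frame measurements.  Density resolution follows the
#' measured-mass convention: an explicit `mass` gives `rho = mass / V`
#' exactly; otherwise `density` must be supplied (typically the species
#' mean mass over mean volume, see [resolve_density()]).
#'
#' @param id specimen identifier (used in error messages).
#' @param ossicle `"malleus"`, `"incus"`, `"stapes"` or `"chain"`.
#' @param mask a `voxel_volume` mask, or a volume file path (segmented with
#'   [segment_window()] defaults when grayscale).
#' @param landmarks a `landmark_set` or landmark file path (optional).
#' @param patches named list of `surface_mesh` patches (`footplate`,
#'   `head`, `isj`) for stapes/incus measurements (optional).
#' @param mass measured mass, mg (optional).
#' @param density density, mg/mm³ (required when `mass` absent).
#' @param spacing_mm spacing override passed to [load_volume()].
#' @return Named list: the `mass_properties` under `$props` and a flat
#'   numeric vector of measurements under `$record`.
#' @export
run_specimen <- function(id, ossicle, mask, landmarks = NULL, patches = NULL,
                         mass = NULL, density = NULL, spacing_mm = NULL) {
  rec <- tryCatch({
    if (is.character(mask)) {
      vol <- load_volume(mask, spacing_mm = spacing_mm)
      mask <- if (is_mask(vol)) vol else segment_window(vol)
    }
    stopifnot(inherits(mask, "voxel_volume"))
    n_vox <- sum(mask$values != 0)
    V <- n_vox * mask$spacing^3
    if (!is.null(mass)) density <- mass / V
    if (is.null(density))
      stop("neither `mass` nor `density` given")
    props <- mass_properties_from_mask(mask, density)
    out <- c(V = props$volume, m = props$mass, rho = props$density,
             I_MIN = props$principal_moments[1],
             I_MED = props$principal_moments[2],
             I_MAX = props$principal_moments[3])
    if (!is.null(landmarks)) {
      if (is.character(landmarks)) landmarks <- load_landmarks(landmarks)
      if (ossicle %in% c("malleus", "incus"))
        out <- c(out, characteristic_lengths(landmarks, ossicle,
                                             com = props$com))
      if (ossicle %in% c("malleus", "chain") &&
          !is.null(landmarks$points$anterior_process) &&
          !is.null(landmarks$points$short_process_tip) &&
          !is.null(landmarks$points$isj_centroid)) {
        hx <- hinge_axis(get_landmark(landmarks, "anterior_process"),
                         get_landmark(landmarks, "short_process_tip"))
        lev <- lever_geometry(hx, get_landmark(landmarks, "umbo_tip"),
                              get_landmark(landmarks, "isj_centroid"),
                              com = props$com)
        out <- c(out, L1 = lev$L1, L2 = lev$L2, lever_ratio = lev$ratio,
                 d_axis_com = lev$d_axis_com)
      }
    }
    if (!is.null(patches$footplate) && !is.null(patches$head)) {
      sf <- stapes_frame(patches$footplate, patches$head, com = props$com)
      out <- c(out, a = sf$a, b = sf$b, a_over_b = sf$a_over_b, h = sf$h,
               A_FT = sf$A_FT, A_FTproj = sf$A_FTproj,
               A_FTproj_over_A_FT = sf$A_FTproj / sf$A_FT,
               d_FT_eq = sf$d_FT_eq, d_FTproj_eq = sf$d_FTproj_eq,
               h_c = sf$h_c, h_c_over_h = sf$h_c_over_h)
    }
    if (!is.null(patches$isj)) {
      p <- patch_area_centroid(patches$isj)
      out <- c(out, A_ISJ = p$area)
    }
    list(props = props, record = out)
  }, error = function(e)
    stop("specimen '", id, "': ", conditionMessage(e), call. = FALSE))
  rec$id <- id
  rec$ossicle <- ossicle
  rec
}

#' Species average density from mean mass and mean volume
#'
#' The measured-mass convention: average density = mean mass / mean volume
#' (not the mean of per-specimen densities), reflecting masses weighed on a
#' subset of specimens.
#'
#' @param masses measured masses, mg (possibly fewer than volumes).
#' @param volumes specimen volumes, mm³.
#' @return Density, mg/mm³.
#' @export
resolve_density <- function(masses, volumes) {
  if (!length(masses) || !length(volumes)) stop("empty mass or volume set")
  mean(masses) / mean(volumes)
}

#' Aggregate specimen records into a mean ± SD summary
#'
#' Quantities that are per-specimen ratios are averaged as the mean of
#' ratios (matching per-sample ± SD reporting); the ratio of group means is
#' reported alongside for every quantity pair requested.
#'
#' @param records list of outputs of [run_specimen()], or a data.frame with
#'   one row per specimen.
#' @param group optional character vector assigning each record to a group
#'   (e.g. species); one summary per group.
#' @return data.frame with columns `group`, `quantity`, `mean`, `sd`, `n`.
#' @export
aggregate_records <- function(records, group = NULL) {
  df <- if (is.data.frame(records)) records else
    do.call(rbind, lapply(records, function(r)
      as.data.frame(as.list(r$record))))
  if (nrow(df) == 0L) stop("no records to aggregate")
  if (is.null(group)) group <- rep("all", nrow(df))
  if (length(group) != nrow(df)) stop("`group` length mismatch")
  out <- do.call(rbind, lapply(split(seq_len(nrow(df)), group), function(ix) {
    sub <- df[ix, , drop = FALSE]
    do.call(rbind, lapply(names(sub), function(q) {
      v <- sub[[q]]
      if (!is.numeric(v)) return(NULL)
      data.frame(group = group[ix[1]], quantity = q,
                 mean = mean(v, na.rm = TRUE),
                 sd = if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE)
                      else 0,
                 n = sum(!is.na(v)), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Cross-species ratio column from an aggregated summary
#'
#' @param summary output of [aggregate_records()].
#' @param numerator,denominator group labels (e.g. `"sheep"`, `"human"`).
#' @return data.frame `quantity`, `ratio` = mean(numerator)/mean(denominator).
#' @export
species_ratio <- function(summary, numerator, denominator) {
  a <- summary[summary$group == numerator, c("quantity", "mean")]
  b <- summary[summary$group == denominator, c("quantity", "mean")]
  m <- merge(a, b, by = "quantity", suffixes = c("_num", "_den"))
  data.frame(quantity = m$quantity, ratio = m$mean_num / m$mean_den,
             stringsAsFactors = FALSE)
}

#' One-call transformer comparison with the default species parameters
#'
#' Emits the impedance-matching summary for the default sheep/human
#' parameter sets (areas, lever ratios, cochlear and air impedances):
#' area ratio, pressure gain, the lever ratio in dB, the tympanic-membrane
#' impedance and the transmitted-energy fraction per species.
#'
#' @param params parameter data.frame (default [default_species_params()]).
#' @param out optional CSV path to write the table to.
#' @return The [species_report()] data.frame, invisibly if `out` is given.
#' @export
reproduce_discussion <- function(params = default_species_params(),
                                 out = NULL) {
  tab <- species_report(params)
  if (!is.null(out)) {
    utils::write.csv(tab, out, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
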