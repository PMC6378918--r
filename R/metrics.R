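#' Relative difference measure star (RDMS)
#'
#' Distance between the unit-normalised true and reconstructed potential
#' patterns: `sqrt(sum((x/||x|| - xhat/||xhat||)^2))`, bounded in
#' `[0, 2]`, zero iff the vectors are positive multiples of each other,
#' 2 for antipodal patterns. Lower is better. Setting
#' `take_root = FALSE` gives the squared variant (the same quantity
#' without the final square root) for comparison.
#'
#' @param x,x_hat numeric vectors of equal length, both non-zero.
#' @param take_root apply the final square root (default `TRUE`, the
#'   conventional definition).
#' @return scalar error score.
#' @export
rdms <- function(x, x_hat, take_root = TRUE) {
  if (length(x) != length(x_hat)) stop("length mismatch")
  nx <- sqrt(sum(x^2)); nh <- sqrt(sum(x_hat^2))
  if (nx == 0 || nh == 0) stop("RDMS undefined for a zero-norm input")
  s <- sum((x / nx - x_hat / nh)^2)
  if (take_root) sqrt(s) else s
}

#' RDMS summary over a field pair
#'
#' Spatial mode computes one RDMS per timestep over the nodes (the
#' standard reported quantity, summarised as mean and standard deviation
#' across timesteps); temporal mode computes one RDMS per node over its
#' time course. Zero-norm columns/rows are flagged, excluded, and
#' counted with a warning.
#'
#' @param x,x_hat `ecgi_field`s (or plain matrices) of matching shape.
#' @param mode `"spatial"` or `"temporal"`.
#' @param take_root see [rdms()].
#' @return list of class `ecgi_rdms` with `per_value` (vector),
#'   `mean`, `sd`, `mode`, `n_excluded`.
#' @export
rdms_summary <- function(x, x_hat, mode = c("spatial", "temporal"),
                         take_root = TRUE) {
  mode <- match.arg(mode)
  xm <- if (inherits(x, "ecgi_field")) x$values else as.matrix(x)
  hm <- if (inherits(x_hat, "ecgi_field")) x_hat$values else as.matrix(x_hat)
  if (!all(dim(xm) == dim(hm))) stop("field shapes differ")
  if (mode == "temporal") { xm <- t(xm); hm <- t(hm) }
  ok <- colSums(xm^2) > 0 & colSums(hm^2) > 0
  if (!all(ok))
    warning(sum(!ok), " zero-norm ", if (mode == "spatial") "timestep(s)"
            else "node trace(s)", " excluded from RDMS")
  vals <- rep(NA_real_, ncol(xm))
  vals[ok] <- vapply(which(ok), function(j) rdms(xm[, j], hm[, j], take_root),
                     numeric(1))
  structure(list(per_value = vals, mean = mean(vals[ok]),
                 sd = stats::sd(vals[ok]), mode = mode,
                 n_excluded = sum(!ok)),
            class = "ecgi_rdms")
}

#' @export
print.ecgi_rdms <- function(x, ...) {
  cat(sprintf("RDMS (%s): mean %.4f +/- %.4f over %d values\n",
              x$mode, x$mean, x$sd, sum(!is.na(x$per_value))))
  invisible(x)
}

#' Ischemia detection threshold
#'
#' `w_threshold = w_bar - Q (w_bar - w_min)` where `w_bar` is the mean
#' and `w_min` the minimum epicardial potential at the detection
#' timestep; elements strictly below the threshold are classified
#' ischemic. A larger `Q` lowers the threshold and shrinks the detected
#' area.
#'
#' @param w vector of epicardial node potentials at one timestep (mV).
#' @param q threshold factor (typical 0.3-0.5; study default 0.4).
#' @return threshold in mV.
#' @export
detection_threshold <- function(w, q) {
  if (!length(w)) stop("empty potential vector")
  wbar <- mean(w)
  wbar - q * (wbar - min(w))
}

#' Detect ischemic elements by thresholding
#'
#' Face potential is the unweighted mean of its three vertex potentials
#' at the detection timestep; a face is classified ischemic iff its
#' potential is strictly below the [detection_threshold()] computed from
#' the node potentials at that timestep (ties count as healthy).
#'
#' @param field heart `ecgi_field`.
#' @param heart heart [ecgi_mesh].
#' @param q threshold factor.
#' @param t_detect detection time (ms); snapped to the nearest timestep.
#' @return logical vector, one entry per face.
#' @export
detect_ischemia <- function(field, heart, q = 0.4, t_detect) {
  times <- field_times(field)
  if (t_detect < min(times) - field$dt / 2 || t_detect > max(times) + field$dt / 2)
    stop("t_detect outside the field timeline")
  j <- which.min(abs(times - t_detect))
  w <- field$values[, j]
  thr <- detection_threshold(w, q)
  f <- heart$faces
  face_pot <- (w[f[, 1]] + w[f[, 2]] + w[f[, 3]]) / 3
  face_pot < thr
}

#' Timestep of maximal epicardial contrast
#'
#' Returns the time at which `mean(w) - min(w)` — the contrast between
#' the depressed ischemic region and the surrounding tissue — peaks,
#' optionally restricted to a window (e.g. the plateau phase, after the
#' whole surface has activated and before repolarisation completes).
#'
#' @param field heart `ecgi_field`.
#' @param t_min,t_max window bounds in ms.
#' @return time in ms.
#' @export
peak_contrast_time <- function(field, t_min = -Inf, t_max = Inf) {
  times <- field_times(field)
  inside <- times >= t_min & times <= t_max
  if (!any(inside)) stop("empty detection window")
  contrast <- colMeans(field$values) - apply(field$values, 2, min)
  times[inside][which.max(contrast[inside])]
}

#' Real lesion face mask
#'
#' A face is "real ischemic" iff its centroid lies within the lesion
#' radius of the lesion centre (matching the Euclidean node rule of
#' [lesion_zones()]).
#'
#' @param heart heart [ecgi_mesh].
#' @param lesion an [lesion_spec()].
#' @return logical vector per face.
#' @export
real_lesion_faces <- function(heart, lesion) {
  cent <- face_centroids(heart)
  sqrt(rowSums(sweep(cent, 2, lesion$centre)^2)) <= lesion$radius
}

#' Traffic-light lesion detection scores
#'
#' Area-based classification of the detection outcome, each expressed as
#' a percentage of the real lesion area: CI (correctly ischemic,
#' detected and real), IH (incorrectly healthy, real but missed) and II
#' (incorrectly ischemic, detected outside the real lesion; may exceed
#' 100% under gross over-detection). CI + IH = 100 by construction.
#'
#' @param real_mask,detected_mask logical per-face masks.
#' @param heart heart [ecgi_mesh] (areas are summed triangle areas).
#' @param reference_area optional lesion area (mm^2) to normalise by
#'   instead of the real mask's own area (used when comparing lesion
#'   sizes against a common reference).
#' @return named numeric vector `c(ci_pct, ih_pct, ii_pct)`.
#' @export
traffic_light <- function(real_mask, detected_mask, heart,
                          reference_area = NULL) {
  if (length(real_mask) != length(detected_mask))
    stop("mask lengths differ")
  a <- face_areas(heart)
  area_real <- sum(a[real_mask])
  if (area_real <= 0) stop("empty real lesion")
  ref <- reference_area %||% area_real
  c(ci_pct = 100 * sum(a[real_mask & detected_mask]) / area_real,
    ih_pct = 100 * sum(a[real_mask & !detected_mask]) / area_real,
    ii_pct = 100 * sum(a[!real_mask & detected_mask]) / ref)
}

#' Per-face traffic-light labels
#'
#' Label file for visualisation: 0 = true negative, 1 = correctly
#' ischemic, 2 = incorrectly healthy, 3 = incorrectly ischemic.
#' @inheritParams traffic_light
#' @return integer vector per face.
#' @export
traffic_light_labels <- function(real_mask, detected_mask) {
  ifelse(real_mask & detected_mask, 1L,
         ifelse(real_mask & !detected_mask, 2L,
                ifelse(detected_mask, 3L, 0L)))
}
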