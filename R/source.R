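#' Potential field on a mesh
#'
#' Node-by-time matrix of electric potentials (mV) with a uniform time
#' step, the common currency of the simulation and inversion stages.
#'
#' @param values numeric matrix, nodes x timesteps (mV).
#' @param dt time step (ms), > 0.
#' @param t0 time of the first column (ms).
#' @param role which surface the field lives on (`"heart"`/`"torso"`).
#' @return object of class `ecgi_field`.
#' @export
potential_field <- function(values, dt = 1, t0 = 0, role = "generic") {
  values <- as.matrix(values)
  if (ncol(values) < 1) stop("field needs at least one timestep")
  if (dt <= 0) stop("dt must be positive")
  if (any(!is.finite(values))) stop("non-finite potential values")
  structure(list(values = values, dt = dt, t0 = t0, role = role),
            class = "ecgi_field")
}

#' @export
print.ecgi_field <- function(x, ...) {
  cat(sprintf("ecgi_field (%s): %d nodes x %d timesteps, dt = %g ms, t0 = %g ms\n",
              x$role, nrow(x$values), ncol(x$values), x$dt, x$t0))
  cat(sprintf("  range: [%.2f, %.2f] mV\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Field timeline
#' @param field an `ecgi_field`.
#' @return vector of column times (ms).
#' @export
field_times <- function(field) field$t0 + field$dt * (seq_len(ncol(field$values)) - 1L)

#' Action potential template
#'
#' Phenomenological ventricular action potential summarised by four
#' parameters. Healthy defaults: resting -85 mV, peak +20 mV (typical
#' ventricular values), APD at 90% repolarisation 274 ms, upstroke 2 ms.
#'
#' @param resting_potential resting (diastolic) potential, mV.
#' @param peak_potential potential reached at the end of the upstroke, mV.
#' @param apd action potential duration at 90% repolarisation, ms.
#' @param upstroke_duration depolarisation upstroke duration, ms.
#' @return object of class `ecgi_ap_template`.
#' @export
ap_template <- function(resting_potential = -85, peak_potential = 20,
                        apd = 274, upstroke_duration = 2) {
  if (peak_potential <= resting_potential) stop("peak must exceed resting")
  if (!(apd > upstroke_duration && upstroke_duration > 0))
    stop("need apd > upstroke_duration > 0")
  structure(list(resting_potential = resting_potential,
                 peak_potential = peak_potential,
                 apd = apd, upstroke_duration = upstroke_duration),
            class = "ecgi_ap_template")
}

#' Ischemic remodelling of an action potential template
#'
#' Linear interpolation between the healthy template and the
#' fully-remodelled central-ischemic phenotype as a function of the
#' lesion ramp weight `w` in `[0, 1]`: resting potential depolarised by
#' `18 * w` mV, APD shortened from 274 towards 150 ms, upstroke slowed by
#' a factor `1 + 2 w` (a three-fold slowing at full weight), and the
#' plateau/peak amplitude depressed by `25 * w` mV so the lesion sits
#' below the surrounding healthy potential during the plateau.
#'
#' @param healthy healthy [ap_template()].
#' @param weight remodelling weight in `[0,1]` (vectorised).
#' @param resting_shift,apd_central,peak_drop,upstroke_factor remodelling
#'   magnitudes at full weight.
#' @return list of per-element parameter vectors (`resting`, `peak`,
#'   `apd`, `upstroke`).
#' @export
ischemic_parameters <- function(healthy = ap_template(), weight,
                                resting_shift = 18, apd_central = 150,
                                peak_drop = 25, upstroke_factor = 3) {
  w <- pmin(pmax(weight, 0), 1)
  list(resting = healthy$resting_potential + resting_shift * w,
       peak = healthy$peak_potential - peak_drop * w,
       apd = healthy$apd + (apd_central - healthy$apd) * w,
       upstroke = healthy$upstroke_duration * (1 + (upstroke_factor - 1) * w))
}

#' Action potential waveform
#'
#' Evaluates the template waveform at times since local activation:
#' resting before activation, a smooth monotone upstroke reaching the
#' peak at `upstroke_duration`, a plateau with mild linear decay and a
#' sigmoidal repolarisation calibrated so the 90% repolarisation
#' crossing falls exactly at `apd`.
#'
#' @param template an [ap_template()].
#' @param t_since_activation time(s) since activation, ms (may be < 0).
#' @return potential(s) in mV, same length as `t_since_activation`.
#' @export
ap_waveform <- function(template, t_since_activation) {
  with(template, {
    ap_shape(t_since_activation, upstroke_duration, apd) *
      (peak_potential - resting_potential) + resting_potential
  })
}

## normalised AP shape in [0,1]; vectorised over t (and over parameters of
## matching shape, used by epicardial_field)
ap_shape <- function(t, upstroke, apd) {
  up <- ifelse(t <= 0, 0, ifelse(t >= upstroke, 1, sin(pi * t / (2 * upstroke))^2))
  plateau <- pmax(1 - 0.1 * pmax(t, 0) / apd, 0)
  w_rep <- apd / 20
  t90 <- apd - w_rep * log(8)   # so plateau(apd) * sigmoid(apd) = 0.10
  rep_s <- 1 / (1 + exp(pmin((t - t90) / w_rep, 700)))
  up * plateau * rep_s
}

#' Activation map from pacing sites
#'
#' Activation time at each heart node is the graph-geodesic distance
#' (along mesh edges, Euclidean edge lengths) to the nearest pacing node
#' divided by the conduction velocity; pacing nodes activate at time 0.
#'
#' @param heart heart [ecgi_mesh].
#' @param pacing_nodes non-empty vector of 1-based node indices.
#' @param conduction_velocity effective surface conduction velocity,
#'   mm/ms (default 0.8, an effective Purkinje-coupled spread rate).
#' @return object of class `ecgi_activation`: numeric vector of
#'   activation times (ms) per node.
#' @export
activation_map <- function(heart, pacing_nodes, conduction_velocity = 0.8) {
  if (length(pacing_nodes) == 0) stop("pacing node set is empty")
  if (conduction_velocity <= 0) stop("conduction velocity must be positive")
  g <- mesh_graph(heart)
  d <- igraph::distances(g, v = pacing_nodes)
  tact <- apply(d, 2, min) / conduction_velocity
  if (any(!is.finite(tact))) stop("disconnected heart mesh")
  structure(as.numeric(tact), class = "ecgi_activation")
}

#' Nearest mesh node to a point
#' @param mesh an [ecgi_mesh].
#' @param point length-3 coordinate (mm).
#' @return 1-based node index.
#' @export
nearest_node <- function(mesh, point) {
  which.min(rowSums(sweep(mesh$vertices, 2, point)^2))
}

#' Default pacing sites for the phantom ventricle
#'
#' Three sites emulating early endocardial breakthrough: the apex and
#' two opposed mid-wall points, taken as the mesh nodes nearest to fixed
#' directions on the surface. Chosen so the full surface activates
#' within roughly 100 ms at the default conduction velocity.
#'
#' @param heart heart [ecgi_mesh].
#' @return integer vector of 3 node indices.
#' @export
default_pacing_sites <- function(heart) {
  ctr <- colMeans(heart$vertices)
  half <- apply(heart$vertices, 2, function(x) diff(range(x))) / 2
  dirs <- rbind(c(0, 0, -1), c(0.9, -0.4, 0.3), c(-0.9, 0.4, 0.3))
  unique(vapply(seq_len(nrow(dirs)), function(i) {
    d <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    nearest_node(heart, ctr + half * d)
  }, integer(1)))
}

#' Simulated epicardial potential field
#'
#' Evaluates per-node action potentials on the timeline: each node's
#' trace is the template waveform shifted by its activation time, with
#' template parameters linearly interpolated (by the lesion ramp weight)
#' between the healthy and central-ischemic phenotypes. With no lesion
#' all traces are identical up to the activation-time shift.
#'
#' @param heart heart [ecgi_mesh].
#' @param lesion an [lesion_spec()] or `NULL`.
#' @param activation an [activation_map()] result.
#' @param timeline list with `t0`, `dt` (ms) and `n_steps`; default
#'   0/1/400, covering one full beat over 400 ms.
#' @param healthy healthy [ap_template()].
#' @param ... remodelling magnitudes passed to [ischemic_parameters()].
#' @return an `ecgi_field` on the heart.
#' @export
epicardial_field <- function(heart, lesion, activation,
                             timeline = list(t0 = 0, dt = 1, n_steps = 400),
                             healthy = ap_template(), ...) {
  n <- nrow(heart$vertices)
  stopifnot(length(activation) == n)
  times <- timeline$t0 + timeline$dt * (seq_len(timeline$n_steps) - 1L)
  if (diff(range(times)) < healthy$apd)
    warning("timeline shorter than one action potential duration")
  if (max(times) < max(activation) + healthy$apd)
    warning("timeline ends before the last node completes its action potential")
  w <- lesion_zones(heart, lesion)$weight
  pars <- ischemic_parameters(healthy, w, ...)
  ## ts[node, step] = time since local activation; per-node parameter
  ## vectors recycle down columns of the node x time matrix
  ts <- outer(-as.numeric(activation), times, `+`)
  shape <- ap_shape(ts, pars$upstroke, pars$apd)
  vals <- shape * (pars$peak - pars$resting) + pars$resting
  potential_field(vals, dt = timeline$dt, t0 = timeline$t0, role = "heart")
}

#' Add Gaussian measurement noise at a target SNR
#'
#' Adds zero-mean Gaussian noise with variance `P / 10^(snr_db/10)`,
#' where `P` is the mean squared signal value over all nodes and
#' timesteps (global SNR convention). Deterministic for a fixed seed.
#'
#' @param field an `ecgi_field`.
#' @param snr_db target signal-to-noise ratio in dB.
#' @param seed integer RNG seed.
#' @return noisy `ecgi_field`; `snr_db = Inf` returns the input.
#' @export
add_gaussian_noise <- function(field, snr_db, seed) {
  if (is.infinite(snr_db) && snr_db > 0) return(field)
  if (!is.finite(snr_db)) stop("snr_db must be finite (or +Inf for none)")
  p_sig <- mean(field$values^2)
  if (p_sig == 0) stop("all-zero field: SNR undefined")
  set.seed(as.integer(seed))
  sd_noise <- sqrt(p_sig / 10^(snr_db / 10))
  noisy <- field$values + matrix(stats::rnorm(length(field$values), sd = sd_noise),
                                 nrow(field$values), ncol(field$values))
  potential_field(noisy, field$dt, field$t0, field$role)
}

#' Write / read potential fields as delimited text
#'
#' The matrix (rows = nodes, columns = timesteps) is written
#' tab-separated; a sidecar file `<path>.meta` holds `dt`, `t0` and the
#' surface role.
#'
#' @param field an `ecgi_field`.
#' @param path file path for the matrix.
#' @return `path` / an `ecgi_field`.
#' @export
write_field <- function(field, path) {
  utils::write.table(field$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  writeLines(c(paste("dt", field$dt), paste("t0", field$t0),
               paste("role", field$role)), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(vals) <- NULL
  meta <- strsplit(readLines(paste0(path, ".meta")), " ")
  kv <- stats::setNames(vapply(meta, `[[`, "", 2), vapply(meta, `[[`, "", 1))
  potential_field(vals, dt = as.numeric(kv[["dt"]]), t0 = as.numeric(kv[["t0"]]),
                  role = kv[["role"]])
}
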