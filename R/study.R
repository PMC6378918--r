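#' Named lesion sites on the phantom ventricle
#'
#' Surface points emulating the anatomical lesion locations of interest:
#' right-ventricle lateral wall (`RV_LAT`, the primary site), left
#' ventricle anterior / lateral / posterior walls (`LV_ANT`, `LV_LAT`,
#' `LV_POS`) and a septal proxy (`SEPTAL`) — a medial, posterior-inferior
#' site facing away from the chest wall, standing in for the
#' interventricular septum which a single closed surface cannot host.
#' Coordinate convention: +x left, -y anterior, +z superior.
#'
#' @param heart_semiaxes,heart_offset phantom ventricle geometry (mm).
#' @return named list of length-3 surface points (mm).
#' @export
lesion_sites <- function(heart_semiaxes = c(45, 40, 70),
                         heart_offset = c(40, -35, 60)) {
  dirs <- list(
    RV_LAT = c(-0.9, -0.4, 0),
    LV_ANT = c(0.2, -1, 0.1),
    LV_LAT = c(1, 0, 0),
    LV_POS = c(0.2, 1, 0),
    SEPTAL = c(-0.5, 0.45, -0.74))
  lapply(dirs, function(d) {
    u <- d / sqrt(sum(d^2))
    heart_offset + heart_semiaxes * u
  })
}

#' Study configuration
#'
#' One factorial sweep of the six experimental variables: Tikhonov
#' order, electrode count, lesion location, lesion radius, noise level
#' (SNR in dB; `Inf` = noiseless) and detection threshold factor Q
#' (applied at the scoring stage, so all Q values are evaluated on every
#' reconstruction). Noiseless cells are deterministic and run once;
#' noisy cells run once per seed.
#'
#' @param orders subset of `c(0, 1, 2)`.
#' @param lead_counts electrode counts (study defaults 32...1024).
#' @param lesion_locations names from [lesion_sites()].
#' @param lesion_radii radii in mm (paper-style defaults 27, 20, 14, 8).
#' @param snr_dbs SNRs in dB, `Inf` for noiseless.
#' @param q_factors threshold factors.
#' @param seeds distinct integer seeds for the noise realisations.
#' @param timeline simulation timeline (`t0`, `dt` in ms, `n_steps`).
#' @param conduction_velocity activation spread velocity (mm/ms).
#' @param heart_frequency,torso_frequency phantom mesh resolutions.
#' @return list of class `ecgi_study_config`.
#' @export
study_config <- function(orders = c(0, 1, 2),
                         lead_counts = c(32, 64, 128, 256, 512, 1024),
                         lesion_locations = "RV_LAT",
                         lesion_radii = 27,
                         snr_dbs = Inf,
                         q_factors = c(0.3, 0.4, 0.5),
                         seeds = c(101, 211, 307, 401, 503),
                         timeline = list(t0 = 0, dt = 1, n_steps = 400),
                         conduction_velocity = 0.8,
                         heart_frequency = 10L, torso_frequency = 16L) {
  stopifnot(length(orders) > 0, length(lead_counts) > 0,
            length(lesion_locations) > 0, length(lesion_radii) > 0,
            length(snr_dbs) > 0, length(q_factors) > 0, length(seeds) > 0)
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  structure(list(orders = orders, lead_counts = lead_counts,
                 lesion_locations = lesion_locations,
                 lesion_radii = lesion_radii, snr_dbs = snr_dbs,
                 q_factors = q_factors, seeds = seeds, timeline = timeline,
                 conduction_velocity = conduction_velocity,
                 heart_frequency = heart_frequency,
                 torso_frequency = torso_frequency),
            class = "ecgi_study_config")
}

#' Shared study context
#'
#' Builds (once) everything in the pipeline that does not depend on the
#' sweep cell: the phantom meshes, the BEM transfer matrix, the
#' activation map, and lazy caches of Tikhonov operators per order,
#' electrode layouts / interpolation operators per lead count, and
#' ground-truth epicardial fields and body-surface potentials per
#' lesion. Pass the same context to several [run_study()] calls to
#' amortise the geometry and factorisation cost.
#'
#' @param config an [study_config()].
#' @param progress print stage messages to stderr.
#' @return an environment of class `ecgi_study_context`.
#' @export
study_context <- function(config, progress = FALSE) {
  say <- function(...) if (progress) message(...)
  ctx <- new.env(parent = emptyenv())
  ctx$config <- config
  say("building phantom meshes ...")
  ph <- torso_ventricle_phantom(heart_frequency = config$heart_frequency,
                                torso_frequency = config$torso_frequency)
  ctx$heart <- ph$heart; ctx$torso <- ph$torso
  say("assembling BEM transfer matrix ...")
  ctx$A <- assemble_transfer(ctx$torso, ctx$heart)
  say("activation map ...")
  ctx$activation <- activation_map(ctx$heart, default_pacing_sites(ctx$heart),
                                   config$conduction_velocity)
  ctx$sites <- lesion_sites()
  ctx$operators <- list(); ctx$layouts <- list(); ctx$interp <- list()
  ctx$truth <- list()
  ctx$get_operator <- function(order) {
    key <- as.character(order)
    if (is.null(ctx$operators[[key]])) {
      say("factorising order-", order, " Tikhonov operator ...")
      ctx$operators[[key]] <- tikhonov_operator(ctx$A, regularizer(order, ctx$heart))
    }
    ctx$operators[[key]]
  }
  ctx$get_layout <- function(n) {
    key <- as.character(n)
    if (is.null(ctx$layouts[[key]]))
      ctx$layouts[[key]] <- electrode_grid(ctx$torso, n)
    ctx$layouts[[key]]
  }
  ctx$get_interp <- function(n) {
    key <- as.character(n)
    if (is.null(ctx$interp[[key]])) {
      say("interpolation operator for ", n, " leads ...")
      ctx$interp[[key]] <- interpolation_operator(ctx$torso, ctx$get_layout(n))
    }
    ctx$interp[[key]]
  }
  ctx$get_truth <- function(location, radius) {
    key <- paste(location, radius)
    if (is.null(ctx$truth[[key]])) {
      say("ground truth for lesion ", key, " mm ...")
      lesion <- lesion_spec(ctx$sites[[location]], radius)
      field <- epicardial_field(ctx$heart, lesion, ctx$activation,
                                ctx$config$timeline)
      bsp <- forward_bsp(ctx$A, field)
      ## detection time: peak lesion contrast during the plateau, i.e.
      ## after the whole surface has depolarised
      t_full <- max(ctx$activation) + 10
      t_det <- peak_contrast_time(field, t_min = t_full, t_max = 260)
      ctx$truth[[key]] <- list(lesion = lesion, field = field, bsp = bsp,
                               t_detect = t_det,
                               real_mask = real_lesion_faces(ctx$heart, lesion))
    }
    ctx$truth[[key]]
  }
  class(ctx) <- c("ecgi_study_context", "environment")
  ctx
}

#' Run a factorial ECGI study
#'
#' Sweeps the full factorial of the configuration lists; each cell runs
#' the complete pipeline — simulate epicardial source, forward-project,
#' add noise, sample electrodes, interpolate the body-surface map,
#' invert (global-lambda Tikhonov), and score RDMS and lesion detection
#' at every Q factor. Cell failures are recorded in the `error` column
#' and the sweep continues.
#'
#' @param config an [study_config()].
#' @param context optional shared [study_context()] (built if omitted).
#' @param progress print progress to stderr.
#' @return data frame of class `ecgi_study`, one row per cell x seed x Q.
#' @export
run_study <- function(config, context = NULL, progress = FALSE) {
  ctx <- context %||% study_context(config, progress = progress)
  say <- function(...) if (progress) message(...)
  cells <- expand.grid(order = config$orders, n_leads = config$lead_counts,
                       location = config$lesion_locations,
                       radius = config$lesion_radii, snr_db = config$snr_dbs,
                       stringsAsFactors = FALSE)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    seeds <- if (is.infinite(cell$snr_db)) config$seeds[1] else config$seeds
    for (seed in seeds) {
      say(sprintf("cell %d/%d: order %d, %d leads, %s r=%g, SNR %s, seed %d",
                  ci, nrow(cells), cell$order, cell$n_leads, cell$location,
                  cell$radius, format(cell$snr_db), seed))
      res <- tryCatch(
        run_cell(ctx, cell$order, cell$n_leads, cell$location, cell$radius,
                 cell$snr_db, seed, config$q_factors),
        error = function(e) {
          data.frame(order = cell$order, n_leads = cell$n_leads,
                     location = cell$location, radius_mm = cell$radius,
                     snr_db = cell$snr_db, seed = seed, q = NA_real_,
                     lambda = NA_real_, rdms_mean = NA_real_,
                     rdms_sd = NA_real_, ci_pct = NA_real_, ih_pct = NA_real_,
                     ii_pct = NA_real_, detected_area_pct = NA_real_,
                     t_detect_ms = NA_real_, converged = NA,
                     error = conditionMessage(e), stringsAsFactors = FALSE)
        })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ecgi_study", "data.frame")
  out
}

run_cell <- function(ctx, order, n_leads, location, radius, snr_db, seed,
                     q_factors) {
  truth <- ctx$get_truth(location, radius)
  bsp <- add_gaussian_noise(truth$bsp, snr_db, seed)
  layout <- ctx$get_layout(n_leads)
  leads <- sample_leads(bsp, layout)
  K <- interpolate_full_bsp(leads, layout, ctx$torso, op = ctx$get_interp(n_leads))
  fit <- ecgi_reconstruct(ctx$A, K, reg_config(order = order),
                          heart = ctx$heart,
                          operator = ctx$get_operator(order))
  err <- rdms_summary(truth$field, fit$reconstructed, "spatial")
  do.call(rbind, lapply(q_factors, function(q) {
    det <- detect_ischemia(fit$reconstructed, ctx$heart, q, truth$t_detect)
    tl <- traffic_light(truth$real_mask, det, ctx$heart)
    data.frame(order = order, n_leads = n_leads, location = location,
               radius_mm = radius, snr_db = snr_db, seed = seed, q = q,
               lambda = fit$lambda_used[1], rdms_mean = err$mean,
               rdms_sd = err$sd, ci_pct = tl[["ci_pct"]],
               ih_pct = tl[["ih_pct"]], ii_pct = tl[["ii_pct"]],
               detected_area_pct = tl[["ci_pct"]] + tl[["ii_pct"]],
               t_detect_ms = truth$t_detect, converged = isTRUE(fit$converged),
               error = NA_character_, stringsAsFactors = FALSE)
  }))
}

#' Default study: the paper-style one-factor-at-a-time sweeps
#'
#' Four sweeps sharing one phantom and transfer matrix, mirroring the
#' study structure: (1) the main order-by-lead-count sweep on the
#' primary right-ventricle lateral lesion (27 mm); (2) a noise sweep
#' (order 2, 512 leads, anterior lesion, SNR 10-40 dB plus noiseless);
#' (3) a lesion-size sweep (order 2, 512 leads, radii 20, 14 and 8 mm);
#' (4) a location sweep over the remaining sites. Sweeps (1), (3) and
#' (4) run at 30 dB SNR — a representative mid-range measurement-noise
#' level — with one realisation per seed, so that every summary can be
#' taken as a median over the five seeds; all Q factors are scored on
#' every reconstruction.
#'
#' @param seeds noise seeds (default the package's five fixed seeds).
#' @param snr_db measurement-noise level of the factor sweeps (dB).
#' @param context optional prebuilt [study_context()].
#' @param progress print progress to stderr.
#' @return an `ecgi_study` data frame with a `sweep` column.
#' @export
run_default_study <- function(seeds = c(101, 211, 307, 401, 503),
                              snr_db = 30, context = NULL, progress = FALSE) {
  base <- study_config(seeds = seeds)
  ctx <- context %||% study_context(base, progress = progress)
  sweeps <- list(
    main = study_config(snr_dbs = snr_db, seeds = seeds),
    noise = study_config(orders = 2, lead_counts = 512,
                         lesion_locations = "LV_ANT",
                         snr_dbs = c(Inf, 10, 20, 30, 40), seeds = seeds),
    size = study_config(orders = 2, lead_counts = 512,
                        lesion_radii = c(20, 14, 8), snr_dbs = snr_db,
                        seeds = seeds),
    location = study_config(orders = 2, lead_counts = 512,
                            lesion_locations = c("LV_ANT", "LV_LAT",
                                                 "LV_POS", "SEPTAL"),
                            snr_dbs = snr_db, seeds = seeds))
  out <- do.call(rbind, lapply(names(sweeps), function(nm) {
    df <- run_study(sweeps[[nm]], context = ctx, progress = progress)
    df$sweep <- nm
    df
  }))
  class(out) <- c("ecgi_study", "data.frame")
  out
}

#' @export
print.ecgi_study <- function(x, ...) {
  cat(sprintf("ecgi_study: %d result rows (%d failed cells)\n",
              nrow(x), sum(!is.na(x$error))))
  cat("  orders:", paste(sort(unique(x$order)), collapse = ", "),
      "| leads:", paste(sort(unique(x$n_leads)), collapse = ", "), "\n")
  cat("  locations:", paste(unique(x$location), collapse = ", "),
      "| radii:", paste(sort(unique(x$radius_mm), decreasing = TRUE),
                        collapse = ", "), "mm\n")
  NextMethod()
}
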