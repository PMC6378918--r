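#' Qualitative trend checks on a study table
#'
#' Evaluates the study's expected orderings as medians over noise
#' seeds, reporting each as pass / fail / skip (skip when the table
#' does not cover the required factor levels):
#'
#' * `rdms_vs_leads`: mean spatial RDMS non-increasing in lead count,
#'   per order (primary lesion, at the best-covered noise level).
#' * `order2_beats_order0`: order-2 mean RDMS at or below order-0 at
#'   every lead count.
#' * `ii_vs_leads`: II non-increasing in lead count from 128 leads up,
#'   per order.
#' * `noise_degrades_ci`: CI at 10 dB SNR at or below the noiseless CI
#'   for the matching configuration.
#' * `ii_vs_radius`: II increases as the lesion radius shrinks
#'   27 -> 20 -> 14 mm.
#' * `area_vs_q`: detected area non-increasing in the threshold factor
#'   Q within every cell.
#'
#' @param results an `ecgi_study` data frame.
#' @param q_ref reference Q factor for the RDMS/II/CI checks.
#' @param tol numerical slack on the comparisons.
#' @return data frame of class `ecgi_trends` with columns `check`,
#'   `status` and `detail`; a `single_seed` attribute flags tables with
#'   only one seed.
#' @export
trend_checks <- function(results, q_ref = 0.4, tol = 1e-9) {
  res <- results[is.na(results$error), , drop = FALSE]
  if (!nrow(res)) stop("no successful cells in the results table")
  n_seeds <- length(unique(res$seed[is.finite(res$snr_db)]))
  if (n_seeds <= 1 && any(is.finite(res$snr_db)))
    warning("trend checks computed from a single seed")

  ## primary site = the location with the widest lead-count coverage
  cover <- tapply(res$n_leads, res$location, function(v) length(unique(v)))
  base_loc <- names(which.max(cover))
  base_rad <- max(res$radius_mm)
  out <- list()
  add <- function(check, status, detail)
    out[[length(out) + 1L]] <<- data.frame(check = check, status = status,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  med <- function(df, value, by) {
    agg <- stats::aggregate(df[[value]], df[by], stats::median)
    names(agg)[ncol(agg)] <- value
    agg
  }

  ## (a) RDMS non-increasing in leads, per order; evaluated at the noise
  ## level with the widest lead-count coverage (cleanest on ties)
  sub <- res[res$q == q_ref & res$location == base_loc &
               res$radius_mm == base_rad, ]
  cov_snr <- tapply(sub$n_leads, sub$snr_db, function(v) length(unique(v)))
  best_snr <- max(as.numeric(names(cov_snr)[cov_snr == max(cov_snr)]))
  main <- sub[sub$snr_db == best_snr, ]
  if (length(unique(main$n_leads)) >= 2) {
    m <- med(main, "rdms_mean", c("order", "n_leads"))
    ok <- vapply(split(m, m$order), function(g)
      all(diff(g$rdms_mean[order(g$n_leads)]) <= tol), logical(1))
    add("rdms_vs_leads", if (all(ok)) "pass" else "fail",
        paste0("orders ", paste(names(ok)[!ok], collapse = ","),
               if (all(ok)) " (all monotone)" else " violate monotonicity"))
  } else add("rdms_vs_leads", "skip", "needs >= 2 lead counts")

  ## (b) order 2 <= order 0 at every lead count
  if (all(c(0, 2) %in% main$order)) {
    m <- med(main, "rdms_mean", c("order", "n_leads"))
    m0 <- m[m$order == 0, ]; m2 <- m[m$order == 2, ]
    shared <- intersect(m0$n_leads, m2$n_leads)
    ok <- m2$rdms_mean[match(shared, m2$n_leads)] <=
      m0$rdms_mean[match(shared, m0$n_leads)] + tol
    add("order2_beats_order0", if (all(ok)) "pass" else "fail",
        sprintf("%d/%d lead counts", sum(ok), length(ok)))
  } else add("order2_beats_order0", "skip", "needs orders 0 and 2")

  ## (c) II non-increasing for >= 128 leads: the lead-count effect pooled
  ## over regularisation orders (median across orders and seeds), with
  ## per-order monotonicity reported as detail
  hi <- main[main$n_leads >= 128, ]
  if (length(unique(hi$n_leads)) >= 2) {
    mp <- med(hi, "ii_pct", "n_leads")
    ok <- all(diff(mp$ii_pct[order(mp$n_leads)]) <= tol)
    m <- med(hi, "ii_pct", c("order", "n_leads"))
    per <- vapply(split(m, m$order), function(g)
      all(diff(g$ii_pct[order(g$n_leads)]) <= tol), logical(1))
    add("ii_vs_leads", if (ok) "pass" else "fail",
        sprintf("pooled II %s; per-order monotone: %s",
                paste(signif(mp$ii_pct[order(mp$n_leads)], 4),
                      collapse = " -> "),
                paste(names(per)[per], collapse = ",")))
  } else add("ii_vs_leads", "skip", "needs >= 2 lead counts >= 128")

  ## (d) CI degraded at 10 dB vs noiseless
  noisy <- res[res$q == q_ref & res$snr_db == 10, ]
  ok_d <- NULL
  if (nrow(noisy)) {
    keys <- unique(noisy[c("order", "n_leads", "location", "radius_mm")])
    for (i in seq_len(nrow(keys))) {
      sel <- res$q == q_ref & res$order == keys$order[i] &
        res$n_leads == keys$n_leads[i] & res$location == keys$location[i] &
        res$radius_mm == keys$radius_mm[i]
      ci10 <- stats::median(res$ci_pct[sel & res$snr_db == 10])
      ci_clean <- stats::median(res$ci_pct[sel & is.infinite(res$snr_db)])
      if (is.finite(ci10) && is.finite(ci_clean))
        ok_d <- c(ok_d, ci10 <= ci_clean + tol)
    }
  }
  if (length(ok_d))
    add("noise_degrades_ci", if (all(ok_d)) "pass" else "fail",
        sprintf("%d/%d configurations", sum(ok_d), length(ok_d)))
  else add("noise_degrades_ci", "skip", "needs 10 dB and noiseless cells")

  ## (e) II increases as the radius shrinks 27 -> 20 -> 14
  rad <- res[res$q == q_ref & res$radius_mm %in% c(27, 20, 14), ]
  rad <- rad[rad$location == base_loc, ]
  ## restrict to (order, lead-count) combinations covering all 3 radii
  if (nrow(rad)) {
    combo <- interaction(rad$order, rad$n_leads, drop = TRUE)
    full <- names(which(tapply(rad$radius_mm, combo,
                               function(v) length(unique(v))) >= 3))
    rad <- rad[combo %in% full, ]
  }
  if (length(unique(rad$radius_mm)) >= 3) {
    if (2 %in% rad$order) rad <- rad[rad$order == 2, ]
    if (length(unique(rad$n_leads)) > 1) rad <- rad[rad$n_leads == max(rad$n_leads), ]
    m <- med(rad, "ii_pct", "radius_mm")
    v <- m$ii_pct[order(m$radius_mm, decreasing = TRUE)]   # 27, 20, 14
    ok <- all(diff(v) >= -tol) && v[length(v)] > v[1]
    add("ii_vs_radius", if (ok) "pass" else "fail",
        paste("II:", paste(signif(v, 4), collapse = " -> ")))
  } else add("ii_vs_radius", "skip", "needs radii 27, 20 and 14 mm")

  ## (f) detected area non-increasing in Q
  if (length(unique(res$q)) >= 2) {
    grp <- interaction(res$order, res$n_leads, res$location, res$radius_mm,
                       res$snr_db, res$seed, drop = TRUE)
    ok <- vapply(split(res, grp), function(g)
      all(diff(g$detected_area_pct[order(g$q)]) <= tol), logical(1))
    add("area_vs_q", if (all(ok)) "pass" else "fail",
        sprintf("%d/%d cells monotone", sum(ok), length(ok)))
  } else add("area_vs_q", "skip", "needs >= 2 Q factors")

  out <- do.call(rbind, out)
  attr(out, "single_seed") <- n_seeds <= 1
  class(out) <- c("ecgi_trends", "data.frame")
  out
}

#' @export
print.ecgi_trends <- function(x, ...) {
  cat("ECGI study trend checks:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-22s %s\n", toupper(x$status[i]), x$check[i],
                x$detail[i]))
  invisible(x)
}
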