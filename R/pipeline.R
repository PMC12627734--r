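#' Filter, differentiate and segment one recording
#'
#' Applies the zero-phase low-pass filter to the two hand-height channels
#' and the board angle, differentiates them, and decodes each velocity
#' profile with the corresponding fitted segmenter.
#'
#' @param rec a `bb_recording`.
#' @param models list with `bb_segmenter` elements `L`, `R`, `board`.
#' @param fspec a [filter_spec()].
#' @param min_duration minimum segment duration (s).
#' @return list with `seg_L`, `seg_R`, `seg_board` (`bb_segments`) and the
#'   velocity series `v_L`, `v_R`, `v_theta`.
#' @export
segment_recording <- function(rec, models, fspec = filter_spec(),
                              min_duration = 0.05) {
  fs <- fspec$sample_rate
  vel <- function(x) estimate_velocity(zero_phase_filter(x, fspec), fs)
  v_L <- vel(rec$z_L); v_R <- vel(rec$z_R); v_th <- vel(rec$theta)
  list(seg_L = decode_segments(v_L, models$L, min_duration, fs),
       seg_R = decode_segments(v_R, models$R, min_duration, fs),
       seg_board = decode_segments(v_th, models$board, min_duration, fs),
       v_L = v_L, v_R = v_R, v_theta = v_th)
}

#' Fit session segmenters on a collection of recordings
#'
#' One model per hand and one for the board, each fit on the concatenated
#' filtered velocity profiles of all recordings in the session.
#'
#' @param recordings list of `bb_recording`.
#' @param seed integer seed for the EM fits.
#' @param fspec a [filter_spec()].
#' @param n_restarts EM restarts per model.
#' @return list of `bb_segmenter`s: `L`, `R`, `board`.
#' @export
fit_session_segmenters <- function(recordings, seed = 1,
                                   fspec = filter_spec(), n_restarts = 10) {
  fs <- fspec$sample_rate
  vel <- function(x) estimate_velocity(zero_phase_filter(x, fspec), fs)
  vL <- lapply(recordings, function(r) vel(r$z_L))
  vR <- lapply(recordings, function(r) vel(r$z_R))
  vT <- lapply(recordings, function(r) vel(r$theta))
  list(L = fit_segmenter(vL, seed = seed, n_restarts = n_restarts),
       R = fit_segmenter(vR, seed = seed + 1L, n_restarts = n_restarts),
       board = fit_segmenter(vT, seed = seed + 2L,
                             labels = c("cw", "stationary", "ccw"),
                             n_restarts = n_restarts))
}

#' Coordination and role metrics of one trial
#'
#' @param rec a successful `bb_recording`.
#' @param segs output of [segment_recording()] for `rec`.
#' @param params a [model_params()].
#' @param delay_window onset-pairing half-window (s) for
#'   [aligned_delays()].
#' @return list with `row` (one-row data.frame of per-trial metrics),
#'   `endpoints` (board-rotation endpoint samples for movement-ratio
#'   pooling), `delays`, `C_L`, `C_R`, `uni` (unilateral distances), and
#'   `timeline`.
#' @export
trial_metrics <- function(rec, segs, params = model_params(),
                          delay_window = 0.5) {
  meta <- rec_meta(rec)
  dt <- params$dt
  n_ct <- nrow(rec)
  ct <- meta$completion_time
  timeline <- classify_interaction(segs$seg_L, segs$seg_R)
  ratios <- if (!is.null(ct) && is.finite(ct) && ct > 0)
    coordination_ratios(timeline, ct, dt)
  else c(aligned = NA_real_, opposed = NA_real_, single = NA_real_,
         stationary = NA_real_)
  delays <- aligned_delays(segs$seg_board, segs$seg_L, segs$seg_R,
                           sample_rate = 1 / dt, window = delay_window)
  cr <- corrective_ratio(rec$z_L, rec$z_R, k = round(0.2 / dt))
  uni <- unilateral_ratio(rec$z_L, rec$z_R, segs$seg_L, segs$seg_R)
  row <- data.frame(
    dyad = as.character(meta$dyad), block = meta$block,
    condition = meta$condition, trial = meta$trial,
    outcome = meta$outcome,
    completion_time = if (is.null(ct)) NA_real_ else ct,
    aligned = ratios[["aligned"]], opposed = ratios[["opposed"]],
    single = ratios[["single"]], stationary = ratios[["stationary"]],
    n_delays = nrow(delays),
    mean_delay = if (nrow(delays)) mean(delays$delay) else NA_real_,
    mean_abs_delay = if (nrow(delays)) mean(delays$abs_delay) else NA_real_,
    CR_L = cr$CR_L, CR_R = cr$CR_R)
  list(row = row,
       endpoints = board_segment_endpoints(rec, segs$seg_board),
       delays = delays, C_L = cr$C_L, C_R = cr$C_R, uni = uni,
       timeline = timeline)
}

#' Block-level leadership from pooled trial metrics
#'
#' Pools board-rotation endpoints, onset delays, corrective movements and
#' unilateral distances over the trials of one block (or any pooling
#' unit) and derives the four role metrics and the leader call.
#'
#' @param pieces list of [trial_metrics()] outputs.
#' @param min_points minimum pooled endpoints for the movement-ratio fit.
#' @return list with the pooled `movement` fit, `mean_delay`,
#'   `mean_abs_delay`, `CR_L`, `UR_L`, and the `bb_leadership` summary.
#' @export
block_leadership <- function(pieces, min_points = 5) {
  ep <- do.call(rbind, lapply(pieces, `[[`, "endpoints"))
  dl <- do.call(rbind, lapply(pieces, `[[`, "delays"))
  mv <- movement_ratio(ep$theta, ep$z_L, ep$z_R, min_points = min_points)
  C_L <- mean(vapply(pieces, `[[`, numeric(1), "C_L"))
  C_R <- mean(vapply(pieces, `[[`, numeric(1), "C_R"))
  CR_L <- if (C_L + C_R > 0) C_L / (C_L + C_R) else 0.5
  dist_L <- sum(vapply(pieces, function(p) p$uni$dist_L, numeric(1)))
  dist_R <- sum(vapply(pieces, function(p) p$uni$dist_R, numeric(1)))
  UR_L <- if (dist_L + dist_R > 0) dist_L / (dist_L + dist_R) else NA_real_
  mean_delay <- if (nrow(dl)) mean(dl$delay) else NA_real_
  summary <- leadership_summary(mv$p_L, mean_delay, CR_L, UR_L)
  list(movement = mv, mean_delay = mean_delay,
       mean_abs_delay = if (nrow(dl)) mean(dl$abs_delay) else NA_real_,
       n_delays = if (is.null(dl)) 0L else nrow(dl),
       CR_L = CR_L, UR_L = UR_L, leadership = summary)
}

#' One-way repeated-measures comparison across haptic conditions
#'
#' One-way repeated-measures ANOVA on the within-subject factor
#' `condition` (uncorrected F alongside the Greenhouse-Geisser corrected
#' test), followed by all pairwise paired t-tests with Holm step-down
#' adjustment.
#'
#' @param data data.frame with columns `subject`, `condition`, `value`;
#'   the design must be complete (every subject in every condition,
#'   exactly once).
#' @return An object of class `bb_comparison`: list with `anova`
#'   (data.frame: F, df1, df2, p, gg_epsilon, p_gg) and `pairwise`
#'   (data.frame: a, b, t, df, p, p_holm).
#' @export
compare_conditions <- function(data) {
  need <- c("subject", "condition", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns subject, condition, value")
  data$subject <- factor(data$subject)
  data$condition <- factor(data$condition)
  tabs <- table(data$subject, data$condition)
  if (any(tabs != 1L))
    stop("incomplete design: every subject must appear exactly once in ",
         "every condition")
  k <- nlevels(data$condition); n <- nlevels(data$subject)
  if (k < 2L || n < 2L) stop("need at least 2 conditions and 2 subjects")

  fit <- stats::aov(value ~ condition + Error(subject / condition),
                    data = data)
  tab <- summary(fit)[["Error: subject:condition"]][[1]]
  F_ <- tab["condition", "F value"]
  df1 <- tab["condition", "Df"]
  df2 <- tab["Residuals", "Df"]
  p <- tab["condition", "Pr(>F)"]

  wide <- stats::xtabs(value ~ subject + condition, data = data)
  S <- stats::cov(unclass(wide))
  C <- diag(k) - 1 / k
  M <- C %*% S %*% C
  # the degenerate no-effect case: condition sum of squares is pure
  # floating-point residue relative to the data scale
  if (tab["condition", "Sum Sq"] <=
        1e-10 * max(sum(data$value^2), .Machine$double.xmin)) {
    F_ <- 0; p <- 1
  }
  eps <- if (sum(M^2) > 0)
    sum(diag(M))^2 / ((k - 1) * sum(M^2)) else 1
  p_gg <- if (F_ == 0) 1 else
    stats::pf(F_, df1 * eps, df2 * eps, lower.tail = FALSE)

  levs <- colnames(wide)
  pairs <- utils::combn(levs, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- wide[, a] - wide[, b]
    if (stats::sd(d) == 0) {
      data.frame(a = a, b = b, t = 0, df = n - 1L, p = 1)
    } else {
      tt <- stats::t.test(d)
      data.frame(a = a, b = b, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }
  }))
  pw$p_holm <- stats::p.adjust(pw$p, method = "holm")
  structure(list(anova = data.frame(F = F_, df1 = df1, df2 = df2, p = p,
                                    gg_epsilon = eps, p_gg = p_gg),
                 pairwise = pw),
            class = "bb_comparison")
}

#' @export
print.bb_comparison <- function(x, ...) {
  a <- x$anova
  cat(sprintf(
    "rmANOVA: F(%d, %d) = %.3f, p = %.4g  (GG eps = %.3f, p_GG = %.4g)\n",
    a$df1, a$df2, a$F, a$p, a$gg_epsilon, a$p_gg))
  cat("Holm-adjusted pairwise paired t-tests:\n")
  pw <- x$pairwise
  for (i in seq_len(nrow(pw)))
    cat(sprintf("  %s vs %s: t(%d) = %+.3f, p = %.4g, p_holm = %.4g\n",
                pw$a[i], pw$b[i], pw$df[i], pw$t[i], pw$p[i], pw$p_holm[i]))
  invisible(x)
}

#' Configuration of a synthetic study
#'
#' @param dyads named list of [dyad_spec()] (one entry per synthetic
#'   dyad).
#' @param n_blocks blocks per dyad (sets of five cover the five haptic
#'   conditions).
#' @param trials_per_block successful trials per block.
#' @param config a [trial_config()].
#' @param params a [model_params()].
#' @param seed master seed; all stage seeds derive from it.
#' @param fspec a [filter_spec()].
#' @return An object of class `bb_study_config`.
#' @export
study_config <- function(dyads = list(dyad1 = dyad_spec()), n_blocks = 5,
                         trials_per_block = 4, config = trial_config(),
                         params = model_params(), seed = 1,
                         fspec = filter_spec()) {
  if (!length(dyads)) stop("at least one dyad spec is required")
  if (is.null(names(dyads)) || any(names(dyads) == ""))
    names(dyads) <- paste0("dyad", seq_along(dyads))
  if (n_blocks < 1L) stop("empty block schedule")
  structure(list(dyads = dyads, n_blocks = n_blocks,
                 trials_per_block = trials_per_block, config = config,
                 params = params, seed = seed, fspec = fspec),
            class = "bb_study_config")
}

#' Run a full synthetic study: simulate, segment, measure, compare
#'
#' Executes the pipeline end to end for every dyad in the configuration:
#' generates the session recordings (failed trials are repeated and
#' excluded from the metric tables), fits the session segmenters, computes
#' per-trial coordination metrics and per-block leadership, pools
#' motion-triggered trajectory averages per role and condition, and — when
#' at least three dyads are present — compares completion time and aligned
#' ratio across haptic conditions with the repeated-measures pipeline.
#' Fully deterministic given the configuration seed.
#'
#' @param sc a [study_config()].
#' @param out_dir optional directory; when given, the metric tables are
#'   written as delimited files plus a JSON run manifest.
#' @return list with `trials` (per-trial metric table), `leadership`
#'   (per dyad x block), `mtta` (long curve table), `comparisons` (list of
#'   `bb_comparison` or NULL), `ground_truth`, `dropped` (failed-trial
#'   counts).
#' @export
run_study <- function(sc, out_dir = NULL) {
  stopifnot(inherits(sc, "bb_study_config"))
  trial_rows <- list(); lead_rows <- list(); mtta_trials <- list()
  ground_truth <- list(); dropped <- integer()
  for (d in seq_along(sc$dyads)) {
    id <- names(sc$dyads)[d]
    ds <- generate_dyad_dataset(sc$dyads[[d]], n_blocks = sc$n_blocks,
                                trials_per_block = sc$trials_per_block,
                                config = sc$config, params = sc$params,
                                seed = sc$seed + 7919L * d, dyad_id = id)
    ground_truth[[id]] <- ds$ground_truth
    ok <- Filter(function(r) rec_meta(r)$outcome == "success",
                 ds$recordings)
    dropped[id] <- length(ds$recordings) - length(ok)
    models <- fit_session_segmenters(ok, seed = sc$seed + 7919L * d,
                                     fspec = sc$fspec, n_restarts = 3)
    pieces_by_block <- list()
    for (r in ok) {
      segs <- segment_recording(r, models, sc$fspec)
      tm <- trial_metrics(r, segs, sc$params)
      trial_rows[[length(trial_rows) + 1L]] <- tm$row
      b <- as.character(rec_meta(r)$block)
      pieces_by_block[[b]] <- c(pieces_by_block[[b]], list(tm))
      mtta_trials[[length(mtta_trials) + 1L]] <-
        list(rec = r, board_segs = segs$seg_board, dyad = id,
             condition = rec_meta(r)$condition)
    }
    # leader decided per dyad on all pooled blocks, reported per block too
    all_pieces <- unlist(pieces_by_block, recursive = FALSE)
    dyad_lead <- block_leadership(all_pieces)
    for (b in names(pieces_by_block)) {
      bl <- tryCatch(block_leadership(pieces_by_block[[b]]),
                     error = function(e) NULL)
      if (is.null(bl)) next
      lead_rows[[length(lead_rows) + 1L]] <- data.frame(
        dyad = id, block = as.integer(b), scope = "block",
        p_L = bl$movement$p_L, k_L = bl$movement$k_L,
        k_R = bl$movement$k_R, r2_L = bl$movement$r_squared[["L"]],
        r2_R = bl$movement$r_squared[["R"]],
        mean_delay = bl$mean_delay, mean_abs_delay = bl$mean_abs_delay,
        CR_L = bl$CR_L, UR_L = bl$UR_L, leader = bl$leadership$leader)
    }
    lead_rows[[length(lead_rows) + 1L]] <- data.frame(
      dyad = id, block = NA_integer_, scope = "dyad",
      p_L = dyad_lead$movement$p_L, k_L = dyad_lead$movement$k_L,
      k_R = dyad_lead$movement$k_R,
      r2_L = dyad_lead$movement$r_squared[["L"]],
      r2_R = dyad_lead$movement$r_squared[["R"]],
      mean_delay = dyad_lead$mean_delay,
      mean_abs_delay = dyad_lead$mean_abs_delay,
      CR_L = dyad_lead$CR_L, UR_L = dyad_lead$UR_L,
      leader = dyad_lead$leadership$leader)
    for (i in seq_along(mtta_trials))
      if (mtta_trials[[i]]$dyad == id && is.null(mtta_trials[[i]]$leader))
        mtta_trials[[i]]$leader <- dyad_lead$leadership$leader
  }
  trials <- do.call(rbind, trial_rows)
  leadership <- do.call(rbind, lead_rows)
  mtta_tab <- mtta(mtta_trials, params = sc$params)

  comparisons <- NULL
  if (length(sc$dyads) >= 3L) {
    comparisons <- list()
    for (metric in c("completion_time", "aligned")) {
      agg <- stats::aggregate(trials[[metric]],
                              by = list(subject = trials$dyad,
                                        condition = trials$condition),
                              FUN = mean, na.rm = TRUE)
      names(agg)[3] <- "value"
      comparisons[[metric]] <- tryCatch(compare_conditions(agg),
                                        error = function(e) NULL)
    }
  }
  out <- list(trials = trials, leadership = leadership, mtta = mtta_tab,
              comparisons = comparisons, ground_truth = ground_truth,
              dropped = dropped)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trials, file.path(out_dir, "trials.csv"),
                     row.names = FALSE)
    utils::write.csv(leadership, file.path(out_dir, "leadership.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(mtta_tab),
                     file.path(out_dir, "mtta.csv"), row.names = FALSE)
    manifest <- list(seed = sc$seed, n_blocks = sc$n_blocks,
                     trials_per_block = sc$trials_per_block,
                     params = unclass(sc$params),
                     dropped = as.list(dropped),
                     ground_truth = ground_truth)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
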