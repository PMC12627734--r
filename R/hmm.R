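#' Fit a 3-state velocity segmenter (Gaussian hidden Markov model)
#'
#' Fits a hidden Markov model with scalar Gaussian emissions to one or more
#' velocity series by expectation-maximization, with k-means
#' initialization and multiple restarts (best likelihood kept). After
#' fitting, states are relabeled so emission means are strictly ascending
#' and mapped to the supplied labels — for hands
#' `c("down", "stationary", "up")`, for the board
#' `c("cw", "stationary", "ccw")` (positive angular velocity is
#' counterclockwise). The middle label is treated as the stationary state.
#'
#' @param velocities numeric vector or list of numeric vectors (e.g. one
#'   per trial); the model is fit on all of them jointly, treating each as
#'   an independent chain.
#' @param seed integer seed controlling initialization; fits are
#'   reproducible given the seed.
#' @param labels state labels in ascending order of emission mean.
#' @param n_restarts number of k-means/EM restarts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @return An object of class `bb_segmenter` with elements `means`, `sds`,
#'   `transition` (row-stochastic), `init`, `labels`, `loglik`, `n_iter`,
#'   `seed`.
#' @export
fit_segmenter <- function(velocities, seed = 1,
                          labels = c("down", "stationary", "up"),
                          n_restarts = 10, max_iter = 200, tol = 1e-8) {
  if (!is.list(velocities)) velocities <- list(velocities)
  velocities <- lapply(velocities, as.numeric)
  pooled <- unlist(velocities)
  K <- length(labels)
  if (length(pooled) < 10L * K) stop("too few samples to fit the segmenter")
  if (stats::sd(pooled) < 1e-9)
    stop("degenerate input: velocity series is (near-)constant; ",
         "cannot separate movement states")
  min_sd <- max(1e-8, 1e-4 * stats::sd(pooled))

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(pooled, centers = K, nstart = 1,
                                     iter.max = 50)),
      error = function(e) NULL)
    if (is.null(km)) {
      mu <- as.numeric(stats::quantile(pooled, (seq_len(K) - 0.5) / K)) +
        stats::rnorm(K, 0, min_sd)
      sg <- rep(max(stats::sd(pooled), min_sd), K)
    } else {
      mu <- as.numeric(km$centers)
      sg <- vapply(seq_len(K), function(k) {
        v <- pooled[km$cluster == k]
        if (length(v) < 2L) min_sd else max(stats::sd(v), min_sd)
      }, numeric(1))
    }
    pi0 <- rep(1 / K, K)
    A <- matrix(0.01 / (K - 1), K, K); diag(A) <- 0.99

    ll_old <- -Inf; ll <- -Inf; it <- 0L
    for (it in seq_len(max_iter)) {
      ll <- 0
      g_sum <- numeric(K); gv_sum <- numeric(K); gvv_sum <- numeric(K)
      xi_sum <- matrix(0, K, K); pi_acc <- numeric(K)
      for (v in velocities) {
        logd <- vapply(seq_len(K), function(k)
          stats::dnorm(v, mu[k], sg[k], log = TRUE), numeric(length(v)))
        fb <- hmm_forward_backward(logd, A, pi0)
        ll <- ll + fb$loglik
        g <- fb$gamma
        g_sum <- g_sum + colSums(g)
        gv_sum <- gv_sum + colSums(g * v)
        gvv_sum <- gvv_sum + colSums(g * v^2)
        xi_sum <- xi_sum + fb$xi_sum
        pi_acc <- pi_acc + g[1, ]
      }
      mu <- gv_sum / g_sum
      sg <- pmax(sqrt(pmax(gvv_sum / g_sum - mu^2, 0)), min_sd)
      A <- xi_sum / rowSums(xi_sum)
      pi0 <- pi_acc / sum(pi_acc)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$loglik)
      best <- list(means = mu, sds = sg, transition = A, init = pi0,
                   loglik = ll, n_iter = it)
  }
  ord <- order(best$means)
  structure(list(means = best$means[ord], sds = best$sds[ord],
                 transition = best$transition[ord, ord, drop = FALSE],
                 init = best$init[ord], labels = labels,
                 loglik = best$loglik, n_iter = best$n_iter, seed = seed),
            class = "bb_segmenter")
}

#' @export
print.bb_segmenter <- function(x, ...) {
  cat("Gaussian-HMM velocity segmenter\n")
  for (k in seq_along(x$labels))
    cat(sprintf("  %-10s mean %+.4f  sd %.4f\n", x$labels[k], x$means[k],
                x$sds[k]))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations (seed %d)\n",
              x$loglik, x$n_iter, x$seed))
  invisible(x)
}

state_logdens <- function(v, model) {
  vapply(seq_along(model$labels), function(k)
    stats::dnorm(v, model$means[k], model$sds[k], log = TRUE),
    numeric(length(v)))
}

#' Decode a velocity series into labeled movement segments
#'
#' Computes the most likely state path (Viterbi) under a fitted
#' [fit_segmenter()] model, then merges segments shorter than
#' `min_duration` into the neighboring segment whose label carries the
#' higher posterior mass over the short segment's samples. Movement onsets
#' are the first samples of non-stationary segments.
#'
#' @param v velocity series.
#' @param model a `bb_segmenter`.
#' @param min_duration minimum segment duration (s) after merging.
#' @param sample_rate sampling rate (Hz).
#' @return An object of class `bb_segments`: list with `labels` (character
#'   vector per sample) and `segments` (data.frame `start`, `end`, `label`,
#'   `duration`; sample indices, inclusive).
#' @export
decode_segments <- function(v, model, min_duration = 0.05,
                            sample_rate = 1000) {
  logd <- state_logdens(v, model)
  path <- hmm_viterbi(logd, model$transition, model$init)
  labels <- model$labels[path]
  min_n <- max(1L, round(min_duration * sample_rate))
  if (min_n > 1L) {
    gamma <- hmm_forward_backward(logd, model$transition, model$init)$gamma
    labels <- merge_short_segments(labels, gamma, model$labels, min_n)
  }
  structure(list(labels = labels,
                 segments = segments_from_labels(labels, sample_rate),
                 min_duration = min_duration, sample_rate = sample_rate),
            class = "bb_segments")
}

#' Contiguous segments of a label sequence
#'
#' @param labels character vector of per-sample labels.
#' @param sample_rate sampling rate (Hz), used for durations.
#' @return data.frame with `start`, `end` (sample indices, inclusive),
#'   `label`, `duration` (s). Segments partition the sequence and
#'   consecutive segments differ in label.
#' @export
segments_from_labels <- function(labels, sample_rate = 1000) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths + 1L, end = end, label = r$values,
             duration = r$lengths / sample_rate,
             stringsAsFactors = FALSE)
}

# Merge segments shorter than min_n samples into the neighbor whose label
# has the larger summed posterior over the short segment's samples.
# Iterates shortest-first until no short segment remains (or one is left).
merge_short_segments <- function(labels, gamma, state_labels, min_n) {
  repeat {
    seg <- segments_from_labels(labels, 1)
    len <- seg$end - seg$start + 1L
    short <- which(len < min_n)
    if (!length(short) || nrow(seg) == 1L) break
    i <- short[which.min(len[short])]
    idx <- seg$start[i]:seg$end[i]
    cand <- c(if (i > 1L) seg$label[i - 1L],
              if (i < nrow(seg)) seg$label[i + 1L])
    cand <- unique(cand)
    post <- vapply(cand, function(lb) {
      k <- match(lb, state_labels)
      sum(gamma[idx, k])
    }, numeric(1))
    labels[idx] <- cand[which.max(post)]
  }
  labels
}

#' Movement onset samples of a segmentation
#'
#' @param segs a `bb_segments`.
#' @param stationary the label of the stationary state.
#' @return data.frame of the non-stationary segments with their onset
#'   sample (`start`) and label.
#' @export
movement_onsets <- function(segs, stationary = "stationary") {
  s <- segs$segments
  s[s$label != stationary, c("start", "end", "label"), drop = FALSE]
}
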