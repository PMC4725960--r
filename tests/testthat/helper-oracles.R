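# Brute-force oracles, deliberately written as explicit loops so they stay
# independent of the vectorized implementation they check.

# naive O(N^4) 2-D DFT power spectrum with the same 1/(nr*nc) energy scaling
naive_power_spectrum <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (u in 0:(nr - 1)) for (v in 0:(nc - 1)) {
    acc <- 0 + 0i
    for (r in 0:(nr - 1)) for (c in 0:(nc - 1))
      acc <- acc + m[r + 1, c + 1] *
        exp(-2i * pi * (u * r / nr + v * c / nc))
    out[u + 1, v + 1] <- Mod(acc)^2
  }
  out / (nr * nc)
}

# scalar-loop re-derivation of the Fourier I15 band-energy fraction from a
# power spectrum with fx/fy attributes
naive_band_fraction <- function(ps, period_min, period_max, sector_deg) {
  fx <- attr(ps, "fx"); fy <- attr(ps, "fy")
  # locate the dominant annulus bin
  best <- -Inf; theta0 <- NA
  for (i in seq_along(fy)) for (j in seq_along(fx)) {
    r <- sqrt(fx[j]^2 + fy[i]^2)
    if (r > 0 && r >= 1 / period_max && r <= 1 / period_min &&
        ps[i, j] > best) {
      best <- ps[i, j]
      theta0 <- atan2(fy[i], fx[j]) %% pi
    }
  }
  num <- 0; den <- 0
  for (i in seq_along(fy)) for (j in seq_along(fx)) {
    r <- sqrt(fx[j]^2 + fy[i]^2)
    if (r == 0) next
    den <- den + ps[i, j]
    if (r >= 1 / period_max && r <= 1 / period_min) {
      a <- abs((atan2(fy[i], fx[j]) %% pi) - theta0)
      if (min(a, pi - a) <= sector_deg * pi / 180 + 1e-12)
        num <- num + ps[i, j]
    }
  }
  num / den
}

# scalar-loop second-order spectral moments -> anisotropy index
naive_moment_index <- function(ps) {
  fx <- attr(ps, "fx"); fy <- attr(ps, "fy")
  tot <- 0
  for (i in seq_along(fy)) for (j in seq_along(fx))
    if (fx[j] != 0 || fy[i] != 0) tot <- tot + ps[i, j]
  mx <- 0; my <- 0
  for (i in seq_along(fy)) for (j in seq_along(fx))
    if (fx[j] != 0 || fy[i] != 0) {
      mx <- mx + ps[i, j] / tot * fx[j]
      my <- my + ps[i, j] / tot * fy[i]
    }
  cxx <- 0; cyy <- 0; cxy <- 0
  for (i in seq_along(fy)) for (j in seq_along(fx))
    if (fx[j] != 0 || fy[i] != 0) {
      p <- ps[i, j] / tot
      cxx <- cxx + p * (fx[j] - mx)^2
      cyy <- cyy + p * (fy[i] - my)^2
      cxy <- cxy + p * (fx[j] - mx) * (fy[i] - my)
    }
  tr <- cxx + cyy
  disc <- sqrt(max((cxx - cyy)^2 + 4 * cxy^2, 0))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  1 - max(l2, 0) / l1
}

# all-pairs Mann-Whitney AUC, ties counted one half
naive_auc <- function(scores, labels) {
  pos <- scores[labels == "AWM"]; neg <- scores[labels == "NODAL"]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + if (p > q) 1 else if (p == q) 0.5 else 0
  acc / (length(pos) * length(neg))
}

# tpr/fpr at one threshold by explicit tallying
naive_rates <- function(scores, labels, thr) {
  tp <- 0; fp <- 0; npos <- 0; nneg <- 0
  for (k in seq_along(scores)) {
    if (labels[k] == "AWM") {
      npos <- npos + 1
      if (scores[k] >= thr) tp <- tp + 1
    } else {
      nneg <- nneg + 1
      if (scores[k] >= thr) fp <- fp + 1
    }
  }
  c(tpr = tp / npos, fpr = fp / nneg)
}

# exhaustive-search cutoff for a given rule over the curve's own candidates
naive_best_threshold <- function(scores, labels, rule, fp_cost, fn_cost) {
  s <- sort(unique(scores))
  cand <- c(max(s) + 1,
            if (length(s) > 1) rev((s[-1] + s[-length(s)]) / 2),
            min(s) - 1)
  best_obj <- Inf; best_thr <- NA
  for (t in cand) {
    rt <- naive_rates(scores, labels, t)
    obj <- if (rule == "product") -(rt["tpr"] * (1 - rt["fpr"]))
           else sqrt(fn_cost * (1 - rt["tpr"])^2 + fp_cost * rt["fpr"]^2)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best_thr <- t }
  }
  best_thr
}

# small white-noise frame for oracle comparisons
random_frame <- function(seed, n = 16, px = 1.8) {
  withr::with_seed(seed,
    image_frame(matrix(runif(n * n), n, n), pixel_size_um = px,
                source_id = paste0("rand", seed)))
}

# compact generator settings used across tests (small frames, fast)
small_striated <- function(...) striated_params(shape_px = c(32L, 32L), ...)
small_reticular <- function(...) reticular_params(shape_px = c(32L, 32L), ...)

# seeded random scored sets for ROC/cutoff property tests
random_scored <- function(seed, n_pos = 12, n_neg = 12) {
  withr::with_seed(seed, {
    data.frame(
      i15 = c(round(runif(n_pos, 0.3, 1), 2), round(runif(n_neg, 0, 0.7), 2)),
      label = rep(c("AWM", "NODAL"), c(n_pos, n_neg)))
  })
}
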