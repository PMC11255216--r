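# Independent (slow, brute-force) reference implementations used as
# oracles. These deliberately avoid the package's computational paths.

# partial correlation by residual regression: regress all other nodes out
# of i and j, correlate the residuals
pcor_residual_oracle <- function(ts) {
  m <- ncol(ts)
  out <- diag(m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      others <- setdiff(seq_len(m), c(i, j))
      ri <- if (length(others)) {
        stats::resid(stats::lm(ts[, i] ~ ts[, others]))
      } else {
        ts[, i] - mean(ts[, i])
      }
      rj <- if (length(others)) {
        stats::resid(stats::lm(ts[, j] ~ ts[, others]))
      } else {
        ts[, j] - mean(ts[, j])
      }
      out[i, j] <- out[j, i] <- stats::cor(ri, rj)
    }
  }
  out
}

# plain-R nested LOPO cross-validation mirroring the documented contract
ref_inner_select <- function(X, y, ks, alphas, scale_features = FALSE) {
  n <- nrow(X)
  sse <- matrix(0, length(ks), length(alphas))
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    sc <- suppressWarnings(abs(as.numeric(stats::cor(Xt, yt))))
    sc[is.na(sc)] <- 0
    ord <- order(-sc, seq_along(sc))
    for (ki in seq_along(ks)) {
      k <- min(ks[ki], ncol(X))
      sel <- ord[seq_len(k)]
      ctr <- colMeans(Xt[, sel, drop = FALSE])
      scl <- if (scale_features) {
        s <- apply(Xt[, sel, drop = FALSE], 2, stats::sd)
        s[s < 1e-12] <- 1
        s
      } else {
        rep(1, k)
      }
      Z <- sweep(sweep(Xt[, sel, drop = FALSE], 2, ctr), 2, scl, "/")
      zi <- (X[i, sel] - ctr) / scl
      yc <- yt - mean(yt)
      for (ai in seq_along(alphas)) {
        w <- solve(crossprod(Z) + diag(alphas[ai], k), crossprod(Z, yc))
        sse[ki, ai] <- sse[ki, ai] + (mean(yt) + sum(zi * w) - y[i])^2
      }
    }
  }
  best <- Inf
  bk <- ks[1]
  ba <- alphas[length(alphas)]
  for (ki in seq_along(ks)) {
    for (ai in rev(seq_along(alphas))) {
      if (sse[ki, ai] < best) {
        best <- sse[ki, ai]
        bk <- min(ks[ki], ncol(X))
        ba <- alphas[ai]
      }
    }
  }
  list(k = bk, alpha = ba)
}

ref_fit <- function(X, y, k, alpha, scale_features = FALSE) {
  sc <- suppressWarnings(abs(as.numeric(stats::cor(X, y))))
  sc[is.na(sc)] <- 0
  sel <- sort(order(-sc, seq_along(sc))[seq_len(k)])
  ctr <- colMeans(X[, sel, drop = FALSE])
  scl <- if (scale_features) {
    s <- apply(X[, sel, drop = FALSE], 2, stats::sd)
    s[s < 1e-12] <- 1
    s
  } else {
    rep(1, k)
  }
  Z <- sweep(sweep(X[, sel, drop = FALSE], 2, ctr), 2, scl, "/")
  w <- solve(crossprod(Z) + diag(alpha, k), crossprod(Z, y - mean(y)))
  list(sel = sel, w = as.numeric(w), ctr = ctr, scl = scl, b = mean(y))
}

ref_outer_lopo <- function(X, y, ks, alphas, scale_features = FALSE) {
  n <- nrow(X)
  pred <- numeric(n)
  for (o in seq_len(n)) {
    hp <- ref_inner_select(X[-o, , drop = FALSE], y[-o], ks, alphas,
                           scale_features)
    f <- ref_fit(X[-o, , drop = FALSE], y[-o], hp$k, hp$alpha,
                 scale_features)
    pred[o] <- f$b + sum((X[o, f$sel] - f$ctr) / f$scl * f$w)
  }
  pred
}

# a discovery + validation cohort pair drawn from one shared template
paired_cohorts <- function(seed, n_disc = 30, n_val = 50, n_nodes = 20,
                           true_edges = 3, effect_size = 0.5,
                           n_timepoints = 260, coupling_sd = 0.25) {
  spec <- cohort_spec(n_subjects = n_disc, n_nodes = n_nodes,
                      n_timepoints = n_timepoints, true_edges = true_edges,
                      coupling_sd = coupling_sd, effect_size = effect_size,
                      seed = seed, label = "disc")
  tpl <- cohort_template(spec)
  vspec <- cohort_spec(n_subjects = n_val, n_nodes = n_nodes,
                       n_timepoints = n_timepoints, true_edges = true_edges,
                       coupling_sd = coupling_sd, effect_size = effect_size,
                       seed = seed + 5000L, label = "val")
  list(discovery = generate_cohort(spec, tpl),
       validation = generate_cohort(vspec, tpl),
       template = tpl)
}

# four-cell rating table for one subject
ratings_row <- function(id, plus_hab, plus_acq, minus_hab, minus_acq,
                        modality = "pain") {
  cond <- if (modality == "pain") "CS_plus_pain" else "CS_plus_tone"
  data.frame(
    subject_id = id,
    condition = c(cond, cond, "CS_minus", "CS_minus"),
    phase = rep(c("habituation", "acquisition_end"), 2),
    value = c(plus_hab, plus_acq, minus_hab, minus_acq),
    stringsAsFactors = FALSE)
}
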