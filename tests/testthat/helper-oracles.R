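# Independent brute-force oracles used across the suite. These stay
# deliberately naive: per-pixel loops, explicit enumerations, direct
# arithmetic -- never the production code paths they check.

# per-pixel disc coverage by direct distance evaluation
brute_coverage <- function(points, r_px, width, height) {
  counts <- matrix(0L, width, height)
  if (nrow(points) == 0) return(as.vector(counts))
  cx <- round(points[, 1])
  cy <- round(points[, 2])
  for (px in seq_len(width)) {
    for (py in seq_len(height)) {
      counts[px, py] <- sum((px - cx)^2 + (py - cy)^2 <= r_px^2)
    }
  }
  as.vector(counts)
}

# two-sided Fisher p by full hypergeometric enumeration over one margin
brute_fisher_p <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ])
  r2 <- sum(m[2, ])
  c1 <- sum(m[, 1])
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# mean silhouette width for 1-D values with two known groups
silhouette_1d <- function(x, grp) {
  d <- as.matrix(stats::dist(x))
  ug <- unique(grp)
  stopifnot(length(ug) == 2)
  s <- vapply(seq_along(x), function(i) {
    own <- grp == grp[i]
    own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, !(grp == grp[i])])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# minimal hand-built cluster profile for profiling-module tests
fake_profile <- function(id, sig_ranked, all_markers) {
  tab <- data.frame(
    marker = all_markers,
    p = ifelse(all_markers %in% sig_ranked, 1e-6, 0.5),
    effect = ifelse(all_markers %in% sig_ranked,
                    2 + match(all_markers, rev(sig_ranked), nomatch = 0),
                    0),
    note = "", stringsAsFactors = FALSE
  )
  tab$p_adj <- pmin(tab$p * length(all_markers), 1)
  tab$significant <- all_markers %in% sig_ranked
  structure(
    list(cluster = id, n_cells = 50L, table = tab, ranked = sig_ranked,
         footprint = NULL),
    class = "cluster_profile"
  )
}

# uniform points inside an axis-aligned rectangle polygon
runif_rect <- function(n, x0, x1, y0, y1) {
  cbind(stats::runif(n, x0, x1), stats::runif(n, y0, y1))
}
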