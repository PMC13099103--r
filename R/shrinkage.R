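#' Fit per-marker lognormal-shrinkage mixtures
#'
#' For every marker, fits a one-dimensional Gaussian mixture to
#' `log(1 + intensity)` with at most `G_i` components (BIC model selection
#' over 1..`G_i`, unequal variances); components of negligible weight are
#' dropped afterwards, so the converged component count `G_f` never exceeds
#' `G_i`. The fitted mixture drives [apply_shrinkage()], which contracts each
#' value toward the mean of its maximum-responsibility component to sharpen
#' phenotype clusters before embedding.
#'
#' @param x non-negative intensity matrix (cells x markers) or a
#'   `cell_table`.
#' @param G_i maximum number of mixture components per marker (default 20; a
#'   larger budget, e.g. 28, suits very large samples — the fit should never
#'   be limited by `G_i`, which acts only as an upper bound on `G_f`).
#' @param seed integer seed recorded with the model; the univariate fit is
#'   deterministic, the seed is kept so refits are reproducible by contract.
#' @param weight_tol components with weight below this are dropped and the
#'   remaining weights renormalized.
#' @return an object of class `shrinkage_model`: per-marker component tables
#'   (mean, sd, weight on the log scale) with `G_i` and `G_f`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_shrinkage <- function(x, G_i = 20L, seed = 1L, weight_tol = 1e-3) {
  if (inherits(x, "cell_table")) x <- ct_intensity_matrix(x)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("m%d", seq_len(ncol(x)))
  if (any(x < 0)) stop("intensities must be >= 0")
  if (G_i < 1) stop("G_i must be >= 1")
  fits <- vector("list", ncol(x))
  names(fits) <- colnames(x)
  with_seed(seed, {
    for (j in seq_len(ncol(x))) {
      y <- log1p(x[, j])
      if (stats::sd(y) < 1e-12) {
        warning("marker '", colnames(x)[j],
                "' is constant; single-component model")
        fits[[j]] <- list(
          mean = mean(y), sd = 0, weight = 1, G_f = 1L
        )
        next
      }
      fit <- tryCatch(
        mclust::Mclust(y, G = seq_len(G_i), modelNames = "V",
                       verbose = FALSE),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        fit <- mclust::Mclust(y, G = 1L, modelNames = "V", verbose = FALSE)
      }
      w <- fit$parameters$pro
      mu <- as.vector(fit$parameters$mean)
      sig <- sqrt(fit$parameters$variance$sigmasq)
      if (length(sig) == 1L) sig <- rep(sig, length(mu))
      keep <- w >= weight_tol
      if (!any(keep)) keep <- which.max(w)
      w <- w[keep] / sum(w[keep])
      mu <- mu[keep]
      sig <- sig[keep]
      ord <- order(mu)
      fits[[j]] <- list(
        mean = mu[ord], sd = sig[ord], weight = w[ord],
        G_f = length(mu)
      )
    }
  })
  structure(
    list(markers = fits, G_i = as.integer(G_i), seed = as.integer(seed),
         weight_tol = weight_tol),
    class = "shrinkage_model"
  )
}

#' @export
print.shrinkage_model <- function(x, ...) {
  gf <- vapply(x$markers, function(m) m$G_f, integer(1))
  cat(sprintf(
    "shrinkage_model: %d markers, G_i = %d, G_f in [%d, %d] (median %d)\n",
    length(gf), x$G_i, min(gf), max(gf), as.integer(stats::median(gf))
  ))
  invisible(x)
}

#' @export
summary.shrinkage_model <- function(object, ...) {
  df <- do.call(rbind, lapply(names(object$markers), function(nm) {
    m <- object$markers[[nm]]
    data.frame(marker = nm, component = seq_along(m$mean),
               mean = m$mean, sd = m$sd, weight = m$weight, G_f = m$G_f,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

# maximum-responsibility component per value; ties go to the lower-mean
# component (components are stored in increasing mean order)
.assign_component <- function(y, m) {
  k <- length(m$mean)
  if (k == 1L) return(rep(1L, length(y)))
  resp <- vapply(seq_len(k), function(i) {
    sd <- max(m$sd[i], 1e-9)
    m$weight[i] * stats::dnorm(y, m$mean[i], sd)
  }, numeric(length(y)))
  if (length(y) == 1L) resp <- matrix(resp, nrow = 1L)
  max.col(resp, ties.method = "first")
}

#' Apply lognormal shrinkage
#'
#' Each log-value `x` is assigned to its maximum-responsibility mixture
#' component with mean `mu_k` and replaced by `mu_k + (1 - lambda) * (x -
#' mu_k)`. `lambda = 0` is the identity on `log(1 + intensity)`; `lambda = 1`
#' collapses values to their component means; for `lambda < 1` the order of
#' values within a component is preserved.
#'
#' @param model a [fit_shrinkage()] model.
#' @param x intensity matrix or `cell_table` with the same marker set the
#'   model was fitted on.
#' @param lambda contraction factor in \[0, 1\] (default 0.8).
#' @return matrix of shrunk log-scale values (cells x markers).
#' @export
apply_shrinkage <- function(model, x, lambda = 0.8) {
  stopifnot(inherits(model, "shrinkage_model"))
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (inherits(x, "cell_table")) x <- ct_intensity_matrix(x)
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) == length(model$markers)) {
    colnames(x) <- names(model$markers)
  }
  if (!setequal(colnames(x), names(model$markers))) {
    stop("marker set does not match the fitted model")
  }
  out <- matrix(0, nrow(x), ncol(x),
                dimnames = list(rownames(x), names(model$markers)))
  for (nm in names(model$markers)) {
    y <- log1p(x[, nm])
    m <- model$markers[[nm]]
    comp <- .assign_component(y, m)
    mu <- m$mean[comp]
    out[, nm] <- mu + (1 - lambda) * (y - mu)
  }
  out
}

#' @export
predict.shrinkage_model <- function(object, newdata, lambda = 0.8, ...) {
  apply_shrinkage(object, newdata, lambda = lambda)
}

#' Serialize a shrinkage model to a component table file
#'
#' Writes one CSV row per (marker, component) with log-scale mean, sd and
#' weight, plus `G_i`/`G_f`, for audit; [read_shrinkage_model()] restores the
#' model.
#'
#' @param model a `shrinkage_model`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_shrinkage_model <- function(model, path) {
  df <- summary(model)
  df$G_i <- model$G_i
  df$seed <- model$seed
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shrinkage_model
#' @param path CSV written by [write_shrinkage_model()].
#' @export
read_shrinkage_model <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fits <- lapply(split(df, factor(df$marker, levels = unique(df$marker))),
                 function(d) {
    d <- d[order(d$mean), ]
    list(mean = d$mean, sd = d$sd, weight = d$weight, G_f = d$G_f[1])
  })
  structure(
    list(markers = fits, G_i = df$G_i[1], seed = df$seed[1],
         weight_tol = NA_real_),
    class = "shrinkage_model"
  )
}
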