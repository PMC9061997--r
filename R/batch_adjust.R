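# Empirical-Bayes location-scale batch correction for log-scale expression
# (the classical two-moment ComBat model: per-(gene,batch) additive shifts
# and multiplicative noise scales, shrunk toward batch-level priors).

#' Empirical-Bayes location/scale batch correction
#'
#' Fits the standard location-scale batch model on log-scale expression:
#' genes are standardized against the batch-weighted grand mean and pooled
#' residual variance, per-(gene,batch) location (`gamma`) and scale
#' (`delta^2`) effects are estimated and - when `parametric = TRUE` -
#' shrunk toward parametric priors (normal for location, inverse-gamma for
#' scale) with method-of-moments hyperparameters, iterated to convergence;
#' the batch effects are then removed. With `parametric = FALSE` the raw
#' per-batch estimates are used unshrunk, which in `location_only` mode
#' equalizes per-gene batch means exactly.
#'
#' @param expr genes x samples matrix; per-sample batch labels are taken
#'   from `attr(expr, "batch")` unless `batch` is given.
#' @param batch optional character/factor of per-sample batch labels.
#' @param mode `"location_scale"` (default) or `"location_only"` (scale
#'   effects fixed at 1).
#' @param parametric use parametric EB shrinkage (`TRUE`, default) or the
#'   unshrunk batch estimates (`FALSE`).
#' @param tol,max_iter convergence tolerance and iteration cap for the EB
#'   fixed-point updates.
#' @return list with `corrected` (same dimensions as `expr`, batch
#'   attribute preserved) and `model` (grand effects, pooled sds, raw and
#'   shrunk batch parameters, hyperparameters, and `flagged` genes left
#'   unadjusted for lack of within-batch variance).
#' @export
combat_adjust <- function(expr, batch = NULL,
                          mode = c("location_scale", "location_only"),
                          parametric = TRUE, tol = 1e-4, max_iter = 100L) {
  mode <- match.arg(mode)
  if (is.null(batch)) batch <- attr(expr, "batch")
  if (is.null(batch)) abort_icp("no batch labels supplied")
  batch <- as.character(batch)
  if (length(batch) != ncol(expr))
    abort_icp("batch labels do not match the number of samples")
  levels_b <- unique(batch)
  nb <- length(levels_b)
  if (nb == 1L) {
    warning("single batch: nothing to correct, returning input unchanged")
    return(list(corrected = expr, model = NULL))
  }
  n_per <- table(batch)
  if (any(n_per < 2L))
    abort_icp("batch(es) with a single sample: ",
              paste(names(n_per)[n_per < 2L], collapse = ", "))

  g <- nrow(expr); n <- ncol(expr)
  bidx <- lapply(levels_b, function(b) which(batch == b))

  batch_means <- vapply(bidx, function(ix)
    rowMeans(expr[, ix, drop = FALSE]), numeric(g))   # g x nb
  w <- as.numeric(n_per[levels_b]) / n
  alpha <- as.numeric(batch_means %*% w)
  resid <- expr - batch_means[, match(batch, levels_b)]
  var_pooled <- rowSums(resid^2) / n

  flagged <- which(var_pooled <= .Machine$double.eps)
  if (length(flagged))
    warning(length(flagged),
            " gene(s) constant within every batch left unadjusted")
  ok <- setdiff(seq_len(g), flagged)
  sigma <- sqrt(var_pooled)

  z <- expr
  z[ok, ] <- (expr[ok, , drop = FALSE] - alpha[ok]) / sigma[ok]

  gamma_hat <- vapply(bidx, function(ix)
    rowMeans(z[, ix, drop = FALSE]), numeric(g))
  delta_hat <- vapply(seq_len(nb), function(b) {
    ix <- bidx[[b]]
    rowSums((z[, ix, drop = FALSE] - gamma_hat[, b])^2) / (length(ix) - 1L)
  }, numeric(g))

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  hyper <- NULL
  if (parametric) {
    hyper <- vector("list", nb)
    for (b in seq_len(nb)) {
      gh <- gamma_hat[ok, b]; dh <- delta_hat[ok, b]
      gbar <- mean(gh); tau2 <- stats::var(gh)
      m <- mean(dh); s2 <- stats::var(dh)
      a_prior <- (2 * s2 + m^2) / s2          # inverse-gamma shape
      b_prior <- (m * s2 + m^3) / s2          # inverse-gamma rate
      nb_s <- length(bidx[[b]])
      gs <- gh; ds <- dh
      for (it in seq_len(max_iter)) {
        gs_new <- (nb_s * tau2 * gh + ds * gbar) / (nb_s * tau2 + ds)
        ss <- rowSums((z[ok, bidx[[b]], drop = FALSE] - gs_new)^2)
        ds_new <- (0.5 * ss + b_prior) / (nb_s / 2 + a_prior - 1)
        change <- max(abs(gs_new - gs) / (abs(gs) + 1e-12),
                      abs(ds_new - ds) / (abs(ds) + 1e-12))
        gs <- gs_new; ds <- ds_new
        if (change < tol) break
      }
      gamma_star[ok, b] <- gs
      delta_star[ok, b] <- ds
      hyper[[b]] <- list(gamma_bar = gbar, tau2 = tau2,
                         a_prior = a_prior, b_prior = b_prior,
                         iterations = it)
    }
    names(hyper) <- levels_b
  }
  if (mode == "location_only") delta_star[] <- 1

  corrected <- expr
  bmap <- match(batch, levels_b)
  adj <- (z[ok, , drop = FALSE] - gamma_star[ok, bmap, drop = FALSE]) /
    sqrt(delta_star[ok, bmap, drop = FALSE])
  corrected[ok, ] <- adj * sigma[ok] + alpha[ok]
  attr(corrected, "batch") <- attr(expr, "batch")

  dimnames(gamma_star) <- dimnames(delta_star) <-
    dimnames(gamma_hat) <- dimnames(delta_hat) <-
    list(rownames(expr), levels_b)
  list(corrected = corrected,
       model = list(alpha = stats::setNames(alpha, rownames(expr)),
                    sigma = stats::setNames(sigma, rownames(expr)),
                    gamma_hat = gamma_hat, delta_hat = delta_hat,
                    gamma_star = gamma_star, delta_star = delta_star,
                    hyper = hyper, mode = mode, parametric = parametric,
                    batches = levels_b,
                    flagged = rownames(expr)[flagged]))
}
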