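#' Specify PLS-PM measurement blocks
#'
#' Each latent variable is measured reflectively (mode A: outer weights are
#' manifest-latent correlations) by one or more manifest columns of the
#' data table. A manifest may appear in exactly one block.
#'
#' @param ... named character vectors: `latent_name = c("manifest", ...)`.
#' @return named list of class `block_spec`.
#' @export
plspm_blocks <- function(...) {
  blocks <- list(...)
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    stop("every block must be named")
  if (any(lengths(blocks) < 1L)) stop("every block needs >= 1 manifest")
  all_m <- unlist(blocks)
  if (anyDuplicated(all_m))
    stop("manifest(s) assigned to more than one block: ",
         paste(unique(all_m[duplicated(all_m)]), collapse = ", "))
  structure(blocks, class = "block_spec")
}

#' Specify the inner path matrix
#'
#' Square 0/1 matrix over the latents: `paths[i, j] = 1` means latent `j`
#' is a direct predecessor of latent `i`. Must be strictly lower-triangular
#' under the declared latent ordering (acyclic by construction) with at
#' least one endogenous latent.
#'
#' @param blocks a [plspm_blocks()] spec (defines the latent ordering).
#' @param edges list of `c(from, to)` character pairs.
#' @return 0/1 matrix with latent names on both dimensions.
#' @export
plspm_paths <- function(blocks, edges) {
  latents <- names(blocks)
  m <- matrix(0, length(latents), length(latents),
              dimnames = list(latents, latents))
  for (e in edges) {
    if (length(e) != 2L || !all(e %in% latents))
      stop("each edge must be c(from, to) over declared latents")
    m[e[2L], e[1L]] <- 1
  }
  if (any(m[upper.tri(m, diag = TRUE)] != 0))
    stop("path matrix must be strictly lower-triangular under the block ordering")
  if (all(rowSums(m) == 0)) stop("need at least one endogenous latent")
  m
}

standardize_cols <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv == 0))
    stop("constant manifest column(s): ",
         paste(colnames(x)[sdv == 0], collapse = ", "))
  scale(x, center = mu, scale = sdv)
}

#' Fit a partial least squares path model
#'
#' Manifests are standardized; outer weights start at 1; the algorithm
#' alternates inner estimation (centroid scheme by default: adjacent latent
#' scores combined with the signs of their correlations) and mode-A outer
#' estimation (weights = correlations of a block's manifests with its inner
#' estimate), rescaling latent scores to zero mean and unit variance, until
#' the largest absolute change in normalized outer weights drops below
#' `tol`. Path coefficients are then ordinary least squares of each
#' endogenous latent on its predecessors; loadings are manifest-latent
#' correlations; block communality is the mean squared loading.
#'
#' @param data data.frame/matrix containing every manifest column.
#' @param blocks a [plspm_blocks()] spec.
#' @param paths a path matrix from [plspm_paths()].
#' @param scheme inner weighting scheme: `"centroid"` (default),
#'   `"factorial"`, or `"path"`.
#' @param max_iter,tol iteration control.
#' @return object of class `plspm_result`: `scores` (n x latents, mean 0
#'   sd 1), `outer_weights`, `loadings`, `path_coefficients` (data.frame
#'   `from`, `to`, `coefficient`), `path_matrix` (coefficients in matrix
#'   form), `r_squared` (per endogenous latent), `communality` (per
#'   block), `gof`, `iterations`, `converged`, `last_delta`.
#' @export
fit_plspm <- function(data, blocks, paths,
                      scheme = c("centroid", "factorial", "path"),
                      max_iter = 300L, tol = 1e-7) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(blocks, "block_spec"))
  latents <- names(blocks)
  if (!identical(rownames(paths), latents) ||
      !identical(colnames(paths), latents))
    stop("path matrix dimnames must match the block names")
  data <- as.data.frame(data)
  miss <- setdiff(unlist(blocks), names(data))
  if (length(miss)) stop("manifest(s) absent: ", paste(miss, collapse = ", "))
  n <- nrow(data)
  max_pred <- max(rowSums(paths))
  if (n < max_pred + 2L)
    stop("need n >= (number of predecessors of any latent) + 2")
  X <- lapply(blocks, function(m) standardize_cols(as.matrix(data[, m, drop = FALSE])))
  adj <- (paths + t(paths)) > 0
  if (any(rowSums(adj) == 0))
    stop("latent(s) not connected to any other: ",
         paste(latents[rowSums(adj) == 0], collapse = ", "))

  norm_score <- function(v) (v - mean(v)) / stats::sd(v)
  w <- lapply(X, function(x) {
    wi <- rep(1, ncol(x))
    # normalize so the implied score has unit variance
    wi / stats::sd(as.numeric(x %*% wi))
  })
  Y <- mapply(function(x, wi) norm_score(as.numeric(x %*% wi)), X, w)
  colnames(Y) <- latents

  iter <- 0L
  delta <- Inf
  repeat {
    iter <- iter + 1L
    R <- stats::cor(Y)
    Z <- matrix(0, n, length(latents), dimnames = list(NULL, latents))
    for (b in seq_along(latents)) {
      nb <- which(adj[b, ])
      e <- switch(scheme,
        centroid  = sign(R[b, nb]),
        factorial = R[b, nb],
        path = {
          preds <- which(paths[b, ] > 0)
          succs <- setdiff(nb, preds)
          ee <- numeric(length(nb)); names(ee) <- latents[nb]
          if (length(preds)) {
            cf <- stats::lm.fit(Y[, preds, drop = FALSE], Y[, b])$coefficients
            ee[latents[preds]] <- cf
          }
          if (length(succs)) ee[latents[succs]] <- R[b, succs]
          ee
        })
      Z[, b] <- Y[, nb, drop = FALSE] %*% as.numeric(e)
    }
    w_new <- vector("list", length(latents))
    for (b in seq_along(latents)) {
      wb <- as.numeric(stats::cor(X[[b]], Z[, b]))   # mode A
      wb <- wb / stats::sd(as.numeric(X[[b]] %*% wb))
      w_new[[b]] <- wb
    }
    delta <- max(abs(unlist(w_new) - unlist(w)))
    w <- w_new
    Y <- mapply(function(x, wi) norm_score(as.numeric(x %*% wi)), X, w)
    colnames(Y) <- latents
    if (delta < tol || iter >= max_iter) break
  }
  converged <- delta < tol
  if (!converged)
    warning(sprintf("PLS-PM did not converge in %d iterations (last delta %.3g)",
                    iter, delta))

  # sign convention: each latent points in the direction of its manifests
  for (b in seq_along(latents)) {
    ld <- as.numeric(stats::cor(X[[b]], Y[, b]))
    if (sum(ld) < 0) {
      Y[, b] <- -Y[, b]
      w[[b]] <- -w[[b]]
    }
  }
  loadings <- lapply(seq_along(latents), function(b) {
    ld <- as.numeric(stats::cor(X[[b]], Y[, b]))
    names(ld) <- colnames(X[[b]])
    ld
  })
  names(loadings) <- names(w) <- latents

  endo <- latents[rowSums(paths) > 0]
  path_mat <- matrix(0, length(latents), length(latents),
                     dimnames = dimnames(paths))
  r2 <- stats::setNames(numeric(length(endo)), endo)
  coef_rows <- list()
  for (b in endo) {
    preds <- latents[paths[b, ] > 0]
    Xp <- Y[, preds, drop = FALSE]
    qr_p <- qr(Xp)
    if (qr_p$rank < length(preds))
      stop("singular predecessor set for latent '", b, "'")
    beta <- qr.coef(qr_p, Y[, b])
    fittedv <- as.numeric(Xp %*% beta)
    r2[b] <- 1 - sum((Y[, b] - fittedv)^2) / sum(Y[, b]^2)
    path_mat[b, preds] <- beta
    for (p in preds)
      coef_rows[[length(coef_rows) + 1L]] <-
        data.frame(from = p, to = b, coefficient = unname(beta[p]),
                   stringsAsFactors = FALSE)
  }
  communality <- vapply(loadings, function(ld) mean(ld^2), numeric(1))
  res <- structure(
    list(scores = Y, outer_weights = w, loadings = loadings,
         path_coefficients = do.call(rbind, coef_rows),
         path_matrix = path_mat, r_squared = r2,
         communality = communality, blocks = blocks, paths = paths,
         scheme = scheme, iterations = iter, converged = converged,
         last_delta = delta),
    class = "plspm_result"
  )
  res$gof <- gof(res)
  res
}

#' Goodness of fit of a PLS path model
#'
#' `sqrt(mean(communality) * mean(R^2))`, where the communality mean runs
#' over blocks with more than one manifest (a single-indicator block
#' measures its latent exactly, communality 1, and is excluded; if all
#' blocks are single-indicator the communality term is 1) and the R-squared
#' mean runs over the endogenous latents.
#'
#' @param result a `plspm_result`.
#' @return GoF in \[0, 1\].
#' @export
gof <- function(result) {
  stopifnot(inherits(result, "plspm_result"))
  multi <- lengths(result$blocks) > 1L
  mean_comm <- if (any(multi)) mean(result$communality[multi]) else 1
  sqrt(mean_comm * mean(result$r_squared))
}

#' @export
print.plspm_result <- function(x, ...) {
  cat(sprintf("PLS path model (%s scheme): %d latents, %d iterations%s\n",
              x$scheme, length(x$blocks), x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  cat("Path coefficients:\n")
  print(x$path_coefficients, row.names = FALSE)
  cat(sprintf("R-squared: %s\n",
              paste(sprintf("%s=%.3f", names(x$r_squared), x$r_squared),
                    collapse = ", ")))
  cat(sprintf("GoF: %.3f\n", x$gof))
  invisible(x)
}

#' Bootstrap significance of PLS-PM path coefficients
#'
#' Resamples rows with replacement, refits the model, and summarises each
#' path coefficient's bootstrap distribution: percentile 95% confidence
#' interval and a two-sided p-value from the tail fraction on the opposite
#' side of zero. Deterministic under a fixed seed. Aborts if more than 20%
#' of refits fail.
#'
#' @param data,blocks,paths,scheme as in [fit_plspm()].
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param conf confidence level for the percentile interval.
#' @return data.frame with `from`, `to`, `estimate`, `ci_lower`,
#'   `ci_upper`, `p_value`, `flag` (`"*"` if p < 0.05 else `"ns"`).
#' @export
bootstrap_paths <- function(data, blocks, paths, scheme = "centroid",
                            n_boot = 500L, seed = 1L, conf = 0.95) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  data <- as.data.frame(data)
  fit0 <- fit_plspm(data, blocks, paths, scheme)
  key <- paste(fit0$path_coefficients$from, fit0$path_coefficients$to,
               sep = "->")
  draws <- with_seed(seed, {
    idx <- replicate(n_boot, sample.int(nrow(data), replace = TRUE),
                     simplify = FALSE)
    lapply(idx, function(i) {
      tryCatch(suppressWarnings({
        f <- fit_plspm(data[i, , drop = FALSE], blocks, paths, scheme)
        stats::setNames(f$path_coefficients$coefficient,
                        paste(f$path_coefficients$from,
                              f$path_coefficients$to, sep = "->"))[key]
      }), error = function(e) NULL)
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  if (mean(!ok) > 0.2)
    stop(sprintf("bootstrap refit failure rate %.0f%% exceeds 20%%",
                 100 * mean(!ok)))
  B <- do.call(rbind, draws[ok])
  alpha2 <- (1 - conf) / 2
  out <- fit0$path_coefficients
  out$estimate <- out$coefficient
  out$coefficient <- NULL
  out$ci_lower <- apply(B, 2, stats::quantile, alpha2)
  out$ci_upper <- apply(B, 2, stats::quantile, 1 - alpha2)
  p <- vapply(seq_along(key), function(j) {
    b <- B[, j]
    2 * min(mean(b <= 0), mean(b >= 0))
  }, numeric(1))
  out$p_value <- pmax(p, 2 / (sum(ok) + 1))
  out$flag <- ifelse(out$p_value < 0.05, "*", "ns")
  rownames(out) <- NULL
  out
}
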