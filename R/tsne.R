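# Exact (dense) t-SNE for the embedding maps. Perplexity calibration by
# per-point bisection, early exaggeration, momentum gradient descent — the
# classic algorithm, adequate for the few hundred points the audit plots.

tsne_affinities <- function(x, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- d2[i, -i]
    for (iter in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { h <- 0; pr <- w }
      else {
        pr <- w / sw
        h <- -sum(pr[pr > 0] * log(pr[pr > 0]))
      }
      diff <- h - log_u
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    p[i, -i] <- pr
  }
  p <- (p + t(p)) / (2 * n)
  pmax(p, 1e-12)
}

#' Two-dimensional t-SNE map of embeddings
#'
#' @param emb Embedding tibble from [extract_embeddings()], or a numeric
#'   matrix.
#' @param seed Integer seed (fixed seed gives identical coordinates).
#' @param perplexity t-SNE perplexity; needs at least `3 * perplexity`
#'   samples.
#' @param n_iter Gradient-descent iterations.
#' @return A tibble with `dim1`, `dim2` plus any label columns of `emb`,
#'   classed `voiceda_tsne` for [autoplot.voiceda_tsne()].
#' @export
tsne_map <- function(emb, seed = 1L, perplexity = 30, n_iter = 400) {
  meta <- NULL
  if (is.data.frame(emb)) {
    meta <- dplyr::select(emb, -"embedding")
    x <- embedding_matrix(emb)
  } else {
    x <- as.matrix(emb)
  }
  n <- nrow(x)
  stop_if_not(n >= 3 * perplexity,
              "need at least 3 * perplexity = ", 3 * perplexity,
              " samples, got ", n)
  p <- tsne_affinities(x, perplexity)
  with_seed(seed, {
    y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    vel <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (iter in seq_len(n_iter)) {
      exag <- if (iter <= 100) 4 else 1
      mom <- if (iter <= 250) 0.5 else 0.8
      d2 <- as.matrix(stats::dist(y))^2
      num <- 1 / (1 + d2)
      diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      l <- (exag * p - q) * num
      grad <- 4 * (diag(rowSums(l)) - l) %*% y
      gains <- ifelse(sign(grad) != sign(vel), gains + 0.2, gains * 0.8)
      gains <- pmax(gains, 0.01)
      vel <- mom * vel - 200 * gains * grad
      y <- y + vel
      y <- sweep(y, 2, colMeans(y), "-")
    }
    out <- tibble::tibble(dim1 = y[, 1], dim2 = y[, 2])
    if (!is.null(meta)) out <- dplyr::bind_cols(meta, out)
    class(out) <- c("voiceda_tsne", class(out))
    attr(out, "seed") <- seed
    attr(out, "perplexity") <- perplexity
    out
  })
}
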