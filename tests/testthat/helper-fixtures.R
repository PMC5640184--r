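# Builders for small in-memory fixtures shared across the suite.

make_sheet <- function(m, distances = NULL) {
  n_post <- m %/% 2
  n_pre <- m - n_post
  subj <- sprintf("s%02d", c(seq_len(n_pre), seq_len(n_post)))
  if (is.null(distances)) distances <- seq(20, 80, length.out = n_post)
  tibble::tibble(
    sample_id = paste0(subj, rep(c("_PRE", "_POST"), c(n_pre, n_post))),
    subject_id = subj,
    timepoint = rep(c("pre", "post"), c(n_pre, n_post)),
    gender = rep(c("male", "female"), length.out = m),
    distance_km = c(rep(0, n_pre), distances)
  )
}

make_expr <- function(values = NULL, n = 10, m = 6, seed = 1) {
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(rnorm(n * m, mean = 7), n, m)
  }
  n <- nrow(values)
  m <- ncol(values)
  dimnames(values) <- list(sprintf("f%03d", seq_len(n)), NULL)
  sheet <- make_sheet(m)
  colnames(values) <- sheet$sample_id
  expr_set(values, sheet)
}

# independent step-up BH oracle (direct implementation of the definition)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running_min, 1)
  }
  adj
}

# exhaustive hypergeometric upper tail by direct enumeration
hyper_tail_oracle <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# match recovered sources to planted activations by maximal |correlation|
# (greedy assignment); returns the matched |r| per planted source
match_sources <- function(recovered, planted) {
  r <- abs(stats::cor(recovered, planted))
  out <- numeric(ncol(planted))
  for (j in seq_len(ncol(planted))) {
    idx <- which(r == max(r), arr.ind = TRUE)[1, ]
    out[idx[2]] <- r[idx[1], idx[2]]
    r[idx[1], ] <- -1
    r[, idx[2]] <- -1
  }
  out
}
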