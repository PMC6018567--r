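# shared fixtures and independent oracles

test_affine <- function(mm = 2) {
  rbind(c(mm, 0, 0, -10), c(0, mm, 0, -10), c(0, 0, mm, -10), c(0, 0, 0, 1))
}

box_array <- function(dim3, lo, hi, value = 1) {
  a <- array(0, dim3)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- value
  a
}

rand_scores <- function(n) {
  data.frame(spk_pn = rnorm(n, 60, 8), writt_pn = rnorm(n, 58, 7),
             rep_n = rnorm(n, 55, 6), sem_m = rnorm(n, 56, 5),
             cspk_w = rnorm(n, 57, 5), writt_copy = rnorm(n, 58, 4))
}

# build a cohort directly from a lesion matrix (rows = patients)
make_cohort <- function(lesions, dim3, scores, kind = "binary", mm = 2) {
  iterlesion:::new_cohort(sprintf("p%02d", seq_len(nrow(lesions))),
                          lesions, dim3, test_affine(mm), kind, scores,
                          rowSums(lesions > 0.3) * mm^3 / 1000)
}

# dense random cohort: every voxel lesioned in most patients (full mask)
random_cohort <- function(n = 8, dim3 = c(4, 4, 4), seed = 1,
                          kind = "fuzzy") {
  set.seed(seed)
  les <- matrix(runif(n * prod(dim3)), n, prod(dim3))
  if (kind == "binary") les <- (les > 0.4) * 1
  make_cohort(les, dim3, rand_scores(n), kind)
}

full_mask <- function(cohort) {
  build_analysis_mask(overlap_map(cohort), min_overlap = 1L)
}

## --- independent oracles -------------------------------------------------

# normal-equations OLS contrast t for a single response vector
ols_t_oracle <- function(y, X, cvec) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- length(y) - qr(X)$rank
  s2 <- sum(res^2) / df
  drop(crossprod(cvec, b)) / sqrt(s2 * drop(t(cvec) %*% solve(XtX) %*% cvec))
}

# Heap's algorithm: all permutations of 1..n (independent of the package's
# recursive enumerator)
heap_perms <- function(n) {
  out <- matrix(0L, factorial(n), n)
  a <- seq_len(n); c_ <- integer(n); k <- 1L
  out[k, ] <- a
  i <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) a[c(1L, i)] <- a[c(i, 1L)]
      else {
        j <- c_[i] + 1L
        a[c(j, i)] <- a[c(i, j)]
      }
      k <- k + 1L
      out[k, ] <- a
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# exhaustive Freedman-Lane maxT p-values via lm() refits (slow, tiny n only)
fl_maxT_oracle <- function(Y, X, cvec) {
  n <- nrow(Y)
  Z <- X[, cvec == 0, drop = FALSE]
  Yr <- apply(Y, 2L, function(y) stats::residuals(stats::lm.fit(Z, y)))
  P <- heap_perms(n)
  tmat <- matrix(0, nrow(P), ncol(Y))
  for (i in seq_len(nrow(P))) {
    Yp <- Yr[P[i, ], , drop = FALSE]
    for (v in seq_len(ncol(Y)))
      tmat[i, v] <- ols_t_oracle(Yp[, v], X, cvec)
  }
  maxT <- apply(tmat, 1L, max)
  t_obs <- vapply(seq_len(ncol(Y)), function(v) ols_t_oracle(Y[, v], X, cvec),
                  numeric(1))
  # ties count as exceedances, at the same 1e-8 comparison tolerance the
  # package documents
  vapply(t_obs, function(tt) mean(maxT >= tt - 1e-8 * max(1, abs(tt))),
         numeric(1))
}

# BFS connected components, 26-neighbourhood (O(m^2), tiny sets only)
bfs_components <- function(idx, dim3) {
  m <- length(idx)
  if (m == 0L) return(integer(0))
  co <- arrayInd(idx, dim3)
  lab <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (w in seq_len(m)) {
        if (lab[w] == 0L && max(abs(co[v, ] - co[w, ])) <= 1L) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# same partition up to label renaming?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, `==`) == outer(b, b, `==`))
}
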