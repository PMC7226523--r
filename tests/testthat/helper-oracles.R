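# Independent brute-force oracles and fixture builders. These are written
# directly from the definitions (pair enumeration, direct convolution, flood
# fill) and deliberately share no code with the package implementations.

DIRS13 <- rbind(
  c(1,0,0), c(0,1,0), c(0,0,1),
  c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
  c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))

bf_concordance <- function(r, t, e) {
  num <- 0; den <- 0
  n <- length(r)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (t[i] == t[j]) next
    s <- if (t[i] < t[j]) i else j
    l <- if (s == i) j else i
    if (!e[s]) next
    den <- den + 1
    num <- num + if (r[s] > r[l]) 1 else if (r[s] == r[l]) 0.5 else 0
  }
  if (den == 0) NA_real_ else num / den
}

bf_auc <- function(s, y) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

bf_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# symmetric co-occurrence counts by direct voxel-pair enumeration
bf_glcm <- function(lev, ng) {
  d <- dim(lev)
  out <- array(0, c(ng, ng, 13))
  for (dd in 1:13) {
    off <- DIRS13[dd, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lev[x, y, z]
      if (a == 0) next
      p <- c(x, y, z) + off
      if (any(p < 1) || any(p > d)) next
      b <- lev[p[1], p[2], p[3]]
      if (b == 0) next
      out[a, b, dd] <- out[a, b, dd] + 1
      out[b, a, dd] <- out[b, a, dd] + 1
    }
  }
  out
}

# run-length counts by walking maximal straight same-level segments
bf_glrlm <- function(lev, ng) {
  d <- dim(lev)
  maxrun <- max(d)
  out <- array(0, c(ng, maxrun, 13))
  inside <- function(p) all(p >= 1) && all(p <= d)
  for (dd in 1:13) {
    off <- DIRS13[dd, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lev[x, y, z]
      if (a == 0) next
      prev <- c(x, y, z) - off
      if (inside(prev) && lev[prev[1], prev[2], prev[3]] == a) next
      len <- 1
      cur <- c(x, y, z) + off
      while (inside(cur) && lev[cur[1], cur[2], cur[3]] == a) {
        len <- len + 1
        cur <- cur + off
      }
      out[a, len, dd] <- out[a, len, dd] + 1
    }
  }
  out
}

# size-zone counts by recursive flood fill over the 26-neighborhood
bf_glszm <- function(lev, ng) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  zones <- list()
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || lev[x, y, z] == 0) next
    a <- lev[x, y, z]
    queue <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (k in seq_len(nrow(nb))) {
        p <- v + nb[k, ]
        if (any(p < 1) || any(p > d)) next
        if (!seen[p[1], p[2], p[3]] && lev[p[1], p[2], p[3]] == a) {
          seen[p[1], p[2], p[3]] <- TRUE
          queue[[length(queue) + 1]] <- p
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  maxsize <- max(vapply(zones, `[`, numeric(1), 2))
  out <- matrix(0, ng, maxsize)
  for (zn in zones) out[zn[1], zn[2]] <- out[zn[1], zn[2]] + 1
  out
}

# direct circular correlation with a centered separable kernel
bf_sepconv <- function(vol, fx, fy, fz) {
  d <- dim(vol)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  apply1 <- function(v, f, axis) {
    out <- array(0, d)
    cc <- (length(f) - 1) %/% 2
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      acc <- 0
      for (k in seq_along(f)) {
        p <- c(x, y, z)
        p[axis] <- wrap(p[axis] + k - 1 - cc, d[axis])
        acc <- acc + f[k] * v[p[1], p[2], p[3]]
      }
      out[x, y, z] <- acc
    }
    out
  }
  apply1(apply1(apply1(vol, fx, 1), fy, 2), fz, 3)
}

digital_ball <- function(r_vox, dm = 2 * r_vox + 7) {
  ctr <- (dm + 1) / 2
  b <- array(0L, c(dm, dm, dm))
  for (i in 1:dm) for (j in 1:dm) for (k in 1:dm)
    if ((i - ctr)^2 + (j - ctr)^2 + (k - ctr)^2 <= r_vox^2) b[i, j, k] <- 1L
  b
}

as_roi <- function(lev) {
  structure(list(levels = lev, n_levels = max(lev), bin_width = 1,
                 min_intensity = 0), class = "discretized_roi")
}

random_roi <- function(d = c(5, 5, 5), ng = 3, p_mask = 0.8) {
  lev <- array(0L, d)
  inside <- array(runif(prod(d)) < p_mask, d)
  lev[inside] <- sample.int(ng, sum(inside), replace = TRUE)
  if (all(lev == 0)) lev[1, 1, 1] <- 1L
  lev
}

# small survival dataset with a planted linear hazard
surv_sim <- function(n, beta_sd = 1, censor_frac = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rnorm(n)
  eta <- beta_sd * x
  t_true <- rexp(n) / (0.01 * exp(eta))
  if (censor_frac > 0) {
    cmax <- uniroot(function(cc) mean(pmin(t_true / cc, 1)) - censor_frac,
                    c(min(t_true) / 100, max(t_true) * 100))$root
    cens <- runif(n, 0, cmax)
    list(x = x, time = pmin(t_true, cens), event = as.integer(t_true <= cens))
  } else list(x = x, time = t_true, event = rep(1L, n))
}
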