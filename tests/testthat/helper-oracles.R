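# Independent brute-force oracles used to validate the texture features,
# the AUC and the KNN scores. Everything here is written as plain double
# loops over definitions, deliberately sharing no code with the package
# implementation.

oracle_glcm <- function(levels, G, offset) {
  nr <- nrow(levels); nc <- ncol(levels)
  P <- matrix(0, G, G)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      r2 <- r + offset[1]; c2 <- cc + offset[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        P[levels[r, cc], levels[r2, c2]] <- P[levels[r, cc], levels[r2, c2]] + 1
      }
    }
  }
  P / sum(P)
}

oracle_haralick_one <- function(P) {
  G <- nrow(P)
  px <- numeric(G); py <- numeric(G)
  for (i in 1:G) for (j in 1:G) { px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j] }
  mux <- sum((1:G) * px); muy <- sum((1:G) * py)
  sdx <- sqrt(sum(((1:G) - mux)^2 * px)); sdy <- sqrt(sum(((1:G) - muy)^2 * py))
  lg <- function(v) if (v > 0) log(v) else 0

  asm <- 0; contrast <- 0; corr_num <- 0; vari <- 0; idm <- 0; ent <- 0
  hxy1 <- 0; hxy2 <- 0
  psum <- numeric(2 * G); pdiff <- numeric(G)  # indices k and d+1
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    corr_num <- corr_num + i * j * p
    vari <- vari + (i - mux)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    ent <- ent - p * lg(p)
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
    if (px[i] * py[j] > 0) {
      hxy1 <- hxy1 - p * log(px[i] * py[j])
      hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
    }
  }
  correlation <- if (sdx > 0 && sdy > 0) (corr_num - mux * muy) / (sdx * sdy) else 0
  sa <- 0; for (k in 2:(2 * G)) sa <- sa + k * psum[k]
  sv <- 0; for (k in 2:(2 * G)) sv <- sv + (k - sa)^2 * psum[k]
  se <- 0; for (k in 2:(2 * G)) se <- se - psum[k] * lg(psum[k])
  dmu <- 0; for (d in 0:(G - 1)) dmu <- dmu + d * pdiff[d + 1]
  dv <- 0; for (d in 0:(G - 1)) dv <- dv + (d - dmu)^2 * pdiff[d + 1]
  de <- 0; for (d in 0:(G - 1)) de <- de - pdiff[d + 1] * lg(pdiff[d + 1])
  hx <- 0; hy <- 0
  for (i in 1:G) { hx <- hx - px[i] * lg(px[i]); hy <- hy - py[i] * lg(py[i]) }
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))

  keep_r <- which(px > 0); keep_c <- which(py > 0)
  mcc <- 0
  if (length(keep_r) >= 2 && length(keep_c) >= 2) {
    Q <- matrix(0, length(keep_r), length(keep_r))
    for (a in seq_along(keep_r)) for (b in seq_along(keep_r)) {
      i <- keep_r[a]; j <- keep_r[b]
      s <- 0
      for (kk in keep_c) s <- s + P[i, kk] * P[j, kk] / (px[i] * py[kk])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2) mcc <- sqrt(max(0, ev[2]))
  }
  c(asm, contrast, correlation, vari, idm, sa, sv, se, ent, dv, de,
    imc1, imc2, mcc)
}

oracle_glrlm <- function(levels, G, direction) {
  # collect maximal runs along scan lines
  lines <- list()
  if (direction[1] == 0) {
    for (r in seq_len(nrow(levels))) lines[[r]] <- levels[r, ]
  } else {
    for (cc in seq_len(ncol(levels))) lines[[cc]] <- levels[, cc]
  }
  lmax <- length(lines[[1]])
  R <- matrix(0, G, lmax)
  for (ln in lines) {
    if (direction[1] < 0 || direction[2] < 0) ln <- rev(ln)
    i <- 1
    while (i <= length(ln)) {
      j <- i
      while (j < length(ln) && ln[j + 1] == ln[i]) j <- j + 1
      R[ln[i], j - i + 1] <- R[ln[i], j - i + 1] + 1
      i <- j + 1
    }
  }
  R
}

oracle_glrl_one <- function(R, np) {
  G <- nrow(R); L <- ncol(R)
  nr <- sum(R)
  f <- numeric(11)
  for (i in 1:G) for (j in 1:L) {
    r <- R[i, j]
    if (r == 0) next
    f[1] <- f[1] + r / j^2
    f[2] <- f[2] + r * j^2
    f[6] <- f[6] + r / i^2
    f[7] <- f[7] + r * i^2
    f[8] <- f[8] + r / (i^2 * j^2)
    f[9] <- f[9] + r * i^2 / j^2
    f[10] <- f[10] + r * j^2 / i^2
    f[11] <- f[11] + r * i^2 * j^2
  }
  for (i in 1:G) f[3] <- f[3] + sum(R[i, ])^2
  for (j in 1:L) f[4] <- f[4] + sum(R[, j])^2
  f[c(1:4, 6:11)] <- f[c(1:4, 6:11)] / nr
  f[5] <- nr / np
  f
}

# 25 texture features (11 GLRL + 14 Haralick) averaged over the four
# directions, straight from the definitions.
oracle_texture_features <- function(pixels, G) {
  lo <- min(pixels); hi <- max(pixels)
  if (hi == lo) {
    lev <- matrix(1L, nrow(pixels), ncol(pixels))
  } else {
    lev <- pmin(floor(G * (pixels - lo) / (hi - lo)) + 1, G)
  }
  offs <- list(c(0, 1), c(-1, 0), c(0, -1), c(1, 0))
  glrl <- 0; har <- 0
  for (off in offs) {
    glrl <- glrl + oracle_glrl_one(oracle_glrlm(lev, G, off), length(lev))
    har <- har + oracle_haralick_one(oracle_glcm(lev, G, off))
  }
  c(glrl / 4, har / 4)
}

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1 else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# Brute-force KNN score: explicit correlation distances, full sort with
# index tie-break.
oracle_knn_score <- function(Xtr, ytr, x, k) {
  d <- numeric(nrow(Xtr))
  for (t in seq_len(nrow(Xtr))) {
    u <- as.numeric(x); v <- as.numeric(Xtr[t, ])
    if (length(u) == 1) {
      d[t] <- abs(u - v)
    } else if (stats::sd(u) == 0 || stats::sd(v) == 0) {
      d[t] <- 1
    } else {
      d[t] <- 1 - stats::cor(u, v)
    }
  }
  nb <- order(d, seq_along(d))[1:k]
  mean(ytr[nb])
}

# Manual linear-interpolation percentile: h = (n-1)p + 1 on the sorted
# sample.
oracle_percentile <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}
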