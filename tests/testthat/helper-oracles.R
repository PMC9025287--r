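# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles with naive loops so they share no code
# path with the package implementation.

oracle_directions <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    o <- c(dx, dy, dz)
    if (all(o == 0)) next
    nz <- o[o != 0]
    if (nz[1] > 0) out[[length(out) + 1]] <- o
  }
  out
}

# GLCM by exhaustive neighbor-pair enumeration; features from the textbook
# formulas, one direction at a time, then averaged.
oracle_glcm <- function(labels) {
  g <- sort(unique(labels[labels > 0]))
  ng <- length(g)
  d <- dim(labels)
  per_dir <- list()
  for (o in oracle_directions()) {
    C <- matrix(0, ng, ng)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      a <- labels[i, j, k]
      if (a == 0) next
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 ||
          kk > d[3]) next
      b <- labels[ii, jj, kk]
      if (b == 0) next
      C[match(a, g), match(b, g)] <- C[match(a, g), match(b, g)] + 1
    }
    C <- C + t(C)
    if (sum(C) == 0) next
    per_dir[[length(per_dir) + 1]] <- C / sum(C)
  }
  feats <- sapply(per_dir, function(p) {
    px <- rowSums(p); py <- colSums(p)
    mux <- 0; muy <- 0
    for (i in 1:ng) { mux <- mux + g[i] * px[i]; muy <- muy + g[i] * py[i] }
    s2x <- sum((g - mux)^2 * px); s2y <- sum((g - muy)^2 * py)
    auto <- 0; prom <- 0; shade <- 0; tend <- 0; ctr <- 0
    idv <- 0; idmv <- 0; idmn <- 0; idn <- 0; invvar <- 0
    je <- 0; jent <- 0; maxp <- 0
    for (i in 1:ng) for (j in 1:ng) {
      pij <- p[i, j]
      auto <- auto + pij * g[i] * g[j]
      s <- g[i] + g[j] - mux - muy
      prom <- prom + pij * s^4; shade <- shade + pij * s^3
      tend <- tend + pij * s^2
      dd <- abs(g[i] - g[j])
      ctr <- ctr + pij * dd^2
      idv <- idv + pij / (1 + dd)
      idmv <- idmv + pij / (1 + dd^2)
      idmn <- idmn + pij / (1 + dd^2 / ng^2)
      idn <- idn + pij / (1 + dd / ng)
      if (dd > 0) invvar <- invvar + pij / dd^2
      je <- je + pij^2
      if (pij > 0) jent <- jent - pij * log2(pij)
      maxp <- max(maxp, pij)
    }
    kd <- 0:(max(g) - min(g))
    pd <- sapply(kd, function(v) {
      s <- 0
      for (i in 1:ng) for (j in 1:ng)
        if (abs(g[i] - g[j]) == v) s <- s + p[i, j]
      s
    })
    ks <- (2 * min(g)):(2 * max(g))
    ps <- sapply(ks, function(v) {
      s <- 0
      for (i in 1:ng) for (j in 1:ng)
        if (g[i] + g[j] == v) s <- s + p[i, j]
      s
    })
    da <- sum(kd * pd)
    dent <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
    dvar <- sum(pd * (kd - da)^2)
    sav <- sum(ks * ps)
    sent <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
    hx <- -sum(px[px > 0] * log2(px[px > 0]))
    hy <- -sum(py[py > 0] * log2(py[py > 0]))
    hxy1 <- 0; hxy2 <- 0
    for (i in 1:ng) for (j in 1:ng) {
      q <- px[i] * py[j]
      if (q > 0) {
        if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(q)
        hxy2 <- hxy2 - q * log2(q)
      }
    }
    corr <- if (s2x <= 0 || s2y <= 0) 1 else
      (auto - mux * muy) / sqrt(s2x * s2y)
    imc1 <- if (max(hx, hy) == 0) 0 else (jent - hxy1) / max(hx, hy)
    imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - jent))))
    keep <- px > 0 & py > 0
    mcc <- if (sum(keep) < 2) 1 else {
      pk <- p[keep, keep, drop = FALSE]
      pxk <- rowSums(pk); pyk <- colSums(pk)
      nk <- nrow(pk)
      Q <- matrix(0, nk, nk)
      for (i in 1:nk) for (j in 1:nk) {
        s <- 0
        for (m in 1:nk) s <- s + pk[i, m] * pk[j, m] / (pxk[i] * pyk[m])
        Q[i, j] <- s
      }
      ev <- sort(Re(eigen(Q)$values), decreasing = TRUE)
      sqrt(max(0, ev[2]))
    }
    c(Autocorrelation = auto, ClusterProminence = prom,
      ClusterShade = shade, ClusterTendency = tend, Contrast = ctr,
      Correlation = corr, DifferenceAverage = da,
      DifferenceEntropy = dent, DifferenceVariance = dvar, Id = idv,
      Idm = idmv, Idmn = idmn, Idn = idn, Imc1 = imc1, Imc2 = imc2,
      InverseVariance = invvar, JointAverage = mux, JointEnergy = je,
      JointEntropy = jent, MCC = mcc, MaximumProbability = maxp,
      SumAverage = sav, SumEntropy = sent, SumSquares = s2x)
  })
  rowMeans(feats)
}

# Flood-fill (explicit stack, 26-connectivity) zone decomposition and
# direct GLSZM formulas.
oracle_glszm <- function(labels) {
  d <- dim(labels)
  visited <- array(FALSE, d)
  zones <- data.frame(gray = integer(0), size = integer(0))
  offs <- expand.grid(-1:1, -1:1, -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (labels[i, j, k] == 0 || visited[i, j, k]) next
    gray <- labels[i, j, k]
    stack <- list(c(i, j, k))
    visited[i, j, k] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        w <- v + as.numeric(offs[r, ])
        if (any(w < 1) || any(w > d)) next
        if (visited[w[1], w[2], w[3]]) next
        if (labels[w[1], w[2], w[3]] != gray) next
        visited[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1]] <- w
      }
    }
    zones <- rbind(zones, data.frame(gray = gray, size = size))
  }
  nz <- nrow(zones); np <- sum(labels > 0)
  g <- zones$gray; s <- zones$size
  glev <- sort(unique(g)); slev <- sort(unique(s))
  pg <- sapply(glev, function(v) sum(g == v)) / nz
  ps <- sapply(slev, function(v) sum(s == v)) / nz
  mu_g <- sum(glev * pg); mu_s <- sum(slev * ps)
  cell <- numeric(0)
  for (gv in glev) for (sv in slev) {
    q <- sum(g == gv & s == sv) / nz
    if (q > 0) cell <- c(cell, q)
  }
  c(SmallAreaEmphasis = sum(1 / s^2) / nz,
    LargeAreaEmphasis = sum(s^2) / nz,
    GrayLevelNonUniformity = sum(sapply(glev, function(v)
      sum(g == v))^2) / nz,
    GrayLevelNonUniformityNormalized = sum(sapply(glev, function(v)
      sum(g == v))^2) / nz^2,
    SizeZoneNonUniformity = sum(sapply(slev, function(v)
      sum(s == v))^2) / nz,
    SizeZoneNonUniformityNormalized = sum(sapply(slev, function(v)
      sum(s == v))^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(pg * (glev - mu_g)^2),
    ZoneVariance = sum(ps * (slev - mu_s)^2),
    ZoneEntropy = -sum(cell * log2(cell)),
    LowGrayLevelZoneEmphasis = sum(1 / g^2) / nz,
    HighGrayLevelZoneEmphasis = sum(g^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(1 / (g^2 * s^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(g^2 / s^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(s^2 / g^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(g^2 * s^2) / nz)
}

# Mean silhouette by definition, all pairs.
oracle_silhouette <- function(x, cl) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in 1:n) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(sqrt(rowSums((x[own, , drop = FALSE] -
                              matrix(x[i, ], length(own), ncol(x),
                                     byrow = TRUE))^2)))
    b <- Inf
    for (g in setdiff(unique(cl), cl[i])) {
      oth <- which(cl == g)
      b <- min(b, mean(sqrt(rowSums((x[oth, , drop = FALSE] -
                                       matrix(x[i, ], length(oth), ncol(x),
                                              byrow = TRUE))^2))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_ch <- function(x, cl) {
  n <- nrow(x); k <- length(unique(cl))
  mu <- colMeans(x)
  B <- 0; W <- 0
  for (g in unique(cl)) {
    xg <- x[cl == g, , drop = FALSE]
    mg <- colMeans(xg)
    B <- B + nrow(xg) * sum((mg - mu)^2)
    for (r in seq_len(nrow(xg))) W <- W + sum((xg[r, ] - mg)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# Harrell's C by exhaustive pair enumeration.
oracle_c_index <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    # usable pair: i fails before j's observed time
    if (event[i] == 1 && (time[i] < time[j] ||
                          (time[i] == time[j] && event[j] == 0))) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# Newton-Raphson on the Breslow partial log-likelihood (no ties assumed
# beyond Breslow handling).
oracle_cox_newton <- function(x, time, event, tol = 1e-12, max_iter = 100) {
  x <- as.matrix(x)
  beta <- rep(0, ncol(x))
  for (it in 1:max_iter) {
    grad <- rep(0, ncol(x)); hess <- matrix(0, ncol(x), ncol(x))
    for (i in which(event == 1)) {
      rs <- which(time >= time[i])
      w <- exp(drop(x[rs, , drop = FALSE] %*% beta))
      xb <- colSums(x[rs, , drop = FALSE] * w) / sum(w)
      grad <- grad + x[i, ] - xb
      xx <- t(x[rs, , drop = FALSE] * w) %*% x[rs, , drop = FALSE] / sum(w)
      hess <- hess + xx - outer(xb, xb)
    }
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}
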