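# Independent brute-force oracles. These deliberately avoid the package's
# computational paths: path enumeration instead of forward-backward,
# explicit per-site loops instead of vectorised tallies.

# Exhaustive path-sum posterior over the diploid copying model.
# Returns site x 3 genotype posterior and the Viterbi (max) path.
oracle_hmm <- function(H, loggl, cm, rho_scale, mu) {
  K <- nrow(H); M <- ncol(H)
  states <- expand.grid(j = 1:K, k = 1:K)
  ns <- K * K
  lam <- c(0, 1 - exp(-rho_scale * diff(cm) / 100 / K))
  trans_mat <- function(l) {
    t1 <- matrix(lam[l] / K, K, K)
    diag(t1) <- 1 - lam[l] + lam[l] / K
    T2 <- matrix(0, ns, ns)
    for (a in 1:ns) for (b in 1:ns)
      T2[a, b] <- t1[states$j[a], states$j[b]] * t1[states$k[a], states$k[b]]
    T2
  }
  emis_terms <- function(l) {
    q <- mu + (1 - 2 * mu) * H[, l]
    e <- exp(loggl[l, ])
    t(sapply(1:ns, function(s) {
      qj <- q[states$j[s]]; qk <- q[states$k[s]]
      c(e[1] * (1 - qj) * (1 - qk),
        e[2] * ((1 - qj) * qk + qj * (1 - qk)),
        e[3] * qj * qk)
    }))
  }
  paths <- as.matrix(expand.grid(rep(list(1:ns), M)))
  lp <- rep(-log(ns), nrow(paths))
  eml <- lapply(1:M, emis_terms)
  for (l in 1:M) {
    lp <- lp + log(rowSums(eml[[l]])[paths[, l]])
    if (l > 1) {
      Tm <- trans_mat(l)
      lp <- lp + log(Tm[cbind(paths[, l - 1], paths[, l])])
    }
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  gp <- matrix(0, M, 3)
  for (l in 1:M) {
    post <- rep(0, ns)
    agg <- tapply(w, paths[, l], sum)
    post[as.integer(names(agg))] <- agg
    for (s in 1:ns) {
      w3 <- eml[[l]][s, ]
      gp[l, ] <- gp[l, ] + post[s] * w3 / sum(w3)
    }
  }
  best <- paths[which.max(lp), ]
  list(gp = gp, best_path = cbind(states$j[best], states$k[best]),
       best_logprob = max(lp))
}

# Per-read product genotype likelihood (n_alt alt reads, n_ref ref reads).
oracle_gl <- function(n_ref, n_alt, e) {
  p_alt <- c(e, 0.5, 1 - e)
  ll <- sapply(p_alt, function(p) {
    tot <- 0
    for (i in seq_len(n_alt)) tot <- tot + log(p)
    for (i in seq_len(n_ref)) tot <- tot + log(1 - p)
    tot
  })
  ll - max(ll)
}

# Naive per-site tally of matches/errors by validation class.
oracle_discordance <- function(imputed, validation) {
  counts <- c(m_rr = 0, m_ra = 0, m_aa = 0, e_rr = 0, e_ra = 0, e_aa = 0)
  missing <- 0
  for (i in seq_along(imputed)) {
    if (is.na(imputed[i]) || is.na(validation[i])) {
      missing <- missing + 1
      next
    }
    cls <- c("rr", "ra", "aa")[validation[i] + 1]
    key <- paste0(if (imputed[i] == validation[i]) "m_" else "e_", cls)
    counts[key] <- counts[key] + 1
  }
  list(counts = counts, missing = missing)
}

oracle_nrd <- function(counts) {
  err <- counts[["e_rr"]] + counts[["e_ra"]] + counts[["e_aa"]]
  den <- counts[["m_ra"]] + counts[["m_aa"]] + err
  if (den == 0) NA_real_ else err / den
}

oracle_het_retention <- function(pre_missing, post_missing, gt, validation) {
  kept <- tot <- 0
  for (i in seq_along(gt)) {
    if (!pre_missing[i] && !is.na(validation[i]) &&
        gt[i] == 1 && validation[i] == 1) {
      tot <- tot + 1
      if (!post_missing[i]) kept <- kept + 1
    }
  }
  if (tot == 0) NA_real_ else kept / tot
}

oracle_pairwise <- function(target, g) {
  sapply(seq_len(nrow(g)), function(i) {
    s <- 0; n <- 0
    for (l in seq_along(target)) {
      if (!is.na(target[l]) && !is.na(g[i, l])) {
        s <- s + abs(target[l] - g[i, l])
        n <- n + 1
      }
    }
    if (n == 0) NA_real_ else s / n
  })
}

# Literal window-by-window ROH caller.
oracle_roh <- function(pos, gt, p) {
  n <- length(pos)
  w <- p$window_snp
  eligible <- rep(FALSE, n)
  if (n >= w) {
    hom_win <- rep(NA, n - w + 1)
    for (s in 1:(n - w + 1)) {
      win <- gt[s:(s + w - 1)]
      hom_win[s] <- sum(!is.na(win) & win == 1) <= p$window_het &&
        sum(is.na(win)) <= p$window_missing
    }
    for (t in 1:n) {
      overlapping <- intersect(max(1, t - w + 1):min(t, n - w + 1),
                               1:(n - w + 1))
      if (length(overlapping) > 0)
        eligible[t] <- mean(hom_win[overlapping]) >= p$window_threshold
    }
  }
  segs <- NULL
  i <- 1
  while (i <= n) {
    if (!eligible[i]) { i <- i + 1; next }
    j <- i
    while (j < n && eligible[j + 1]) j <- j + 1
    # split run i..j at large gaps
    pieces <- list(); cur <- i
    for (t in i:j) {
      if (t < j && (pos[t + 1] - pos[t]) > p$max_gap_kb * 1000) {
        pieces[[length(pieces) + 1]] <- c(cur, t)
        cur <- t + 1
      }
    }
    pieces[[length(pieces) + 1]] <- c(cur, j)
    for (pc in pieces) {
      n_snps <- pc[2] - pc[1] + 1
      kb <- (pos[pc[2]] - pos[pc[1]]) / 1000
      if (n_snps >= p$min_snp && kb >= p$min_kb &&
          kb / n_snps <= p$max_density_kb_per_snp)
        segs <- rbind(segs, data.frame(start = pos[pc[1]], end = pos[pc[2]],
                                       n_snps = n_snps, length_kb = kb))
    }
    i <- j + 1
  }
  segs
}

# Log-probability of one explicit state path (columns j, k), by direct
# multiplication of initial, transition and emission terms.
oracle_path_logprob <- function(inst, path) {
  H <- inst$H; loggl <- inst$loggl; cm <- inst$cm
  K <- nrow(H); M <- ncol(H)
  lam <- c(0, 1 - exp(-inst$rho * diff(cm) / 100 / K))
  lp <- -log(K * K)
  for (l in 1:M) {
    q <- inst$mu + (1 - 2 * inst$mu) * H[, l]
    e <- exp(loggl[l, ])
    qj <- q[path[l, 1]]; qk <- q[path[l, 2]]
    em <- e[1] * (1 - qj) * (1 - qk) +
      e[2] * ((1 - qj) * qk + qj * (1 - qk)) + e[3] * qj * qk
    lp <- lp + log(em)
    if (l > 1) {
      tj <- if (path[l, 1] == path[l - 1, 1]) 1 - lam[l] + lam[l] / K
            else lam[l] / K
      tk <- if (path[l, 2] == path[l - 1, 2]) 1 - lam[l] + lam[l] / K
            else lam[l] / K
      lp <- lp + log(tj) + log(tk)
    }
  }
  lp
}
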