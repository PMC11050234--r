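# shared fixtures and independent brute-force oracles

# 3 genes x 4 samples toy: A and B differ by a constant, C fluctuates
toy_ct_matrix <- function() {
  ct <- rbind(A = c(20, 21, 22, 23),
              B = c(25, 26, 27, 28),
              C = c(20, 22, 21, 24))
  colnames(ct) <- paste0("s", 1:4)
  ct_matrix(ct, group = c("g1", "g1", "g2", "g2"))
}

random_ct_matrix <- function(k, n, groups = 1) {
  ct <- matrix(stats::runif(k * n, 15, 35), k, n,
               dimnames = list(paste0("g", seq_len(k)),
                               paste0("s", seq_len(n))))
  grp <- rep(paste0("grp", seq_len(groups)), length.out = n)
  ct_matrix(ct, group = grp)
}

# ---- brute-force oracles (explicit loops, no shared code paths) ----

sd_n1 <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

brute_delta_ct <- function(ct) {
  k <- nrow(ct)
  out <- numeric(k)
  for (i in seq_len(k)) {
    sds <- c()
    for (j in seq_len(k)) {
      if (j == i) next
      sds <- c(sds, sd_n1(ct[i, ] - ct[j, ]))
    }
    out[i] <- mean(sds)
  }
  names(out) <- rownames(ct)
  out
}

brute_genorm_m <- function(ct, base = 2) {
  k <- nrow(ct)
  q <- ct
  for (i in seq_len(k)) q[i, ] <- base^(-(ct[i, ] - min(ct[i, ])))
  out <- numeric(k)
  for (j in seq_len(k)) {
    vs <- c()
    for (l in seq_len(k)) {
      if (l == j) next
      vs <- c(vs, sd_n1(log2(q[j, ] / q[l, ])))
    }
    out[j] <- mean(vs)
  }
  names(out) <- rownames(ct)
  out
}

brute_normfinder_ungrouped <- function(ct) {
  k <- nrow(ct); n <- ncol(ct)
  grand <- mean(ct)
  u <- numeric(k)
  for (i in seq_len(k)) {
    acc <- 0
    for (j in seq_len(n)) {
      r <- ct[i, j] - mean(ct[i, ]) - mean(ct[, j]) + grand
      acc <- acc + r^2
    }
    u[i] <- acc / (n - 1)
  }
  sv <- numeric(k)
  for (i in seq_len(k)) {
    s2 <- (k / (k - 2)) * (u[i] - sum(u) / (k * (k - 1)))
    sv[i] <- sqrt(max(s2, 0))
  }
  names(sv) <- rownames(ct)
  sv
}

brute_normfinder_grouped <- function(ct, group) {
  k <- nrow(ct)
  groups <- unique(group)
  grand <- mean(ct)
  sv <- numeric(k)
  terms <- matrix(0, k, length(groups))
  for (gi in seq_along(groups)) {
    cols <- which(group == groups[gi])
    yg <- ct[, cols, drop = FALSE]
    n_g <- length(cols)
    u <- numeric(k)
    for (i in seq_len(k)) {
      acc <- 0
      for (j in seq_len(n_g)) {
        r <- yg[i, j] - mean(yg[i, ]) - mean(yg[, j]) + mean(yg)
        acc <- acc + r^2
      }
      u[i] <- acc / (n_g - 1)
    }
    s2 <- numeric(k)
    for (i in seq_len(k))
      s2[i] <- max((k / (k - 2)) * (u[i] - sum(u) / (k * (k - 1))), 0)
    d <- numeric(k)
    for (i in seq_len(k))
      d[i] <- (mean(yg[i, ]) - mean(ct[i, ])) - (mean(yg) - grand)
    gamma2 <- max(0, sum(d^2) / (k - 1) - mean(s2) / n_g)
    for (i in seq_len(k)) {
      dt <- d[i] * gamma2 / (gamma2 + s2[i] / n_g)
      terms[i, gi] <- abs(dt) +
        sqrt(gamma2 * (s2[i] / n_g) / (gamma2 + s2[i] / n_g))
    }
  }
  for (i in seq_len(k)) sv[i] <- mean(terms[i, ])
  names(sv) <- rownames(ct)
  sv
}

# enumerate every cysteine subset of the right size and keep those whose
# consecutive gaps fall in the pattern windows
brute_motif_matches <- function(seq, pattern, strict = FALSE) {
  res <- strsplit(toupper(seq), "")[[1]]
  cys <- which(res == "C")
  need <- pattern$cys_count
  if (length(cys) < need) return(list())
  out <- list()
  for (idx in utils::combn(length(cys), need, simplify = FALSE)) {
    pos <- cys[idx]
    ok <- TRUE
    for (g in seq_len(need - 1)) {
      gap <- pos[g + 1] - pos[g] - 1
      if (gap < pattern$gaps[g, 1] || gap > pattern$gaps[g, 2]) {
        ok <- FALSE
        break
      }
      if (strict && any(cys > pos[g] & cys < pos[g + 1])) {
        ok <- FALSE
        break
      }
    }
    if (ok) out[[length(out) + 1]] <- pos
  }
  out
}

random_protein <- function(len, cys_prob = 0.15) {
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C")
  res <- ifelse(stats::runif(len) < cys_prob, "C",
                sample(aa, len, replace = TRUE))
  paste(res, collapse = "")
}
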