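# Independent oracles, written from first principles and kept free of any
# package internals so they can arbitrate correctness.

# average ranks by explicit sorting (no call to rank())
oracle_avg_rank <- function(x) {
  n <- length(x)
  ord <- order(x)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Pearson correlation from sufficient statistics
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y)
  sxx <- sum(x^2); syy <- sum(y^2)
  num <- n * sxy - sx * sy
  den <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  num / den
}

# Spearman rho + two-sided t-approximation p-value
oracle_spearman <- function(x, y) {
  n <- length(x)
  rho <- oracle_pearson(oracle_avg_rank(x), oracle_avg_rank(y))
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

# literal Benjamini-Hochberg step-up with cumulative minimum
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  if (m > 1L) for (i in (m - 1L):1L) q[i] <- min(q[i], q[i + 1L])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# OLS slope / R^2 / F-test p from sufficient statistics
oracle_ols <- function(y, x) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  ssx <- sxx - sx^2 / n
  ssy <- syy - sy^2 / n
  spxy <- sxy - sx * sy / n
  slope <- spxy / ssx
  intercept <- sy / n - slope * sx / n
  ss_res <- ssy - slope * spxy
  r2 <- 1 - ss_res / ssy
  fstat <- (ssy - ss_res) / (ss_res / (n - 2))
  p <- pf(fstat, 1, n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p,
       n = n)
}

# brute-force network: enumerate pairs, correlate, BH over the chosen pool,
# threshold; returns the sorted "a|b" edge keys
oracle_network_edges <- function(A_euk, A_bac, rho_min, alpha, pool) {
  keep <- function(A) A[apply(A, 1L, function(v) length(unique(v)) > 1L), ,
                        drop = FALSE]
  A_euk <- keep(A_euk); A_bac <- keep(A_bac)
  pairs <- list(); ps <- numeric(0L)
  add_pair <- function(ida, idb, x, y, cross) {
    s <- oracle_spearman(x, y)
    pairs[[length(pairs) + 1L]] <<- list(a = ida, b = idb, rho = s$rho,
                                         p = s$p, cross = cross)
    ps[length(ps) + 1L] <<- s$p
  }
  for (i in seq_len(nrow(A_euk))) {
    for (j in seq_len(nrow(A_bac))) {
      add_pair(rownames(A_euk)[i], rownames(A_bac)[j],
               A_euk[i, ], A_bac[j, ], TRUE)
    }
  }
  if (pool == "all_pairs") {
    within <- function(A) {
      n <- nrow(A)
      if (n < 2L) return(invisible())
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          add_pair(rownames(A)[i], rownames(A)[j], A[i, ], A[j, ], FALSE)
        }
      }
    }
    within(A_euk); within(A_bac)
  }
  padj <- oracle_bh(ps)
  keys <- character(0L)
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    if (pr$cross && pr$rho > rho_min && padj[k] < alpha) {
      keys <- c(keys, paste(pr$a, pr$b, sep = "|"))
    }
  }
  sort(keys)
}

# small helper: a random ASV table fixture
random_asv_table <- function(n_asv = 6L, n_tp = 8L, marker = "16S",
                             max_count = 50L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(rpois(n_asv * n_tp, max_count / 2), n_asv, n_tp,
                   dimnames = list(sprintf("asv_%03d", seq_len(n_asv)),
                                   as.character(seq(60, by = 2,
                                                    length.out = n_tp))))
  tax <- data.frame(domain = rep("Bacteria", n_asv),
                    phylum = rep(c("X", "Y"), length.out = n_asv),
                    class = "", order = "", family = "",
                    genus = rep(c("g1", "g2", "g3"), length.out = n_asv),
                    stringsAsFactors = FALSE)
  asv_table(counts, marker, taxonomy = tax)
}
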