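# Independent brute-force oracles used to cross-check the statistical
# routines. Kept deliberately naive: definitions, not optimized code.

# Benjamini-Hochberg step-up, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# Pearson chi-square statistic and p from first principles
chisq_oracle <- function(counts) {
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration;
# pmf computed from log binomial coefficients, not dhyper
fisher2x2_oracle <- function(counts) {
  a <- counts[1, 1]; b <- counts[1, 2]; c_ <- counts[2, 1]; d <- counts[2, 2]
  m1 <- a + b; m2 <- c_ + d; k <- a + c_
  lo <- max(0, k - m2); hi <- min(k, m1)
  logp <- function(x) {
    lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k)
  }
  probs <- exp(vapply(lo:hi, logp, numeric(1)))
  p_obs <- exp(logp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson r and two-sided t-test p from sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# cross-product odds ratio with Haldane-Anscombe correction on any zero
or_oracle <- function(counts) {
  a <- counts[1, 1]; b <- counts[1, 2]; c_ <- counts[2, 1]; d <- counts[2, 2]
  if (any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c_)
}

# unnormalized betweenness by explicit enumeration of all shortest paths
# (graphs up to ~12 nodes); edges as a 2-column matrix of vertex indices
betweenness_oracle <- function(n, edges) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  all_shortest <- function(s, t) {
    # BFS layered expansion collecting every shortest path
    paths <- list(s)
    found <- list()
    seen_depth <- rep(Inf, n); seen_depth[s] <- 0
    depth <- 0
    while (length(paths) > 0 && length(found) == 0) {
      depth <- depth + 1
      nxt <- list()
      for (p in paths) {
        for (v in adj[[p[length(p)]]]) {
          if (seen_depth[v] < depth || v %in% p) next
          q <- c(p, v)
          if (v == t) found[[length(found) + 1]] <- q else {
            nxt[[length(nxt) + 1]] <- q
          }
        }
      }
      for (p in nxt) seen_depth[p[length(p)]] <-
          min(seen_depth[p[length(p)]], depth)
      paths <- nxt
    }
    found
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    sp <- all_shortest(s, t)
    if (length(sp) == 0) next
    for (v in setdiff(1:n, c(s, t))) {
      frac <- mean(vapply(sp, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + frac
    }
  }
  btw
}

# reference ssGSEA score by an explicit running-sum walk over one sample's
# descending ranking; `member` is a logical vector in rank order
ssgsea_walk <- function(member, alpha = 0.25) {
  n <- length(member)
  rw <- (n:1)^alpha
  inc <- rw * member / sum(rw[member])
  dec <- if (n > sum(member)) (!member) / (n - sum(member)) else 0
  running <- cumsum(inc - dec)
  sum(running)
}

# small helpers used across test files -------------------------------------

toy_db <- function(pathways) {
  # pathways: named list of gene vectors
  validate_pathway_db(dplyr::bind_rows(purrr::imap(pathways, function(g, id) {
    tibble::tibble(pathway_id = id, name = id, gene = g, weight = 1)
  })))
}

toy_contingency <- function(counts, groups = c("young", "old"),
                            pair = c("A", "B"), ties = 0) {
  counts <- matrix(as.integer(counts), nrow = length(groups),
                   dimnames = list(groups, c("first", "second")))
  structure(list(counts = counts, pair_id = paste(pair, collapse = "|"),
                 first = pair[1], second = pair[2],
                 n_ties_excluded = ties,
                 degenerate = any(rowSums(counts) == 0) ||
                   any(colSums(counts) == 0)),
            class = "mp_contingency")
}

gmt_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
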