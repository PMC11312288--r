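# Independent brute-force oracles, deliberately written as plain loops over
# definitions so they share no code path with the package implementation.

brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  # step-up: q_(i) = min_{j >= i} min(1, m * p_(j) / j)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[ord[i]] / i)
    q[ord[i]] <- running
  }
  q
}

brute_distance <- function(values) {
  n <- nrow(values)
  d <- matrix(0, n, n, dimnames = list(rownames(values), rownames(values)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((values[i, ] - values[j, ])^2))
    }
  }
  d
}

brute_abs_cosine <- function(values) {
  n <- nrow(values)
  C <- matrix(0, n, n, dimnames = list(rownames(values), rownames(values)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- abs(sum(values[i, ] * values[j, ])) /
        (sqrt(sum(values[i, ]^2)) * sqrt(sum(values[j, ]^2)))
    }
  }
  diag(C) <- 1
  C
}

# Naive average-linkage agglomeration; returns the sorted merge heights.
brute_average_linkage_heights <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  members <- c(members, vector("list", n - 1))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_h <- Inf
    idx <- which(active[seq_len(n + step - 1)])
    for (a in idx) {
      for (b in idx) {
        if (a >= b) next
        h <- mean(d[members[[a]], members[[b]]])
        if (h < best_h) {
          best_h <- h
          best <- c(a, b)
        }
      }
    }
    heights[step] <- best_h
    new <- n + step
    members[[new]] <- c(members[[best[1]]], members[[best[2]]])
    active[best] <- FALSE
    active[new] <- TRUE
  }
  sort(heights)
}

brute_collapse <- function(tab) {
  keys <- unique(tab[, c("gene", "group", "animal")])
  keys$ct <- NA_real_
  for (i in seq_len(nrow(keys))) {
    sel <- tab$gene == keys$gene[i] & tab$group == keys$group[i] &
      tab$animal == keys$animal[i]
    keys$ct[i] <- mean(tab$ct[sel])
  }
  keys[order(keys$gene, keys$group, keys$animal), , drop = FALSE]
}

# Full-enumeration enrichment score (walks every position explicitly).
brute_es <- function(scores, hit, weight_exponent) {
  N <- length(scores)
  Nh <- sum(hit)
  w <- abs(scores[hit])^weight_exponent
  w <- if (sum(w) > 0) w / sum(w) else rep(1 / Nh, Nh)
  rs <- numeric(N)
  cur <- 0
  k <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      k <- k + 1
      cur <- cur + w[k]
    } else {
      cur <- cur - 1 / (N - Nh)
    }
    rs[i] <- cur
  }
  rs[which.max(abs(rs))]
}

adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

random_signature_set <- function(n_pop = 5, n_genes = 20,
                                 allow_negative = TRUE) {
  v <- matrix(stats::rnorm(n_pop * n_genes), n_pop, n_genes,
              dimnames = list(paste0("pop", seq_len(n_pop)),
                              paste0("g", seq_len(n_genes))))
  if (!allow_negative) v <- abs(v)
  signature_set(v)
}

random_ct_table <- function(n_genes = 3, n_animals = 3, n_rep = 3) {
  grid <- expand.grid(replicate = seq_len(n_rep),
                      gene = paste0("gene", seq_len(n_genes)),
                      animal = paste0("a", seq_len(2 * n_animals)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$group <- ifelse(as.integer(sub("a", "", grid$animal)) <= n_animals,
                       "WT", "KO")
  grid$ct <- stats::runif(nrow(grid), 5, 35)
  grid[, c("gene", "group", "animal", "replicate", "ct")]
}

two_block_sim_config <- function(seed) {
  signature_sim_config(
    blocks = list(
      neurodevelopment = c("PAM", "ATM", "CD11c", "AQP4_AC", "AQP4_CC"),
      disease_ageing = c("APP", "Aged", "DAM1", "DAM2", "MGnD", "LDAM")),
    n_genes = 500, within_block_cosine = 0.9, between_block_cosine = 0.2,
    noise_sd = 0.1, seed = seed)
}
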