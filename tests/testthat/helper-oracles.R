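# Independent brute-force oracles used to validate the package's metric and
# texture implementations. These deliberately share no code with R/.

# Harrell C by explicit double loop over all ordered pairs.
oracle_cindex <- function(time, event, risk) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# Adjusted Rand index by explicit pair counting.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- s11 + s00 + s10 + s01
  expected <- (s11 + s10) * (s11 + s01) / np
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == expected) return(1)
  (s11 - expected) / (max_idx - expected)
}

# Symmetric normalized GLCM of one direction by explicit voxel enumeration.
oracle_glcm_matrix <- function(levels, mask, dir) {
  d <- dim(mask)
  L <- max(levels[mask])
  M <- matrix(0, L, L)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    ni <- i + dir[1]; nj <- j + dir[2]; nk <- k + dir[3]
    if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2] || nk < 1 || nk > d[3]) next
    if (!mask[ni, nj, nk]) next
    a <- levels[i, j, k]; b <- levels[ni, nj, nk]
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M / sum(M)
}

# Cluster prominence of one normalized GLCM, written independently.
oracle_cluster_prominence <- function(P) {
  L <- nrow(P)
  mux <- sum(rowSums(P) * seq_len(L))
  muy <- sum(colSums(P) * seq_len(L))
  out <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    out <- out + (i + j - mux - muy)^4 * P[i, j]
  }
  out
}

# All set partitions of n labelled items (restricted growth strings).
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  rec <- function(prefix, maxlab) {
    pos <- length(prefix) + 1
    if (pos > n) { out[[length(out) + 1]] <<- prefix; return() }
    for (lab in seq_len(maxlab + 1)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# Small censored survival instance generator for metric tests.
random_surv_instance <- function(n, tie_prob = 0.3) {
  time <- sample(1:8, n, replace = TRUE) + ifelse(runif(n) < tie_prob, 0, runif(n))
  event <- rbinom(n, 1, 0.7)
  risk <- sample(1:5, n, replace = TRUE) + ifelse(runif(n) < tie_prob, 0, runif(n))
  list(time = time, event = event, risk = risk)
}

quiet_cohort <- function(...) suppressWarnings(generate_cohort(cohort_spec(...)))
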