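# Independent oracles, deliberately naive: plain window enumeration with
# order() for permutation entropy, exhaustive agglomeration for average
# linkage, and a direct confusion-count F1. These never share code with the
# package's fast paths.

brute_pattern_counts <- function(x, n, tau) {
  L <- length(x) - (n - 1) * tau
  pats <- character(L)
  for (i in seq_len(L)) {
    w <- x[i + (0:(n - 1)) * tau]
    pats[i] <- paste(order(w) - 1L, collapse = "")
  }
  table(pats)
}

brute_pe <- function(x, n, tau, normalize = TRUE) {
  tb <- brute_pattern_counts(x, n, tau)
  p <- as.numeric(tb) / sum(tb)
  h <- -sum(p * log(p))
  if (normalize) h / log(factorial(n)) else h
}

# exhaustive average-linkage agglomeration; returns merge heights in order
hand_average_linkage <- function(X) {
  D <- as.matrix(dist(X))
  members <- as.list(seq_len(nrow(X)))
  active <- seq_len(nrow(X))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- NULL; bh <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        a <- active[i]; b <- active[j]
        h <- mean(D[members[[a]], members[[b]]])
        if (h < bh) { bh <- h; best <- c(a, b) }
      }
    }
    members[[length(members) + 1]] <- c(members[[best[1]]], members[[best[2]]])
    active <- c(setdiff(active, best), length(members))
    heights <- c(heights, bh)
  }
  heights
}

# direct confusion-count binary F1 (sleep & C positive), NA/OC excluded
hand_binary_f1 <- function(pred, eyes) {
  keep <- !is.na(eyes) & eyes != "OC"
  p <- pred[keep]; e <- eyes[keep]
  tp <- sum(p == "sleep" & e == "C")
  fp <- sum(p == "sleep" & e == "O")
  fn <- sum(p == "wake" & e == "C")
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

# small stage-separated feature cohort built by hand (independent of the
# package's simulate_feature_cohort), for classifier sanity checks
tiny_blob_set <- function(n_per = 30, sep = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(W = c(sep, 0), N2 = c(0, sep), N3 = c(-sep, 0))
  x <- do.call(rbind, lapply(rownames(centers), function(s)
    sweep(matrix(rnorm(n_per * 2, 0, 0.05), ncol = 2), 2, centers[s, ], `+`)))
  colnames(x) <- c("Cz", "Pz")
  list(x = x, y = factor(rep(rownames(centers), each = n_per),
                         levels = c("W", "N1", "N2", "N3", "R")))
}
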