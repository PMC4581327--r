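# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package internals.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_seq <- function(len, alphabet = AA20, prob = NULL) {
  paste(sample(alphabet, len, replace = TRUE, prob = prob), collapse = "")
}

# --- global alignment oracle: exhaustive Needleman-Wunsch DP -------------
# match +1, mismatch 0, gap -1 (linear); returns the optimal score.
nw_score_oracle <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- gap * (0:n)
  D[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (x[i] == y[j] && x[i] != "X") match else mismatch
    D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap, D[i + 1, j] + gap)
  }
  D[n + 1, m + 1]
}

# --- O-glycosylation motif oracle ----------------------------------------
# Enumerates every (k1, x, k2) arity combination at an offset via fixed
# regular expressions; X never matches the literal classes. Returns the
# smallest end of any match starting at 1-based offset i, or NA.
ogly_match_end_oracle <- function(chars, i) {
  L <- length(chars)
  flank <- c("A", "S", "T", "V")
  best <- NA_integer_
  for (k1 in 1:4) for (x in 0:10) for (k2 in 1:4) {
    end <- i + 1 + k1 + x + k2
    if (end > L) next
    seg <- chars[i:end]
    ok <- seg[1] %in% flank &&
      all(seg[2:(1 + k1)] == "P") &&
      seg[2 + k1 + x] %in% flank &&
      all(seg[(3 + k1 + x):(2 + k1 + x + k2)] == "P")
    if (ok && (is.na(best) || end < best)) best <- end
  }
  best
}

# Non-overlapping left-to-right scan with the shortest-extent policy,
# entirely on top of the enumeration above.
ogly_scan_oracle <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- list()
  i <- 1
  while (i + 3 <= L) {
    end <- ogly_match_end_oracle(chars, i)
    if (!is.na(end)) {
      out[[length(out) + 1]] <- c(start = i, end = end, anchor = i + 1)
      i <- end + 1
    } else i <- i + 1
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      anchor = integer()))
  as.data.frame(do.call(rbind, out))
}

# --- N-glycosylation sequon oracle: brute-force triple scan --------------
ngly_scan_oracle <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  hits <- integer(0)
  if (length(chars) >= 3) {
    for (i in 1:(length(chars) - 2)) {
      if (chars[i] == "N" && chars[i + 1] != "P" &&
          chars[i + 2] %in% c("S", "T"))
        hits <- c(hits, i)
    }
  }
  hits
}

# --- Benjamini-Hochberg step-up oracle -----------------------------------
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# --- PEST score oracle ---------------------------------------------------
# Independent restatement of the classic PEST-find score from its published
# constants: 0.55 * corrected DEPST mass percent - 0.5 * mean rescaled
# Kyte-Doolittle hydropathy.
pest_score_oracle <- function(region) {
  mass <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
            C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
            H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
            M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
            T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5,
          Q = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  ch <- strsplit(region, "")[[1]]
  total <- sum(mass[ch])
  depst <- sum(mass[ch[ch %in% c("D", "E", "P", "S", "T")]])
  de <- if ("D" %in% ch) mass[["D"]] else mass[["E"]]
  st <- if ("S" %in% ch) mass[["S"]] else mass[["T"]]
  corr <- depst - de - mass[["P"]] - st
  0.55 * (100 * corr / total) - 0.5 * mean(10 * (kd[ch] + 4.5))
}

# --- exhaustive permutation test oracle ----------------------------------
perm_p_oracle <- function(x, y) {
  pool <- c(x, y)
  idx <- combn(length(pool), length(x))
  obs <- mean(x) - mean(y)
  mean(apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i])) >=
         obs - 1e-12)
}

# --- small builders ------------------------------------------------------
toy_proteome <- function(seqs, species = "spX", group = "other") {
  Proteome(seqs, speciesId = species, group = group)
}
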