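# Independent reference implementations used to check the package's results.
# These are deliberately written with different techniques than the package
# code (regex splitting, dense dynamic programming, explicit enumeration).

# tryptic digestion via a lookahead/lookbehind regex
oracle_digest <- function(seq) {
  strsplit(seq, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}

# quadratic-space Gotoh alignment, score only; gap of length L costs
# open + L * ext, end gaps penalized in global mode
oracle_align_score <- function(a, b, mat, open = 11, ext = 1,
                               mode = c("global", "local")) {
  mode <- match.arg(mode)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  M[1, 1] <- 0
  if (mode == "global") {
    for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  } else {
    M[, 1] <- 0
    M[1, ] <- 0
  }
  best_local <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      diag_best <- max(M[i, j], Ix[i, j], Iy[i, j])
      mv <- diag_best + s
      if (mode == "local") mv <- max(mv, 0)
      M[i + 1, j + 1] <- mv
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext), Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext), Iy[i + 1, j] - ext)
      if (mode == "local") best_local <- max(best_local, M[i + 1, j + 1])
    }
  }
  if (mode == "global") max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  else best_local
}

# two-tailed Fisher p by explicit enumeration over all tables with the
# observed margins, using exact log-factorial point probabilities
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  logp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  xs <- max(0, k - n):min(k, m)
  lp <- vapply(xs, logp, numeric(1))
  p_obs <- exp(logp(a))
  sum(exp(lp)[exp(lp) <= p_obs * (1 + 1e-7)])
}

# brute-force scan of every (offset, residue) binomial p-value on full
# foreground/background window sets; returns the table of candidates
oracle_motif_scan <- function(fg, bg, pad = "_") {
  AA <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  w <- nchar(fg[1])
  center <- (w + 1) %/% 2
  rows <- list()
  for (col in setdiff(seq_len(w), center)) {
    fg_col <- substring(fg, col, col)
    bg_col <- substring(bg, col, col)
    fg_col <- fg_col[fg_col != pad]
    bg_col <- bg_col[bg_col != pad]
    for (r in AA) {
      k <- sum(fg_col == r)
      p0 <- mean(bg_col == r)
      p <- if (k == 0) 1 else stats::pbinom(k - 1, length(fg_col), p0, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        offset = col - center, residue = r, k = k, p = p)
    }
  }
  do.call(rbind, rows)
}

# direct mean computation for normalization checks
oracle_channel_means <- function(tbl, channels) {
  vapply(channels, function(cn) mean(tbl[[cn]], na.rm = TRUE), numeric(1))
}
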