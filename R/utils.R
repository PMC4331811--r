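.BASES <- c("A", "C", "G", "T")

## integer codes 1..4 for A,C,G,T; NA for anything else
.seqCodes <- function(x) {
  x <- toupper(x)
  if (grepl("U", x, fixed = TRUE))
    stop("RNA base 'U' found; DNA sequences only")
  match(strsplit(x, "", fixed = TRUE)[[1]], .BASES)
}

.codesToSeq <- function(codes) paste(.BASES[codes], collapse = "")

.revcompStr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## all k-mers over ACGT in lexicographic order
.allKmers <- function(k) {
  out <- .BASES
  if (k > 1) for (i in seq_len(k - 1)) out <- paste0(rep(out, each = 4), .BASES)
  out
}

## k-mer index (1-based, lexicographic) from a codes matrix (n x L),
## one window column per profile position
.windowIndex <- function(codes, k) {
  L <- ncol(codes)
  P <- L - k + 1
  idx <- codes[, seq_len(P), drop = FALSE] - 1L
  if (k >= 2) for (j in 2:k) idx <- idx * 4L + (codes[, j:(j + P - 1), drop = FALSE] - 1L)
  idx + 1L
}

## profile matrix (n x P) for a codes matrix under a PropertyTable
.profileMatrix <- function(codes, table) {
  n <- nrow(codes)
  L <- ncol(codes)
  k <- table@k
  if (L < k) stop("sequence too short: length ", L, " < k = ", k)
  if (!table@positional) {
    idx <- .windowIndex(codes, k)
    v <- table@values[, 1L][idx]
    matrix(v, n, L - k + 1L)
  } else {
    ## per-nucleotide averaging of the triple contributions of every
    ## trinucleotide window covering the position
    idx <- .windowIndex(codes, 3L)          # n x (L-2)
    P <- L - 2L
    v1 <- matrix(table@values[, 1L][idx], n, P)
    v2 <- matrix(table@values[, 2L][idx], n, P)
    v3 <- matrix(table@values[, 3L][idx], n, P)
    acc <- matrix(0, n, L)
    cnt <- matrix(0L, n, L)
    add <- function(acc, cnt, m, off) {
      ok <- !is.na(m)
      cols <- seq_len(P) + off
      acc[, cols][ok] <- acc[, cols][ok] + m[ok]
      cnt[, cols][ok] <- cnt[, cols][ok] + 1L
      list(acc, cnt)
    }
    r <- add(acc, cnt, v1, 0L); acc <- r[[1]]; cnt <- r[[2]]
    r <- add(acc, cnt, v2, 1L); acc <- r[[1]]; cnt <- r[[2]]
    r <- add(acc, cnt, v3, 2L); acc <- r[[1]]; cnt <- r[[2]]
    out <- acc / cnt
    out[cnt == 0L] <- NA_real_
    out
  }
}

## mean pairwise absolute difference per column of X (n x P), no NAs.
## sum over i<j of |x_i - x_j| equals sum_i (2i - n - 1) x_(i) on sorted x.
.colPairMeanAbsDiff <- function(X) {
  n <- nrow(X)
  w <- 2 * seq_len(n) - n - 1
  S <- apply(X, 2, sort)
  if (is.null(dim(S))) S <- matrix(S, nrow = n)
  as.vector(crossprod(w, S)) / (n * (n - 1) / 2)
}

.isWholeNumber <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)
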