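# Independent oracles, deliberately implemented with different algorithms
# than the package code they check.

# Connected components by iterated minimum-label propagation until fixpoint
# (the package uses breadth-first flood fill). Returns a canonical partition:
# a list of sorted linear-index vectors, ordered by their smallest element.
floodOracle <- function(mask, connectivity) {
  dm <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(list())
  coords <- arrayInd(idx, dm)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(off != 0L) > 0L, , drop = FALSE]
  d <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6" = off[d == 1L, , drop = FALSE],
                "18" = off[d <= 2L, , drop = FALSE],
                "26" = off)
  pairs <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coords, 2L, off[r, ], `+`)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
    if (!any(ok)) next
    lin <- nb[ok, 1L] + (nb[ok, 2L] - 1L) * dm[1L] +
      (nb[ok, 3L] - 1L) * dm[1L] * dm[2L]
    j <- match(lin, idx)
    keep <- !is.na(j)
    if (any(keep))
      pairs <- rbind(pairs, cbind(which(ok)[keep], j[keep]))
  }
  lab <- seq_along(idx)
  if (!is.null(pairs)) {
    repeat {
      m <- tapply(lab[pairs[, 2L]], pairs[, 1L], min)
      new <- lab
      ii <- as.integer(names(m))
      new[ii] <- pmin(new[ii], m)
      if (identical(new, lab)) break
      lab <- new
    }
  }
  parts <- lapply(split(idx, lab), sort)
  names(parts) <- NULL
  parts[order(vapply(parts, min, numeric(1L)))]
}

# Canonical partition of a labeled array from the package, for comparison.
labelPartition <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(list())
  parts <- lapply(split(idx, lab[idx]), sort)
  names(parts) <- NULL
  parts[order(vapply(parts, min, numeric(1L)))]
}

# Benjamini-Hochberg step-up from its definition: sort, p * m / rank,
# cumulative minimum from the largest rank down, cap at 1.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Two-variable OLS via explicit normal equations, with t-based p-values.
olsOracle <- function(y, x, covar = NULL) {
  X <- cbind(1, x, covar)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(sigma2 * solve(XtX)))
  tval <- beta / se
  list(beta = unname(beta[2L]), se = unname(se[2L]),
       p = unname(2 * stats::pt(-abs(tval[2L]), df)))
}

# Shared small template; built once per test session.
tinyTemplate <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- faTemplate(c(16L, 16L, 16L))
    cache
  }
})
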