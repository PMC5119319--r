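# shared helpers and independent brute-force oracles

# run code with auditing disabled, restoring prior state
no_audit <- function(code) {
  old <- auditEnabled(FALSE)
  on.exit(auditEnabled(old))
  force(code)
}

# run code with auditing routed to a fresh temp directory; returns the dir
with_audit_dir <- function(code) {
  dir <- tempfile("audit_")
  dir.create(dir)
  old_e <- auditEnabled(TRUE)
  old_d <- auditDirectory(dir)
  on.exit({
    auditEnabled(old_e)
    auditDirectory(old_d)
  })
  resetAudit()
  force(code)
  dir
}

# independent connected-components oracle: queue-based BFS flood fill over
# equal-valued pixels, 8-connectivity, labels in raster order of first pixel
oracle_flood_fill <- function(m, background = 0L, connectivity = 8L) {
  nr <- nrow(m)
  nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8L) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else {
    list(c(-1,0), c(0,-1), c(0,1), c(1,0))
  }
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (m[r, c] == background || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(queue) > 0L) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (o in offs) {
        rr <- p[1] + o[1]
        cc <- p[2] + o[2]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        if (lab[rr, cc] == 0L && m[rr, cc] == m[r, c]) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# nearest-seed oracle on flat terrain: Manhattan distance to each seed's
# pixel set; returns the winning label where the nearest seed is unique,
# NA where tied
oracle_nearest_seed <- function(seed_labels) {
  ids <- sort(unique(seed_labels[seed_labels > 0L]))
  nr <- nrow(seed_labels)
  nc <- ncol(seed_labels)
  dmat <- array(Inf, dim = c(nr, nc, length(ids)))
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_along(ids)) {
    px <- which(seed_labels == ids[k], arr.ind = TRUE)
    for (j in seq_len(nrow(px)))
      dmat[, , k] <- pmin(dmat[, , k], abs(rr - px[j, 1]) + abs(cc - px[j, 2]))
  }
  out <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d <- dmat[r, c, ]
    w <- which(d == min(d))
    if (length(w) == 1L) out[r, c] <- ids[w]
  }
  out
}

# random logical mask with given TRUE density
random_mask <- function(nr, nc, density = 0.4) {
  matrix(runif(nr * nc) < density, nr, nc)
}

# small fixture spec for fast end-to-end tests (same structure as the
# default study fixture, scaled down where the test allows it)
demo_spec <- function(...) cellGridSpec(...)
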