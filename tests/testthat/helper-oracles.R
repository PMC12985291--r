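# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation: plain nested loops and queues.

# flood-fill connected components; returns an integer label array
floodFillLabels <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18L) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  nextLab <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k] || lab[i, j, k] != 0L) next
    nextLab <- nextLab + 1L
    queue <- matrix(c(i, j, k), 1)
    lab[i, j, k] <- nextLab
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        p <- cur + offs[o, ]
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- nextLab
          queue <- rbind(queue, p)
        }
      }
    }
  }
  lab
}

# brute-force binary opening with a ball structuring element
bruteOpening <- function(mask, radius) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-floor(radius):floor(radius),
                                -floor(radius):floor(radius),
                                -floor(radius):floor(radius)))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  inRange <- function(p) all(p >= 1) && all(p <= d)
  er <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ok <- TRUE
    for (o in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[o, ]
      if (!inRange(p) || !mask[p[1], p[2], p[3]]) { ok <- FALSE; break }
    }
    er[i, j, k] <- ok
  }
  di <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    hit <- FALSE
    for (o in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[o, ]
      if (inRange(p) && er[p[1], p[2], p[3]]) { hit <- TRUE; break }
    }
    di[i, j, k] <- hit
  }
  di
}

# nested-loop per-axis maximum of a masked subvolume (pre-resampling MIP)
bruteMip <- function(sub, axis) {
  d <- dim(sub)
  rem <- setdiff(1:3, axis)
  out <- matrix(-Inf, d[rem[1]], d[rem[2]])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    idx <- c(i, j, k)
    a <- idx[rem[1]]; b <- idx[rem[2]]
    if (sub[i, j, k] > out[a, b]) out[a, b] <- sub[i, j, k]
  }
  out
}

# a small solid ball mask for constructing test volumes
sphereMask <- function(d, centre, radius) {
  arr <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    arr[i, j, k] <- sum((c(i, j, k) - centre)^2) <= radius^2
  arr
}
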