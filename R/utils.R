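# Internal helpers: RNG state handling, small image-processing kernels
# (separable Gaussian smoothing, 8-connected labeling, binary erosion)
# and a config hash. Images are matrices indexed [row, col].

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# Evaluate expr with a locally seeded RNG, restoring global state after.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  expr
}

# Replicate-padded 1D convolution along rows then columns.
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {  # convolve along columns of m
    n <- nrow(m)
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# 5-point discrete Laplacian with replicated (Neumann) borders.
laplacian5 <- function(img) {
  n <- nrow(img); m <- ncol(img)
  up <- img[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- img[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
  lf <- img[, c(1L, seq_len(m - 1L)), drop = FALSE]
  rt <- img[, c(seq_len(m - 1L) + 1L, m), drop = FALSE]
  up + dn + lf + rt - 4 * img
}

# 8-connected component labeling of a logical matrix, labels assigned in
# raster order (row-major: by first pixel reading left-to-right,
# top-to-bottom). Two-pass union-find.
label_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nxt <- 0L
  for (r in seq_len(n)) for (c in seq_len(m)) {
    if (!mask[r, c]) next
    nb <- integer(0)
    if (r > 1L) {
      if (c > 1L && lab[r - 1L, c - 1L]) nb <- c(nb, lab[r - 1L, c - 1L])
      if (lab[r - 1L, c]) nb <- c(nb, lab[r - 1L, c])
      if (c < m && lab[r - 1L, c + 1L]) nb <- c(nb, lab[r - 1L, c + 1L])
    }
    if (c > 1L && lab[r, c - 1L]) nb <- c(nb, lab[r, c - 1L])
    if (length(nb) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, c] <- nxt
    } else {
      lab[r, c] <- min(nb)
      for (b in nb) union_(min(nb), b)
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  # relabel contiguously in raster order of first occurrence
  lab_t <- t(lab)  # row-major scan
  first <- integer(nxt)
  seen <- logical(nxt)
  order_ids <- integer(0)
  for (v in lab_t[lab_t > 0L]) {
    rv <- roots[v]
    if (!seen[rv]) { seen[rv] <- TRUE; order_ids <- c(order_ids, rv) }
  }
  remap <- integer(nxt)
  remap[order_ids] <- seq_along(order_ids)
  lab[lab > 0L] <- remap[roots[lab[lab > 0L]]]
  lab
}

# Split labelled components that contain several well-separated local
# intensity maxima, assigning each pixel to the nearest maximum. A
# secondary maximum counts only when it reaches 40% of the component's
# peak prominence over the threshold and lies >= 3 px from a stronger
# one; this separates adjacent puncta merged by thresholding without
# fragmenting single noisy blobs. Relabels in raster order.
split_label_peaks <- function(lab, image, thr, min_dist = 3, rel_height = 0.4) {
  n <- nrow(lab); m <- ncol(lab)
  out <- matrix(0L, n, m)
  next_id <- 0L
  # strict 8-neighbourhood local maxima
  pad <- matrix(-Inf, n + 2L, m + 2L)
  pad[2:(n + 1L), 2:(m + 1L)] <- image
  is_max <- matrix(TRUE, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & (image >= pad[2:(n + 1L) + dr, 2:(m + 1L) + dc])
  }
  for (id in seq_len(max(lab))) {
    sel <- which(lab == id, arr.ind = TRUE)
    if (nrow(sel) == 0L) next
    vals <- image[sel]
    peak <- max(vals)
    cand <- sel[is_max[sel] & vals >= thr + rel_height * (peak - thr), ,
                drop = FALSE]
    # collapse plateau maxima: connected candidate pixels are one summit
    if (nrow(cand) > 1L) {
      cm <- matrix(FALSE, n, m)
      cm[cand] <- TRUE
      cl <- label_components(cm)
      cand <- do.call(rbind, lapply(seq_len(max(cl)), function(k) {
        pix <- which(cl == k, arr.ind = TRUE)
        round(colMeans(pix))
      }))
      colnames(cand) <- c("row", "col")
    }
    # greedily keep maxima in decreasing height, dropping close neighbours
    if (nrow(cand) > 1L) {
      ord <- order(image[cand], decreasing = TRUE)
      cand <- cand[ord, , drop = FALSE]
      keep <- rep(TRUE, nrow(cand))
      for (i in 2:nrow(cand)) {
        d <- sqrt((cand[seq_len(i - 1L), 1][keep[seq_len(i - 1L)]] - cand[i, 1])^2 +
                  (cand[seq_len(i - 1L), 2][keep[seq_len(i - 1L)]] - cand[i, 2])^2)
        if (length(d) && min(d) < min_dist) keep[i] <- FALSE
      }
      cand <- cand[keep, , drop = FALSE]
    }
    if (nrow(cand) <= 1L) {
      next_id <- next_id + 1L
      out[lab == id] <- next_id
    } else {
      dmat <- outer(seq_len(nrow(sel)), seq_len(nrow(cand)), function(i, j)
        (sel[i, 1] - cand[j, 1])^2 + (sel[i, 2] - cand[j, 2])^2)
      assign_ <- max.col(-dmat, ties.method = "first")
      for (k in seq_len(nrow(cand))) {
        next_id <- next_id + 1L
        pix <- sel[assign_ == k, , drop = FALSE]
        out[pix] <- next_id
      }
    }
  }
  # relabel contiguously in raster order of first occurrence
  out_t <- t(out)
  order_ids <- unique(out_t[out_t > 0L])
  remap <- integer(max(out, 0L))
  remap[order_ids] <- seq_along(order_ids)
  out[out > 0L] <- remap[out[out > 0L]]
  out
}

# Binary erosion with a 3x3 (8-neighbourhood) structuring element.
erode3 <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) {
    n <- nrow(mask); m <- ncol(mask)
    p <- matrix(FALSE, n + 2L, m + 2L)
    p[2:(n + 1L), 2:(m + 1L)] <- mask
    out <- p[2:(n + 1L), 2:(m + 1L)]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      out <- out & p[2:(n + 1L) + dr, 2:(m + 1L) + dc]
    }
    mask <- out
  }
  mask
}

# Robust scale of a numeric vector/matrix (MAD, normal-consistent).
robust_sd <- function(x) stats::mad(as.numeric(x))

# Polynomial hash (mod 2^31 - 1) of a character scalar, as 8 hex
# digits; used to stamp pipeline outputs with their configuration.
config_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}
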