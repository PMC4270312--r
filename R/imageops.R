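# Minimal vectorized image-processing primitives (blur, Otsu, connected
# components, chamfer distance, marker-based growing). Kept in base R; fields
# at screening scale are small enough that whole-matrix shift operations are
# fast, and no image-processing package is required at run time.

# shift with edge replication: out[i,j] = m[clamp(i+dr), clamp(j+dc)]
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  m[ri, ci, drop = FALSE]
}

# shift filling with `fill` outside the image (no replication)
shift_fill <- function(m, dr, dc, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1L, 1L + dr):min(H, H + dr)
  cs <- max(1L, 1L + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Separable Gaussian blur with edge replication
#' @param img numeric matrix.
#' @param sigma Gaussian sd in pixels; 0 returns the input.
#' @return blurred matrix.
#' @export
gaussian_blur <- function(img, sigma = 2) {
  if (sigma <= 0) return(img)
  K <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-K:K, sd = sigma)
  w <- w / sum(w)
  out <- matrix(0, nrow(img), ncol(img))
  for (k in -K:K) out <- out + w[k + K + 1L] * shift_mat(img, k, 0L)
  img2 <- out
  out <- matrix(0, nrow(img), ncol(img))
  for (k in -K:K) out <- out + w[k + K + 1L] * shift_mat(img2, 0L, k)
  out
}

#' Otsu's threshold
#'
#' Maximizes between-class variance on a 256-bin histogram; being computed on
#' normalized intensities it is invariant under uniform intensity scaling.
#' @param img numeric matrix (nonnegative).
#' @param nbins histogram bins.
#' @return threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  v <- as.vector(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)  # constant image: nothing above threshold
  h <- tabulate(pmin(as.integer((v - lo) / (hi - lo) * nbins) + 1L, nbins), nbins)
  p <- h / sum(h)
  mids <- lo + (seq_len(nbins) - 0.5) / nbins * (hi - lo)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  denom <- w0 * (1 - w0)
  sb <- ifelse(denom > 0, (mu_t * w0 - mu)^2 / denom, 0)
  mids[which.max(sb)]
}

#' Label connected components of a binary mask
#'
#' Iterative label propagation (max over neighbors) until a fixed point;
#' labels are relabeled to contiguous 1..n.
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer label matrix (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0, H, W)
  lab[mask] <- seq_len(sum(mask))
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L) {
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  repeat {
    new <- lab
    for (s in shifts) new <- pmax(new, shift_fill(lab, s[1], s[2], 0))
    new[!mask] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  relabel_contiguous(lab)
}

relabel_contiguous <- function(lab) {
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(ids)) out[lab > 0] <- match(lab[lab > 0], ids)
  out
}

#' Chamfer (3-4-type) distance transform to the background
#'
#' Iterative vectorized relaxation with unit axial and sqrt(2) diagonal
#' steps; converges in about max-inscribed-radius iterations.
#' @param mask logical matrix (distance computed inside `TRUE`).
#' @return numeric matrix of distances (0 on background).
#' @export
chamfer_distance <- function(mask) {
  big <- sum(dim(mask))
  d <- matrix(0, nrow(mask), ncol(mask))
  d[mask] <- big
  shifts <- list(c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1),
                 c(1, 1, sqrt(2)), c(1, -1, sqrt(2)),
                 c(-1, 1, sqrt(2)), c(-1, -1, sqrt(2)))
  repeat {
    new <- d
    for (s in shifts) new <- pmin(new, shift_fill(d, s[1], s[2], big) + s[3])
    new[!mask] <- 0
    if (max(abs(new - d)) < 1e-9) break
    d <- new
  }
  d
}

#' Grow labeled seeds through a mask (seeded watershed / region growing)
#'
#' Synchronous multi-source breadth-first label propagation restricted to the
#' foreground mask: region boundaries fall at (approximately) equal geodesic
#' distance between seeds, and no pixel belongs to two regions.
#' @param seeds integer label matrix (seed regions, 0 elsewhere).
#' @param mask logical foreground mask; seeds outside the mask still grow
#'   from their own pixels.
#' @return integer label matrix covering `mask` pixels reachable from seeds.
#' @export
grow_labels <- function(seeds, mask) {
  lab <- seeds
  region <- mask | seeds > 0
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (s in shifts) {
      cand <- shift_fill(lab, s[1], s[2], 0)
      take <- region & lab == 0 & cand > 0
      if (any(take)) {
        lab[take] <- cand[take]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}
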