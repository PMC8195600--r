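# Internal helpers shared across modules.

CHANNEL_NAMES <- c("GFP", "tdTomato", "Cy5", "brightfield")
FLUOR_CHANNELS <- c("GFP", "tdTomato", "Cy5")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Deterministic round-half-up (avoids round()'s banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

assert_scalar_num <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_min && x <= min) stopf("'%s' must be > %g", name, min)
  if (!strict_min && x < min) stopf("'%s' must be >= %g", name, min)
  invisible(x)
}

# Label 8-connected components of a logical matrix. Returns an integer matrix
# (0 = background) plus component sizes. EBImage::bwlabel is 4-connected, so
# adjacency is built explicitly and components come from igraph.
label_components8 <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(list(labels = lab, sizes = integer(0)))
  # neighbor offsets: down, right, down-right, up-right (covers all 8 via symmetry)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    r2 <- r + o[1L]; c2 <- c + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[j]
    if (!any(keep)) next
    edges[[length(edges) + 1L]] <- cbind(idx[ok][keep], j[keep])
  }
  if (length(edges) == 0L) {
    lab[idx] <- seq_along(idx)
    return(list(labels = lab, sizes = rep(1L, length(idx))))
  }
  em <- do.call(rbind, edges)
  verts <- as.character(idx)
  g <- igraph::graph_from_edgelist(cbind(as.character(em[, 1L]), as.character(em[, 2L])),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(verts, igraph::V(g)$name))
  comp <- igraph::components(g)
  memb <- comp$membership[verts]
  lab[idx] <- as.integer(memb)
  sizes <- as.integer(tabulate(memb, nbins = comp$no))
  list(labels = lab, sizes = sizes)
}

# Remove 8-connected components smaller than min_px from a logical matrix.
remove_small_components <- function(mask, min_px) {
  if (min_px <= 0 || !any(mask)) return(mask)
  lab <- label_components8(mask)
  keep <- which(lab$sizes >= min_px)
  lab$labels %in% keep & mask
}

# Chebyshev (box) dilation by 'r' pixels via EBImage.
dilate_mask <- function(mask, r) {
  if (r <= 0 || !any(mask)) return(mask != 0)
  brush <- EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "box")
  EBImage::dilate(mask * 1, brush) > 0
}

# Gaussian blur wrapper; sigma in pixels, no-op for sigma <= 0.
blur_gaussian <- function(pix, sigma) {
  if (sigma <= 0) return(pix)
  as.matrix(EBImage::gblur(pix, sigma = sigma))
}
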