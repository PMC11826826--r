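# Independent oracles used to cross-check the production code paths.

# Exhaustive breakpoint search: 1 ms grid over [0, 2400] with an inner least
# squares over a dense log-spaced half-rise grid and the closed-form
# amplitude. Ties resolve to the smallest breakpoint. Written independently
# of the package's grid/polish machinery.
oracle_fit_b <- function(times, y, variant = "continuous",
                         b_grid = seq(0, 2400, by = 1),
                         h_grid = exp(seq(log(20), log(10000), length.out = 400))) {
  yy <- sum(y * y)
  best_sse <- Inf
  best_b <- NA_real_
  lh <- log(h_grid)
  gain_at <- function(tt_act, y_act, hh) {
    v <- tt_act / (hh + tt_act)
    vv <- sum(v * v); yv <- sum(v * y_act)
    if (vv > 0 && yv > 0) yv^2 / vv else 0
  }
  V0 <- outer(times, h_grid, function(tt, hh) tt / (hh + tt))
  for (b in b_grid) {
    act <- times > b
    if (!any(act)) {
      sse <- yy
    } else {
      tt_act <- if (variant == "literal") times[act] else times[act] - b
      V <- if (variant == "literal") {
        V0[act, , drop = FALSE]
      } else {
        outer(tt_act, h_grid, function(dd, hh) dd / (hh + dd))
      }
      vv <- colSums(V * V)
      yv <- colSums(V * y[act])
      gain <- ifelse(vv > 0 & yv > 0, yv^2 / vv, 0)
      j <- which.max(gain)
      g <- max(gain)
      # parabolic refinement of the inner minimization in log h, so the
      # oracle's h discretization does not limit its breakpoint accuracy
      if (j > 1 && j < length(h_grid) && gain[j] > 0) {
        d1 <- gain[j + 1] - gain[j - 1]
        d2 <- gain[j + 1] - 2 * gain[j] + gain[j - 1]
        if (d2 < 0) {
          lh_ref <- lh[j] - 0.5 * d1 / d2 * (lh[j + 1] - lh[j])
          g <- max(g, gain_at(tt_act, y[act], exp(lh_ref)))
        }
      }
      sse <- yy - g
    }
    if (sse < best_sse - 1e-9 * max(1, yy)) {
      best_sse <- sse
      best_b <- b
    }
  }
  list(b = best_b, sse = best_sse)
}

# Connected components via the voxel adjacency graph (igraph), an
# implementation entirely separate from the package's flood fill.
oracle_area_open <- function(mask, min_size, connectivity) {
  idx <- which(mask)
  if (length(idx) == 0L) return(mask & FALSE)
  dims <- dim(mask)
  co <- arrayInd(idx, dims)
  # neighbour offsets
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  keep <- ord > 0 & switch(as.character(connectivity),
                           "6" = ord <= 1, "18" = ord <= 2, "26" = ord <= 3)
  offs <- offs[keep, ]
  pos_of <- array(0L, dims)
  pos_of[idx] <- seq_along(idx)
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- cbind(co[, 1] + offs$dx[r], co[, 2] + offs$dy[r], co[, 3] + offs$dz[r])
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] + (nb[ok, 2] - 1L) * dims[1] +
      nb[ok, 1]
    tgt <- pos_of[nb_lin]
    src <- seq_along(idx)[ok]
    conn <- tgt > 0L
    edges <- c(edges, rbind(src[conn], tgt[conn]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  keep_vox <- comp$csize[comp$membership] >= min_size
  out <- array(FALSE, dims)
  out[idx[keep_vox]] <- TRUE
  out
}
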