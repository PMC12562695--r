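#' @section Architecture:
#' The network encodes in 3D and decodes in 2D. Each of the \code{levels}
#' encoder stages applies a (residual) double 3x3x3 convolution block and
#' then halves x, y and z (z only while it is larger than 1). Every stage's
#' output is collapsed along the axial dimension by learned softmax
#' attention weights plus a 1x1 channel-mixing convolution, producing the
#' 2D skip connection. The 2D decoder mirrors the encoder: at each level it
#' upsamples, gates the collapsed skip with an additive attention gate,
#' concatenates and applies a (residual) double 3x3 convolution block. An
#' optional nIR channel is fused at the finest decoder level, and a final
#' 1x1 convolution with a logistic squashing yields the en face GA
#' probability mask.
#' @name net3d2d
#' @keywords internal
NULL

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid_ <- function(x) 1 / (1 + exp(-x))

he_mat <- function(nin, nout, scale = 1) {
  matrix(rnorm(nin * nout, sd = scale * sqrt(2 / nin)), nin, nout)
}

concat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (length(db) == 2L) { dim(b) <- c(db, 1L); db <- dim(b) }
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample2_bw <- function(dy) {
  d <- dim(dy)
  io <- seq(1, d[1], by = 2); ie <- seq(2, d[1], by = 2)
  jo <- seq(1, d[2], by = 2); je <- seq(2, d[2], by = 2)
  dy[io, jo, , drop = FALSE] + dy[ie, jo, , drop = FALSE] +
    dy[io, je, , drop = FALSE] + dy[ie, je, , drop = FALSE]
}

# channel counts per level
level_channels <- function(config) config@baseChannels * 2^(seq_len(config@levels) - 1L)

#' Build the 3D-to-2D segmentation network
#'
#' Parameters are He-initialized from \code{config@seed}; the final 1x1
#' convolution is initialized at a tenth of the usual scale. Two builds
#' from the same configuration (including seed) are bit-identical.
#'
#' @param config a \linkS4class{NetConfig}.
#' @return A \linkS4class{GANet}.
#' @examples
#' net <- buildNet(netConfig(c(16, 16, 8), levels = 2L, baseChannels = 4L))
#' net
#' @export
buildNet <- function(config) {
  validObject(config)
  L <- config@levels
  ch <- level_channels(config)
  p <- list()
  with_seed(config@seed, {
    ci <- 1L
    for (l in seq_len(L)) {
      co <- ch[l]
      p[[sprintf("e%dc1W", l)]] <- he_mat(27L * ci, co)
      p[[sprintf("e%dc1b", l)]] <- numeric(co)
      p[[sprintf("e%dc2W", l)]] <- he_mat(27L * co, co)
      p[[sprintf("e%dc2b", l)]] <- numeric(co)
      if (config@useResidual) p[[sprintf("e%dpW", l)]] <- he_mat(ci, co)
      p[[sprintf("col%da", l)]] <- numeric(co)
      p[[sprintf("col%db", l)]] <- numeric(co)
      p[[sprintf("col%dmW", l)]] <- diag(co)
      p[[sprintf("col%dmb", l)]] <- numeric(co)
      ci <- co
    }
    for (l in rev(seq_len(L - 1))) {
      cl <- ch[l]; cu <- ch[l + 1]
      if (config@useAttention) {
        cg <- max(cl %/% 2L, 1L)
        # gate projections start non-negative: skip/gating features are
        # ReLU outputs, so this guarantees live hidden units at init
        p[[sprintf("d%dgWx", l)]] <- abs(he_mat(cl, cg))
        p[[sprintf("d%dgWg", l)]] <- abs(he_mat(cu, cg))
        p[[sprintf("d%dgbg", l)]] <- rep(0.1, cg)
        p[[sprintf("d%dgpsi", l)]] <- he_mat(cg, 1L)
        p[[sprintf("d%dgbp", l)]] <- numeric(1L)
      }
      cin <- cl + cu
      p[[sprintf("d%dc1W", l)]] <- he_mat(9L * cin, cl)
      p[[sprintf("d%dc1b", l)]] <- numeric(cl)
      p[[sprintf("d%dc2W", l)]] <- he_mat(9L * cl, cl)
      p[[sprintf("d%dc2b", l)]] <- numeric(cl)
      if (config@useResidual) p[[sprintf("d%dpW", l)]] <- he_mat(cin, cl)
    }
    if (config@inChannels == 2L) {
      p[["nW"]] <- he_mat(9L * (ch[1] + 1L), ch[1])
      p[["nb"]] <- numeric(ch[1])
    }
    p[["fW"]] <- he_mat(ch[1], 1L, scale = 0.1)
    p[["fb"]] <- numeric(1L)
  })
  new("GANet", config = config, params = p)
}

# ---------------------------------------------------------------------------
# axial collapse: softmax attention over z, then 1x1 channel mixing

collapse_fw <- function(f, a, b, mixW, mixb) {
  r <- cpp_collapse_fw(f, a, b, mixW, mixb)
  list(out = r$out, cache = list(f = f, wm = r$wm, S1 = r$S1, a = a,
                                 mixW = mixW))
}

collapse_bw <- function(cache, dOut) {
  cpp_collapse_bw(cache$f, cache$wm, cache$S1, cache$a, cache$mixW, dOut)
}

#' Collapse a 3D feature grid to 2D by axial softmax attention
#'
#' Reduction over the axial (z) axis using softmax attention weights with
#' per-channel learned logit scale/offset, followed by a 1x1 channel-mixing
#' convolution. With zero logits (the untrained state) the reduction equals
#' the plain mean over z; with z = 1 the output is the single slice after
#' channel mixing.
#'
#' @param features 4D array (z, x, y, channels), or 3D (z, x, y) treated as
#'   one channel.
#' @param a,b per-channel attention logit scale and offset (default 0).
#' @param mixW,mixb channel-mixing weights (default identity) and bias.
#' @return 3D array (x, y, channels).
#' @export
collapseTo2d <- function(features, a = NULL, b = NULL, mixW = NULL,
                         mixb = NULL) {
  if (length(dim(features)) == 3L) dim(features) <- c(dim(features), 1L)
  nc <- dim(features)[4]
  if (is.null(a)) a <- numeric(nc)
  if (is.null(b)) b <- numeric(nc)
  if (is.null(mixW)) mixW <- diag(nc)
  if (is.null(mixb)) mixb <- numeric(nc)
  collapse_fw(features, a, b, mixW, mixb)$out
}

# ---------------------------------------------------------------------------
# additive attention gate

gate_fw <- function(s, u, Wx, Wg, bg, psi, bp) {
  ds <- dim(s)
  m <- ds[1] * ds[2]
  Sm <- matrix(s, m, ds[3])
  Um <- matrix(u, m, dim(u)[3])
  h <- relu(Sm %*% Wx + Um %*% Wg + rep(bg, each = m))
  alpha <- sigmoid_(as.numeric(h %*% psi + bp))
  out <- array(Sm * alpha, ds)
  list(out = out, cache = list(Sm = Sm, Um = Um, h = h, alpha = alpha,
                               Wx = Wx, Wg = Wg, psi = psi, ds = ds,
                               du = dim(u)))
}

gate_bw <- function(cache, dOut) {
  ds <- cache$ds
  m <- ds[1] * ds[2]
  dO <- matrix(dOut, m, ds[3])
  dalpha <- rowSums(dO * cache$Sm)
  dSm <- dO * cache$alpha
  dz <- dalpha * cache$alpha * (1 - cache$alpha)
  dpsi <- t(cache$h) %*% dz
  dbp <- sum(dz)
  dh <- (dz %*% t(cache$psi)) * (cache$h > 0)
  dWx <- t(cache$Sm) %*% dh
  dWg <- t(cache$Um) %*% dh
  dbg <- colSums(dh)
  dSm <- dSm + dh %*% t(cache$Wx)
  dUm <- dh %*% t(cache$Wg)
  list(dS = array(dSm, ds), dU = array(dUm, cache$du), dWx = dWx, dWg = dWg,
       dbg = dbg, dpsi = dpsi, dbp = dbp)
}

#' Apply an additive attention gate to a 2D skip connection
#'
#' Both inputs are projected to an intermediate width, summed, passed
#' through a ReLU, reduced to one channel and squashed to a per-pixel gate
#' alpha in [0, 1]; the output is \code{skip * alpha}. A gating signal at
#' half the skip's resolution is nearest-neighbour upsampled first.
#'
#' @param skip 3D array (x, y, c).
#' @param gating 3D array (x, y, c') at the same or half resolution.
#' @param params optional list with \code{Wx}, \code{Wg}, \code{bg},
#'   \code{psi}, \code{bp}; defaults are zero projections (alpha = 0.5
#'   everywhere), so tests can override \code{bp} to force alpha.
#' @return Gated array, same shape as \code{skip}.
#' @export
attentionGate <- function(skip, gating, params = NULL) {
  if (length(dim(skip)) == 2L) dim(skip) <- c(dim(skip), 1L)
  if (length(dim(gating)) == 2L) dim(gating) <- c(dim(gating), 1L)
  if (all(dim(gating)[1:2] * 2L == dim(skip)[1:2])) gating <- upsample2(gating)
  if (!all(dim(gating)[1:2] == dim(skip)[1:2]))
    stop("spatial dimensions of skip and gating do not match")
  cs <- dim(skip)[3]; cg <- dim(gating)[3]
  ci <- max(cs %/% 2L, 1L)
  if (is.null(params))
    params <- list(Wx = matrix(0, cs, ci), Wg = matrix(0, cg, ci),
                   bg = numeric(ci), psi = matrix(0, ci, 1L), bp = 0)
  gate_fw(skip, gating, params$Wx, params$Wg, params$bg, params$psi,
          params$bp)$out
}

# ---------------------------------------------------------------------------
# full forward / backward

net_fw <- function(net, vol, nir = NULL, keepCache = TRUE) {
  cfg <- net@config
  p <- net@params
  L <- cfg@levels
  if (!all(dim(vol) == cfg@inputDims))
    stop("input volume dimensions do not match the network configuration")
  if (cfg@inChannels == 2L && is.null(nir))
    stop("this network expects an nIR channel")
  if (cfg@inChannels == 1L && !is.null(nir)) nir <- NULL
  x <- vol
  dim(x) <- c(dim(vol), 1L)
  enc <- vector("list", L)
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    c1pre <- cpp_conv3d_fw(x, p[[sprintf("e%dc1W", l)]],
                           p[[sprintf("e%dc1b", l)]], 3L)
    h1 <- relu(c1pre)
    c2pre <- cpp_conv3d_fw(h1, p[[sprintf("e%dc2W", l)]],
                           p[[sprintf("e%dc2b", l)]], 3L)
    if (cfg@useResidual) {
      pre <- c2pre + cpp_conv3d_fw(x, p[[sprintf("e%dpW", l)]],
                                   numeric(ncol(p[[sprintf("e%dpW", l)]])), 1L)
    } else pre <- c2pre
    f <- relu(pre)
    col <- collapse_fw(f, p[[sprintf("col%da", l)]], p[[sprintf("col%db", l)]],
                       p[[sprintf("col%dmW", l)]], p[[sprintf("col%dmb", l)]])
    skips[[l]] <- col$out
    if (keepCache)
      enc[[l]] <- list(x = x, h1 = h1, f = f, pre = pre, c1pre = c1pre,
                       col = col$cache)
    if (l < L) {
      fz <- if (dim(f)[1] > 1L) 2L else 1L
      pl <- cpp_maxpool3d(f, fz, 2L, 2L)
      if (keepCache) enc[[l]]$pool <- list(idx = pl$idx, dimIn = dim(f))
      x <- pl$y
    }
  }
  d <- skips[[L]]
  dec <- vector("list", L)
  for (l in rev(seq_len(L - 1))) {
    u <- upsample2(d)
    s <- skips[[l]]
    if (cfg@useAttention) {
      g <- gate_fw(s, u, p[[sprintf("d%dgWx", l)]], p[[sprintf("d%dgWg", l)]],
                   p[[sprintf("d%dgbg", l)]], p[[sprintf("d%dgpsi", l)]],
                   p[[sprintf("d%dgbp", l)]])
      sg <- g$out
    } else { g <- NULL; sg <- s }
    cat_ <- concat3(sg, u)
    c1pre <- cpp_conv2d_fw(cat_, p[[sprintf("d%dc1W", l)]],
                           p[[sprintf("d%dc1b", l)]], 3L)
    h1 <- relu(c1pre)
    c2pre <- cpp_conv2d_fw(h1, p[[sprintf("d%dc2W", l)]],
                           p[[sprintf("d%dc2b", l)]], 3L)
    if (cfg@useResidual) {
      pre <- c2pre + cpp_conv2d_fw(cat_, p[[sprintf("d%dpW", l)]],
                                   numeric(ncol(p[[sprintf("d%dpW", l)]])), 1L)
    } else pre <- c2pre
    dn <- relu(pre)
    if (keepCache)
      dec[[l]] <- list(cat = cat_, h1 = h1, pre = pre, c1pre = c1pre,
                       gate = if (!is.null(g)) g$cache else NULL)
    d <- dn
  }
  nirCache <- NULL
  if (cfg@inChannels == 2L) {
    cat2 <- concat3(d, nir)
    npre <- cpp_conv2d_fw(cat2, p[["nW"]], p[["nb"]], 3L)
    dnew <- relu(npre)
    if (keepCache) nirCache <- list(cat = cat2, pre = npre)
    d <- dnew
  }
  logit <- cpp_conv2d_fw(d, p[["fW"]], p[["fb"]], 1L)
  prob <- sigmoid_(logit[, , 1])
  cache <- if (keepCache) list(enc = enc, dec = dec, nir = nirCache,
                               dTop = d, logit = logit) else NULL
  list(prob = prob, cache = cache)
}

net_bw <- function(net, cache, dLogit) {
  cfg <- net@config
  p <- net@params
  L <- cfg@levels
  ch <- level_channels(cfg)
  g <- list()
  dl <- dLogit
  dim(dl) <- c(dim(dLogit), 1L)
  bw <- cpp_conv2d_bw(cache$dTop, p[["fW"]], dl, 1L)
  g[["fW"]] <- bw$dW; g[["fb"]] <- bw$db
  dd <- bw$dx
  if (cfg@inChannels == 2L) {
    dd <- dd * (cache$nir$pre > 0)
    bw <- cpp_conv2d_bw(cache$nir$cat, p[["nW"]], dd, 3L)
    g[["nW"]] <- bw$dW; g[["nb"]] <- bw$db
    nc <- dim(bw$dx)[3] - 1L
    dd <- bw$dx[, , seq_len(nc), drop = FALSE]
  }
  # decoder: walk from the finest block upward, carrying dd = grad w.r.t.
  # the decoder state d_l entering block l
  dskips <- vector("list", L)
  for (l in seq_len(L - 1)) {
    dc <- cache$dec[[l]]
    dpre <- dd * (dc$pre > 0)
    bw2 <- cpp_conv2d_bw(dc$h1, p[[sprintf("d%dc2W", l)]], dpre, 3L)
    g[[sprintf("d%dc2W", l)]] <- bw2$dW
    g[[sprintf("d%dc2b", l)]] <- bw2$db
    dh1 <- bw2$dx * (dc$c1pre > 0)
    bw1 <- cpp_conv2d_bw(dc$cat, p[[sprintf("d%dc1W", l)]], dh1, 3L)
    g[[sprintf("d%dc1W", l)]] <- bw1$dW
    g[[sprintf("d%dc1b", l)]] <- bw1$db
    dcat <- bw1$dx
    if (cfg@useResidual) {
      bwp <- cpp_conv2d_bw(dc$cat, p[[sprintf("d%dpW", l)]], dpre, 1L)
      g[[sprintf("d%dpW", l)]] <- bwp$dW
      dcat <- dcat + bwp$dx
    }
    nS <- ch[l]
    dS <- dcat[, , seq_len(nS), drop = FALSE]
    dU <- dcat[, , nS + seq_len(dim(dcat)[3] - nS), drop = FALSE]
    if (cfg@useAttention) {
      gb <- gate_bw(dc$gate, dS)
      g[[sprintf("d%dgWx", l)]] <- gb$dWx
      g[[sprintf("d%dgWg", l)]] <- gb$dWg
      g[[sprintf("d%dgbg", l)]] <- gb$dbg
      g[[sprintf("d%dgpsi", l)]] <- gb$dpsi
      g[[sprintf("d%dgbp", l)]] <- gb$dbp
      dS <- gb$dS
      dU <- dU + gb$dU
    }
    dskips[[l]] <- dS
    dd <- upsample2_bw(dU)          # grad w.r.t. d_{l+1}
  }
  dskips[[L]] <- dd                  # d_L is skip_L itself
  # encoder: from the deepest level back to the input
  dxin <- NULL
  for (l in rev(seq_len(L))) {
    ec <- cache$enc[[l]]
    cb <- collapse_bw(ec$col, dskips[[l]])
    g[[sprintf("col%da", l)]] <- cb$da
    g[[sprintf("col%db", l)]] <- cb$db
    g[[sprintf("col%dmW", l)]] <- cb$dmixW
    g[[sprintf("col%dmb", l)]] <- cb$dmixb
    dF <- cb$dF
    if (l < L)
      dF <- dF + cpp_maxpool3d_bw(ec$pool$idx, dxin, ec$pool$dimIn)
    dpre <- dF * (ec$pre > 0)
    bw2 <- cpp_conv3d_bw(ec$h1, p[[sprintf("e%dc2W", l)]], dpre, 3L)
    g[[sprintf("e%dc2W", l)]] <- bw2$dW
    g[[sprintf("e%dc2b", l)]] <- bw2$db
    dh1 <- bw2$dx * (ec$c1pre > 0)
    bw1 <- cpp_conv3d_bw(ec$x, p[[sprintf("e%dc1W", l)]], dh1, 3L)
    g[[sprintf("e%dc1W", l)]] <- bw1$dW
    g[[sprintf("e%dc1b", l)]] <- bw1$db
    dx <- bw1$dx
    if (cfg@useResidual) {
      bwp <- cpp_conv3d_bw(ec$x, p[[sprintf("e%dpW", l)]], dpre, 1L)
      g[[sprintf("e%dpW", l)]] <- bwp$dW
      dx <- dx + bwp$dx
    }
    dxin <- dx
  }
  g
}

#' Run the network on one input
#'
#' @param net a \linkS4class{GANet}.
#' @param input a \linkS4class{NetInput} (or bare 3D array) at the network's
#'   input dimensions; an nIR channel is required iff the network was built
#'   with \code{inChannels = 2}.
#' @param pixelAreaMM2 en face pixel area to attach; inferred from the
#'   input's target mask when available.
#' @return A probability \linkS4class{EnFaceMask} (values in [0, 1],
#'   \code{binary = FALSE}) at the configured mask dimensions.
#' @export
netForward <- function(net, input, pixelAreaMM2 = NA_real_) {
  if (is.array(input)) input <- NetInput(input)
  out <- net_fw(net, input@volume, input@nir, keepCache = FALSE)
  if (is.na(pixelAreaMM2)) {
    pixelAreaMM2 <- if (!is.null(input@target)) input@target@pixelAreaMM2 else 1
  }
  EnFaceMask(out$prob, pixelAreaMM2, binary = FALSE)
}

#' Threshold a probability mask
#'
#' Pixels with probability greater than or equal to \code{threshold} map to
#' 1 (ties map to 1), others to 0. Idempotent on binary masks at the
#' default threshold.
#'
#' @param p a probability \linkS4class{EnFaceMask} (or numeric matrix).
#' @param threshold scalar in (0, 1).
#' @return A binary \linkS4class{EnFaceMask}.
#' @export
binarizeMask <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (is.matrix(p)) p <- EnFaceMask(p, 1, binary = FALSE)
  EnFaceMask((p@grid >= threshold) * 1, p@pixelAreaMM2, binary = TRUE)
}

#' Checksum of all network parameters
#'
#' Deterministic digest used to assert build reproducibility.
#'
#' @param net a \linkS4class{GANet}.
#' @return A single numeric value.
#' @export
netChecksum <- function(net) {
  v <- unlist(net@params, use.names = FALSE)
  sum(v * seq_along(v) %% 97) + sum(abs(v))
}

#' Save / load a network checkpoint
#'
#' Checkpoints are a single JSON file holding the \linkS4class{NetConfig}
#' header and every parameter tensor with its dimensions.
#'
#' @param net a \linkS4class{GANet}.
#' @param path checkpoint path (.json).
#' @return \code{saveNet}: \code{path} invisibly; \code{loadNet}: the
#'   reconstructed \linkS4class{GANet}.
#' @export
saveNet <- function(net, path) {
  cfg <- net@config
  obj <- list(
    config = list(levels = cfg@levels, baseChannels = cfg@baseChannels,
                  useAttention = cfg@useAttention,
                  useResidual = cfg@useResidual, inChannels = cfg@inChannels,
                  inputDims = cfg@inputDims, seed = cfg@seed),
    params = lapply(net@params, function(x)
      list(dim = dim(x) %||% length(x), values = as.numeric(x))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveNet
#' @export
loadNet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- netConfig(inputDims = obj$config$inputDims,
                   levels = obj$config$levels,
                   baseChannels = obj$config$baseChannels,
                   useAttention = obj$config$useAttention,
                   useResidual = obj$config$useResidual,
                   inChannels = obj$config$inChannels,
                   seed = obj$config$seed)
  params <- lapply(obj$params, function(p) {
    v <- as.numeric(p$values)
    if (length(p$dim) > 1L) dim(v) <- p$dim
    v
  })
  new("GANet", config = cfg, params = params)
}
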