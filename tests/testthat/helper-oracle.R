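# Independent R reference implementation of the network forward pass
# (inference mode), written with naive nested loops directly from the layer
# definitions. Used as the oracle for shapes, convolution arithmetic,
# normalization, GAP and the residual wiring of the compiled implementation.

ref_conv <- function(A, W, b, k, s, pad, groups) {
  H <- dim(A)[1]; Wd <- dim(A)[2]; Cin <- dim(A)[3]
  out_c <- length(b); in_pg <- Cin %/% groups; out_pg <- out_c %/% groups
  Ho <- (H + 2 * pad - k) %/% s + 1
  Wo <- (Wd + 2 * pad - k) %/% s + 1
  Y <- array(0, c(Ho, Wo, out_c))
  for (co in seq_len(out_c)) {
    g <- (co - 1) %/% out_pg
    for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
      acc <- b[co]
      for (cl in seq_len(in_pg)) {
        ci <- g * in_pg + cl
        for (kw in 0:(k - 1)) for (kh in 0:(k - 1)) {
          hi <- (ho - 1) * s - pad + kh + 1
          wi <- (wo - 1) * s - pad + kw + 1
          if (hi >= 1 && hi <= H && wi >= 1 && wi <= Wd)
            acc <- acc + A[hi, wi, ci] * W[(cl - 1) * k * k + kw * k + kh + 1, co]
        }
      }
      Y[ho, wo, co] <- acc
    }
  }
  Y
}

ref_layernorm <- function(A, g, be, eps = 1e-5) {
  out <- A
  for (h in seq_len(dim(A)[1])) for (w in seq_len(dim(A)[2])) {
    v <- A[h, w, ]
    mu <- mean(v); va <- mean((v - mu)^2)
    out[h, w, ] <- (v - mu) / sqrt(va + eps) * g + be
  }
  out
}

ref_batchnorm_inf <- function(A, g, be, rmean, rvar, eps = 1e-5) {
  out <- A
  for (c in seq_len(dim(A)[3]))
    out[, , c] <- (A[, , c] - rmean[c]) / sqrt(rvar[c] + eps) * g[c] + be[c]
  out
}

ref_gelu <- function(A) A * pnorm(A)

# full reference forward for one image (inference mode); skip_blocks drops
# every block's contribution (what the network must equal when all block
# point-wise convolutions are zeroed, by the residual identity)
ref_forward <- function(model, img, skip_blocks = FALSE) {
  spec <- model$spec
  params <- gptnext:::cpp_net_get_params(model$ptr)
  state <- gptnext:::cpp_net_get_state(model$ptr)
  pcur <- 0L
  pop <- function(n) {
    v <- params[pcur + seq_len(n)]
    pcur <<- pcur + n
    v
  }
  scur <- 0L
  pop_state <- function(C) {
    m <- state[scur + seq_len(C)]; v <- state[scur + C + seq_len(C)]
    scur <<- scur + 2L * C
    list(mean = m, var = v)
  }
  f <- spec$filters; ex <- spec$expansion_factor
  # stem
  W <- matrix(pop(4 * 4 * spec$input_channels * f[1]), nrow = 4 * 4 * spec$input_channels)
  b <- pop(f[1])
  A <- ref_conv(img, W, b, k = 4, s = 4, pad = 0, groups = 1)
  g <- pop(f[1]); be <- pop(f[1]); st <- pop_state(f[1])
  A <- ref_gelu(ref_batchnorm_inf(A, g, be, st$mean, st$var))
  for (i in 1:4) {
    C <- f[i]
    for (r in seq_len(spec$repetitions[i])) {
      for (s2 in 1:2) {
        lng <- pop(C); lnb <- pop(C)
        dwW <- matrix(pop(9 * ex * C), nrow = 9); dwb <- pop(ex * C)
        pwW <- matrix(pop(ex * C * C), nrow = ex * C); pwb <- pop(C)
        bng <- pop(C); bnb <- pop(C); st <- pop_state(C)
        t <- ref_layernorm(A, lng, lnb)
        t <- ref_conv(t, dwW, dwb, k = 3, s = 1, pad = 1, groups = C)
        t <- ref_gelu(t)
        t <- ref_conv(t, pwW, pwb, k = 1, s = 1, pad = 0, groups = 1)
        t <- ref_batchnorm_inf(t, bng, bnb, st$mean, st$var)
        if (!skip_blocks) A <- A + t
      }
    }
    if (i < 4) {
      Cn <- f[i + 1]
      dW <- matrix(pop(4 * Cn), nrow = 4); db <- pop(Cn)
      A <- ref_conv(A, dW, db, k = 2, s = 2, pad = 0, groups = C)
      g <- pop(Cn); be <- pop(Cn)
      A <- ref_gelu(ref_layernorm(A, g, be))
    }
  }
  oW <- matrix(pop(f[4] * f[5]), nrow = f[4]); ob <- pop(f[5])
  A <- ref_conv(A, oW, ob, k = 1, s = 1, pad = 0, groups = 1)
  g <- pop(f[5]); be <- pop(f[5])
  A <- ref_layernorm(A, g, be)
  A <- ref_gelu(A)
  g <- pop(f[5]); be <- pop(f[5]); st <- pop_state(f[5])
  A <- ref_batchnorm_inf(A, g, be, st$mean, st$var)
  gap <- apply(A, 3, mean)
  fcW <- matrix(pop(f[5] * spec$num_classes), nrow = f[5])
  fcb <- pop(spec$num_classes)
  logits <- drop(gap %*% fcW) + fcb
  e <- exp(logits - max(logits))
  stopifnot(pcur == length(params), scur == length(state))
  list(gap = gap, probs = e / sum(e))
}
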