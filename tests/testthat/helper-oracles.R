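# Independent oracles for the diploid copying model, written against the
# model definition only (no shared code with src/ls_hmm.cpp).
# State s = (i-1)*H + m encodes the ordered template pair (i, m).

state_i <- function(H) rep(seq_len(H), each = H)
state_m <- function(H) rep(seq_len(H), times = H)

emis_state_vec <- function(ref, gt, l, err) {
  H <- nrow(ref)
  S <- H * H
  if (is.na(gt[l])) return(rep(1, S))
  io <- state_i(H)
  mo <- state_m(H)
  vapply(seq_len(S), function(s) {
    a <- ref[io[s], l] + ref[mo[s], l]
    p1 <- if (a >= 1) 1 - err else err
    p2 <- if (a == 2) 1 - err else err
    c((1 - p1) * (1 - p2), p1 * (1 - p2) + (1 - p1) * p2, p1 * p2)[gt[l] + 1]
  }, numeric(1))
}

state_posterior_to_geno <- function(ref, post_state) {
  H <- nrow(ref)
  L <- ncol(ref)
  io <- state_i(H)
  mo <- state_m(H)
  post <- matrix(0, 3, L)
  for (l in seq_len(L)) {
    g <- ref[io, l] + ref[mo, l]
    for (gg in 0:2) post[gg + 1, l] <- sum(post_state[g == gg, l])
  }
  sweep(post, 2, colSums(post), "/")
}

# forward-backward with the full, explicitly constructed S x S transition
# matrix (kronecker of the single-chromosome kernels)
ls_fb_dense <- function(ref, gt, dmorgan, rho, err) {
  H <- nrow(ref)
  L <- ncol(ref)
  S <- H * H
  TT <- function(d) {
    r <- 1 - exp(-rho * d)
    T1 <- (1 - r) * diag(H) + r / H
    kronecker(T1, T1)
  }
  A <- matrix(0, S, L)
  A[, 1] <- emis_state_vec(ref, gt, 1, err) / S
  A[, 1] <- A[, 1] / sum(A[, 1])
  if (L > 1) for (l in 2:L) {
    v <- as.vector(t(TT(dmorgan[l - 1])) %*% A[, l - 1]) *
      emis_state_vec(ref, gt, l, err)
    A[, l] <- v / sum(v)
  }
  B <- matrix(0, S, L)
  B[, L] <- 1
  if (L > 1) for (l in (L - 1):1) {
    v <- as.vector(TT(dmorgan[l]) %*%
                     (emis_state_vec(ref, gt, l + 1, err) * B[, l + 1]))
    B[, l] <- v / sum(v)
  }
  state_posterior_to_geno(ref, A * B)
}

# brute-force sum over every template-pair path (S^L of them)
ls_enum <- function(ref, gt, dmorgan, rho, err) {
  H <- nrow(ref)
  L <- ncol(ref)
  S <- H * H
  io <- state_i(H)
  mo <- state_m(H)
  E <- sapply(seq_len(L), function(l) emis_state_vec(ref, gt, l, err))
  T1 <- lapply(dmorgan, function(d) {
    r <- 1 - exp(-rho * d)
    (1 - r) * diag(H) + r / H
  })
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), L)))
  w <- rep(1 / S, nrow(paths)) * E[cbind(paths[, 1], 1)]
  if (L > 1) for (l in 2:L) {
    tr <- T1[[l - 1]]
    w <- w * tr[cbind(io[paths[, l - 1]], io[paths[, l]])] *
      tr[cbind(mo[paths[, l - 1]], mo[paths[, l]])] *
      E[cbind(paths[, l], l)]
  }
  post_state <- matrix(0, S, L)
  for (l in seq_len(L))
    post_state[, l] <- as.numeric(rowsum(w, paths[, l],
                                         reorder = TRUE)[
                                           as.character(seq_len(S)), ])
  post_state[is.na(post_state)] <- 0
  state_posterior_to_geno(ref, post_state)
}

rand_hmm_instance <- function(H, L, seed) {
  withr::with_seed(seed, {
    ref <- matrix(sample(0:1, H * L, replace = TRUE), H, L)
    gt <- sample(c(0:2, NA), L, replace = TRUE)
    if (all(is.na(gt))) gt[1] <- sample(0:2, 1)
    list(ref = ref, gt = gt,
         dmorgan = runif(L - 1, 1e-4, 0.05),
         rho = runif(1, 10, 200),
         err = runif(1, 1e-3, 0.1))
  })
}

pkg_fb <- function(inst) {
  seqimp:::.ls_diploid_fb(inst$ref, as.integer(inst$gt), inst$dmorgan,
                          inst$rho, rep(inst$err, ncol(inst$ref)))
}

# brute-force maximal r^2 between two binary variables over a grid of
# admissible disequilibria D
max_r2_grid <- function(p, q, n_grid = 20001) {
  d_lo <- -min(p * q, (1 - p) * (1 - q))
  d_hi <- min(p * (1 - q), q * (1 - p))
  D <- seq(d_lo, d_hi, length.out = n_grid)
  max(D^2 / (p * (1 - p) * q * (1 - q)))
}
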