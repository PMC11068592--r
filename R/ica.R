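# Symmetric FastICA with logcosh contrast.
#
# X: channels x samples (rows centred internally). Whitening uses the
# eigendecomposition of the channel covariance with small eigenvalues
# dropped (average-referenced EEG is rank-deficient by one), so the number
# of components equals the numerical rank. The unmixing matrix may be
# estimated on a column subsample for speed and is then applied to the full
# data. Deterministic for a given seed.
#
# Returns list(S = components x samples, A = channels x components mixing,
# mu = channel means, rank).
.fastica <- function(x, seed = 1L, max_sub = 10000L, tol = 1e-5,
                     maxit = 200L) {
  nch <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / (ncol(xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-9
  r <- sum(keep)
  if (r < 2) stop("data rank below 2; ICA decomposition impossible")
  K <- diag(1 / sqrt(eg$values[keep]), r) %*% t(eg$vectors[, keep, drop = FALSE])
  idx <- if (ncol(xc) > max_sub)
    round(seq(1, ncol(xc), length.out = max_sub)) else seq_len(ncol(xc))
  z <- K %*% xc[, idx, drop = FALSE]
  m <- ncol(z)

  sym_orth <- function(w) {
    s <- eigen(tcrossprod(w), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-12)), r) %*%
      t(s$vectors) %*% w
  }
  w <- with_seed(seed, matrix(stats::rnorm(r * r), r, r))
  w <- sym_orth(w)
  for (it in seq_len(maxit)) {
    wz <- w %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    w1 <- sym_orth(tcrossprod(g, z) / m - diag(gp, r) %*% w)
    delta <- max(abs(abs(diag(w1 %*% t(w))) - 1))
    w <- w1
    if (delta < tol) break
  }
  S <- w %*% (K %*% xc)
  A <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), r) %*% t(w)
  list(S = S, A = A, mu = mu, rank = r)
}

#' ICA-based ocular correction
#'
#' Decomposes the epoch into independent components (FastICA with as many
#' components as the data's numerical rank), zeroes every component whose
#' absolute correlation with a virtual EOG channel (the mean of Fp1 and
#' Fp2) exceeds `threshold`, and back-projects. If the decomposition is
#' impossible (rank below 2) the function falls back to channelwise
#' regression of the virtual EOG out of the data, with a message.
#'
#' @param epoch an `fpvs_epoch` (or recording) containing Fp1 and Fp2.
#' @param threshold absolute correlation above which a component is
#'   considered ocular.
#' @param seed seed for the ICA initialisation.
#' @return A list with `epoch` (corrected) and `n_removed` (components
#'   zeroed; `NA`-free, 0 when nothing resembles the EOG).
#' @export
ocular_correct <- function(epoch, threshold = 0.8, seed = 1L) {
  if (!all(c("Fp1", "Fp2") %in% epoch$labels))
    stop("ocular correction needs Fp1 and Fp2")
  if (nrow(epoch$data) < 2) stop("need at least two channels")
  eog <- colMeans(epoch$data[match(c("Fp1", "Fp2"), epoch$labels), ,
                             drop = FALSE])
  dec <- tryCatch(.fastica(epoch$data, seed = seed), error = function(e) e)
  if (inherits(dec, "error")) {
    message("ICA decomposition failed (", conditionMessage(dec),
            "); falling back to EOG regression")
    ec <- eog - mean(eog)
    v <- sum(ec^2)
    if (v > 0) {
      b <- (epoch$data %*% ec) / v
      epoch$data <- epoch$data - b %*% t(ec)
    }
    return(list(epoch = epoch, n_removed = NA_integer_))
  }
  sds <- apply(dec$S, 1, stats::sd)
  cors <- rep(0, nrow(dec$S))
  ok <- sds > 0 & stats::sd(eog) > 0
  if (any(ok))
    cors[ok] <- abs(apply(dec$S[ok, , drop = FALSE], 1,
                          function(s) stats::cor(s, eog)))
  drop_idx <- which(cors > threshold)
  if (length(drop_idx)) {
    S <- dec$S
    S[drop_idx, ] <- 0
    epoch$data <- dec$A %*% S + dec$mu
  }
  list(epoch = epoch, n_removed = length(drop_idx))
}
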