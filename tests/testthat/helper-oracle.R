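# Independent brute-force likelihood oracle: enumerates every joint
# assignment of (major genotype x polygene level) to every family member
# and sums founder priors x Mendelian/hypergeometric transmission x
# penetrance directly. Never calls the peeling code. State spaces are kept
# tractable by enumerating only states whose allele counts are possible
# under the model (a locus with zero allele frequency admits only zero
# copies).

brute_full_transmission <- function(ctx) {
  G <- ctx$G; R <- ctx$R; S <- G * R
  TM <- major_transmission(ctx$params)
  TP <- ctx$grid$transmission
  Tfull <- array(0, c(S, S, S))
  for (rc in 1:R) for (rm in 1:R) for (rf in 1:R) {
    Tfull[(rc - 1) * G + 1:G, (rm - 1) * G + 1:G, (rf - 1) * G + 1:G] <-
      Tfull[(rc - 1) * G + 1:G, (rm - 1) * G + 1:G, (rf - 1) * G + 1:G] +
      TM * TP[rc, rm, rf]
  }
  Tfull
}

brute_allowed_states <- function(ctx) {
  st <- ctx$states
  ok <- rep(TRUE, nrow(st))
  if (ctx$params$f1 == 0) ok <- ok & st$b1 == 0
  if (ctx$params$f2 == 0) ok <- ok & st$b2 == 0
  if ("m3" %in% names(st) && !is.na(ctx$params$fM) && ctx$params$fM == 0) {
    ok <- ok & st$m3 == 0
  }
  which(rep(ok, times = ctx$R))
}

brute_loglik <- function(ctx, p, chunk = 200000L) {
  S <- ctx$G * ctx$R
  Tfull <- brute_full_transmission(ctx)
  PEN <- ovarisk:::pen_matrix(ctx, p)
  keep <- brute_allowed_states(ctx)
  n <- nrow(p)
  fa <- match(p$father_id, p$id); mo <- match(p$mother_id, p$id)
  K <- length(keep)
  total <- K^n
  stopifnot(total <= 2e6)
  tot <- 0
  done <- 0
  while (done < total) {
    m <- min(chunk, total - done)
    idx <- done + seq_len(m) - 1
    combo <- matrix(0L, m, n)
    rem <- idx
    for (j in 1:n) {
      combo[, j] <- keep[rem %% K + 1L]
      rem <- rem %/% K
    }
    w <- rep(1, m)
    for (j in 1:n) {
      w <- w * PEN[cbind(combo[, j], j)]
      if (is.na(fa[j])) {
        w <- w * ctx$prior[combo[, j]]
      } else {
        w <- w * Tfull[cbind(combo[, j], combo[, mo[j]], combo[, fa[j]])]
      }
    }
    tot <- tot + sum(w)
    done <- done + m
  }
  log(tot)
}

# Gauss-Hermite nodes/weights (Golub-Welsch) for quadrature over a normal
statmod_gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}
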